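#' Count river drainage outlets of an embayment
#'
#' An outlet is the terminal point of a flowline with no downstream
#' pointer. Outlets inside the CEP or within `tol_km` of its cells (mouth
#' whiskers left open by the coastline closing) count towards the CEP.
#'
#' @param ceps a `cep_set`.
#' @param id CEP id; omit to get the count for every CEP.
#' @param flowlines flowline layer with `outlet_x`/`outlet_y` attributes.
#' @param tol_km snap tolerance (km).
#' @return integer count (or named vector over all ids).
#' @export
count_outlets <- function(ceps, id = NULL, flowlines, tol_km = 1) {
  n <- nrow(ceps$table)
  counts <- stats::setNames(integer(n), ceps$table$id)
  at <- flowlines$attrs
  if (n > 0L && !is.null(at$outlet_x) && any(!is.na(at$outlet_x))) {
    ox <- at$outlet_x[!is.na(at$outlet_x)]
    oy <- at$outlet_y[!is.na(at$outlet_x)]
    near <- nearest_feature(ceps$label > 0L)
    cs <- ceps$grid$cellsize
    rc <- grid_xy_cell(ceps$grid, ox, oy)
    for (p in seq_along(ox)) {
      if (is.na(rc[p, 1L])) next
      idx <- near[rc[p, 1L], rc[p, 2L]]
      if (is.na(idx)) next
      xy <- grid_cell_xy(ceps$grid, idx)
      d <- sqrt((xy[1L] - ox[p])^2 + (xy[2L] - oy[p])^2)
      if (d <= tol_km + cs / 2) {
        lb <- ceps$label[idx]
        counts[lb] <- counts[lb] + 1L
      }
    }
  }
  if (is.null(id)) counts else unname(counts[as.character(id)])
}

#' Flag delta embayments
#'
#' Two routes, mirroring the published procedure: a supplied list of known
#' deltas (the literature route) and the drainage-outlet rule — CEPs with
#' more than two outlets to the ocean are delta candidates, confirmed
#' through the review hook (a stand-in for visual assessment; the default
#' hook accepts every candidate).
#'
#' @param ceps a `cep_set`.
#' @param flowlines flowline layer.
#' @param known_delta_ids optional CEP ids asserted to be deltas; unknown
#'   ids raise a warning, not an error.
#' @param confirm optional function(ids) -> logical vector accepting or
#'   rejecting each outlet-rule candidate.
#' @param tol_km outlet snap tolerance.
#' @return list: `delta_ids`, `remaining_ids`, `outlet_counts`.
#' @export
flag_deltas <- function(ceps, flowlines, known_delta_ids = NULL,
                        confirm = NULL, tol_km = 1) {
  counts <- count_outlets(ceps, id = NULL, flowlines = flowlines,
                          tol_km = tol_km)
  ids <- ceps$table$id
  cand <- ids[counts > 2L]
  if (length(cand) && !is.null(confirm)) {
    ok <- confirm(cand)
    cand <- cand[ok]
  }
  listed <- integer(0)
  if (!is.null(known_delta_ids)) {
    missing <- setdiff(known_delta_ids, ids)
    if (length(missing))
      warning("listed delta ids not found: ", paste(missing, collapse = ", "))
    listed <- intersect(known_delta_ids, ids)
  }
  delta <- sort(union(listed, cand))
  list(delta_ids = delta, remaining_ids = setdiff(ids, delta),
       outlet_counts = counts)
}

#' Merge delta CEPs into delta units
#'
#' Delta extents (polygons) group several mouth CEPs of one river system
#' into a single unit; without extents every delta CEP is its own unit. A
#' CEP claimed by two extents goes to the larger overlap, with a warning.
#'
#' @param ceps a `cep_set`.
#' @param delta_ids CEP ids flagged as deltas.
#' @param extents optional polygon [vector_layer()] of delta extents.
#' @return data.frame (cep_id, unit_id).
#' @export
merge_delta_units <- function(ceps, delta_ids, extents = NULL) {
  if (length(delta_ids) == 0L)
    return(data.frame(cep_id = integer(0), unit_id = integer(0)))
  if (is.null(extents) || length(extents$geometry) == 0L)
    return(data.frame(cep_id = delta_ids,
                      unit_id = seq_along(delta_ids)))
  overlap <- matrix(0, length(delta_ids), length(extents$geometry))
  for (e in seq_along(extents$geometry)) {
    m <- rasterize_polygons(extents$geometry[[e]], ceps$grid)
    for (k in seq_along(delta_ids)) {
      cells <- ceps$cells[[match(delta_ids[k], ceps$table$id)]]
      overlap[k, e] <- sum(m[cells])
    }
  }
  unit <- integer(length(delta_ids))
  next_unit <- length(extents$geometry)
  for (k in seq_along(delta_ids)) {
    claims <- which(overlap[k, ] > 0)
    if (length(claims) == 0L) {
      next_unit <- next_unit + 1L
      unit[k] <- next_unit
    } else {
      if (length(claims) > 1L)
        warning("delta CEP ", delta_ids[k], " claimed by ", length(claims),
                " extents; assigned to the largest overlap")
      unit[k] <- claims[which.max(overlap[k, claims])]
    }
  }
  data.frame(cep_id = delta_ids, unit_id = unit)
}

#' Train the landform random forest
#'
#' Fits the bay/estuary/lagoon classifier on a labelled covariate table,
#' holding out a random fraction for validation. The published run used
#' 100,000 trees on 800 bays, 71 lagoons and 300 estuaries with a 20%
#' holdout and otherwise-default forest parameters; tree count is a knob
#' here because at toy scale a few hundred trees are statistically
#' indistinguishable. The forest implementation and settings are recorded
#' on the returned object for reproducibility.
#'
#' @param table data.frame with a `class` column plus the v1..v10
#'   covariates (see [covariate_table()]).
#' @param n_trees trees to grow (default the published 100,000).
#' @param holdout_fraction proportion held out for validation, in (0,1).
#' @param seed integer seed.
#' @return object of class `rf_run`: fitted model, training counts,
#'   validation accuracy and per-class recall.
#' @export
train_rf <- function(table, n_trees = 100000L, holdout_fraction = 0.2,
                     seed = 1L) {
  if (holdout_fraction <= 0 || holdout_fraction >= 1)
    stop("holdout_fraction must lie in (0, 1)")
  cls <- table$class
  cnt <- table(cls)
  if (length(cnt) < 2L) stop("need at least two classes to train")
  if (any(cnt < 2L))
    stop("class '", names(cnt)[which(cnt < 2L)[1L]],
         "' has fewer than 2 training rows")
  feats <- intersect(covariate_names(), colnames(table))
  if (length(feats) == 0L) stop("no covariate columns found")
  with_seed(seed, {
    n <- nrow(table)
    hold <- sample.int(n, max(1L, floor(n * holdout_fraction)))
    train <- setdiff(seq_len(n), hold)
    model <- rf_fit(table[train, feats, drop = FALSE], cls[train],
                    ntree = n_trees, seed = seed + 1L)
    pred <- predict(model, table[hold, , drop = FALSE])
    acc <- mean(pred$class == cls[hold])
    recall <- vapply(model$classes, function(cl) {
      pos <- cls[hold] == cl
      if (!any(pos)) NA_real_ else mean(pred$class[pos] == cl)
    }, numeric(1))
    structure(list(model = model, n_trees = as.integer(n_trees),
                   holdout_fraction = holdout_fraction,
                   seed = as.integer(seed),
                   training_counts = as.list(cnt),
                   validation_accuracy = acc,
                   per_class_recall = recall,
                   features = feats,
                   implementation = model$implementation),
              class = "rf_run")
  })
}

#' @export
print.rf_run <- function(x, ...) {
  cat("<rf_run> ", x$n_trees, " trees (", x$implementation, ")\n", sep = "")
  cat("  training counts:",
      paste(names(x$training_counts), unlist(x$training_counts),
            sep = "=", collapse = ", "), "\n")
  cat("  validation accuracy:", round(x$validation_accuracy, 3), "\n")
  invisible(x)
}

#' Classify embayments with a fitted forest run
#'
#' Every row receives a class in the model's vocabulary plus vote
#' fractions. Exact vote ties break by class priority bay > estuary >
#' lagoon (bays are the modal class of the training composition).
#'
#' @param run an [train_rf()] result.
#' @param table covariate table with `cep_id` and the training columns.
#' @return data.frame (cep_id, class, vote_* columns).
#' @export
classify_ceps <- function(run, table) {
  priority <- intersect(c("bay", "estuary", "lagoon"), run$model$classes)
  priority <- c(priority, setdiff(run$model$classes, priority))
  pred <- predict(run$model, table, tie_break = priority)
  cbind(data.frame(cep_id = if (!is.null(table$cep_id)) table$cep_id
                   else seq_len(nrow(table))), pred)
}

#' Mechanised review hook
#'
#' Stand-in for visual inspection: returns the truth label for each
#' flagged CEP, independently flipped to a random *different* class with
#' probability `error_rate`. With two classes and `error_rate = 1` this is
#' the complement of the truth.
#'
#' @param ids CEP ids under review.
#' @param truth named character vector of true classes (names = ids);
#'   required (synthetic mode).
#' @param error_rate flip probability in \[0, 1\].
#' @param seed integer seed.
#' @param classes class vocabulary for flips; defaults to the classes seen
#'   in `truth`.
#' @return data.frame (cep_id, class).
#' @export
review_hook <- function(ids, truth, error_rate = 0, seed = 1L,
                        classes = sort(unique(truth))) {
  if (missing(truth) || is.null(truth))
    stop("review_hook requires truth labels in synthetic mode")
  lab <- truth[as.character(ids)]
  if (anyNA(lab)) stop("truth labels missing for some reviewed ids")
  with_seed(seed, {
    flip <- stats::runif(length(ids)) < error_rate
    for (k in which(flip)) {
      others <- setdiff(classes, lab[k])
      lab[k] <- others[sample.int(length(others), 1L)]
    }
    data.frame(cep_id = ids, class = unname(lab), stringsAsFactors = FALSE)
  })
}

#' Second-pass classification with review corrections
#'
#' Retrains on the original training table plus the reviewed-and-corrected
#' CEPs, re-predicts the not-reviewed (bay-labelled) pool, flags
#' disagreements between the two passes and routes them through the review
#' hook. Every CEP ends with a final label and a provenance tag
#' (`review`, `pass1` for two-pass agreement, `pass2` otherwise).
#'
#' @param run1 first-pass [train_rf()] result.
#' @param training the original labelled training table.
#' @param corrections data.frame (cep_id, class) from the review hook.
#' @param pool covariate table of all CEPs classified in pass 1.
#' @param labels1 data.frame (cep_id, class) of first-pass labels on the
#'   pool.
#' @param n_trees2 trees for the second forest (published: 75,000).
#' @param seed integer seed.
#' @param review optional function(ids) -> data.frame(cep_id, class) used
#'   on disagreements; when absent, the second-pass label stands and the
#'   CEP is flagged.
#' @return data.frame (cep_id, class, provenance, flagged).
#' @export
second_pass <- function(run1, training, corrections, pool, labels1,
                        n_trees2 = 75000L, seed = 1L, review = NULL) {
  feats <- run1$features
  if (is.null(corrections) || nrow(corrections) == 0L) {
    warning("empty corrections set; second pass retrains on pass-1 data only")
    corrections <- data.frame(cep_id = integer(0), class = character(0))
  }
  corr_rows <- pool[match(corrections$cep_id, pool$cep_id), , drop = FALSE]
  corr_rows$class <- corrections$class
  train2 <- rbind(training[, c("class", feats)],
                  corr_rows[, c("class", feats)])
  model2 <- rf_fit(train2[, feats, drop = FALSE], train2$class,
                   ntree = n_trees2, seed = seed)
  remaining <- pool[!(pool$cep_id %in% corrections$cep_id), , drop = FALSE]
  out <- data.frame(cep_id = corrections$cep_id, class = corrections$class,
                    provenance = rep("review", nrow(corrections)),
                    flagged = rep(FALSE, nrow(corrections)),
                    stringsAsFactors = FALSE)
  if (nrow(remaining)) {
    priority <- intersect(c("bay", "estuary", "lagoon"), model2$classes)
    priority <- c(priority, setdiff(model2$classes, priority))
    p2 <- predict(model2, remaining, tie_break = priority)$class
    p1 <- labels1$class[match(remaining$cep_id, labels1$cep_id)]
    agree <- !is.na(p1) & p1 == p2
    res <- data.frame(cep_id = remaining$cep_id, class = p2,
                      provenance = ifelse(agree, "pass1", "pass2"),
                      flagged = !agree, stringsAsFactors = FALSE)
    if (any(!agree) && !is.null(review)) {
      fixed <- review(res$cep_id[!agree])
      res$class[!agree] <- fixed$class[match(res$cep_id[!agree],
                                             fixed$cep_id)]
      res$provenance[!agree] <- "review"
    }
    out <- rbind(out, res)
  }
  rownames(out) <- NULL
  out
}
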