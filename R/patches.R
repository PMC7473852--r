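cep_class_to_type <- function(cls) {
  map <- c(delta = "deltaic", estuary = "estuarine",
           lagoon = "lagoonal", bay = "open_coast")
  unname(map[cls])
}

#' Extract mangrove patches from the maximal extent
#'
#' Connected components (8-connectivity, so diagonal fringe cells stay in
#' one patch) of the union mangrove mask.
#'
#' @param extent_union logical mask of the maximal extent.
#' @param grid an [mt_grid()].
#' @return object of class `patch_set`: grid, label matrix, cells list and
#'   a table (patch_id, n_cells, area_km2).
#' @export
extract_patches <- function(extent_union, grid) {
  lab <- label_components(extent_union, diagonal = TRUE)
  n <- max(lab)
  cells <- if (n > 0L) unname(split(which(lab > 0L), lab[lab > 0L])) else list()
  structure(list(grid = grid, label = lab, cells = cells,
                 table = data.frame(patch_id = seq_len(n),
                                    n_cells = lengths(cells),
                                    area_km2 = lengths(cells) * grid$cellsize^2)),
            class = "patch_set")
}

# CEP labels within `reach` cells of each patch (adjacency = intersecting)
patch_cep_touch <- function(patches, ceps, reach = 1.5) {
  if (nrow(ceps$table) == 0L)
    return(replicate(length(patches$cells), integer(0), simplify = FALSE))
  near <- nearest_feature(ceps$label > 0L)
  nr <- patches$grid$nrow
  lapply(patches$cells, function(ck) {
    ni <- near[ck]
    i <- ((ck - 1L) %% nr); j <- ((ck - 1L) %/% nr)
    i2 <- ((ni - 1L) %% nr); j2 <- ((ni - 1L) %/% nr)
    d <- sqrt((i - i2)^2 + (j - j2)^2)
    sort(unique(ceps$label[ni[d <= reach]]))
  })
}

#' Split patches straddling several embayments
#'
#' Ensures no patch intersects more than one CEP: straddling patches are
#' cut along the Euclidean allocation boundary between the competing CEPs
#' (every cell goes to its nearest competitor). Total mangrove area is
#' conserved exactly — cells are partitioned, never duplicated.
#'
#' @param patches a `patch_set`.
#' @param ceps a classified `cep_set`.
#' @return a new `patch_set` with an added `parent_id` table column.
#' @export
split_patches <- function(patches, ceps) {
  touch <- patch_cep_touch(patches, ceps)
  lab <- matrix(0L, patches$grid$nrow, patches$grid$ncol)
  cells_out <- list(); parent <- integer(0)
  nxt <- 0L
  for (p in seq_along(patches$cells)) {
    ck <- patches$cells[[p]]
    tp <- touch[[p]]
    if (length(tp) <= 1L) {
      nxt <- nxt + 1L
      lab[ck] <- nxt
      cells_out[[nxt]] <- ck
      parent[nxt] <- p
      next
    }
    sites <- matrix(FALSE, patches$grid$nrow, patches$grid$ncol)
    for (t in tp) sites[ceps$cells[[match(t, ceps$table$id)]]] <- TRUE
    near <- nearest_feature(sites)
    owner <- ceps$label[near[ck]]
    for (t in tp) {
      sub <- ck[owner == t]
      if (length(sub) == 0L) next
      nxt <- nxt + 1L
      lab[sub] <- nxt
      cells_out[[nxt]] <- sub
      parent[nxt] <- p
    }
  }
  structure(list(grid = patches$grid, label = lab, cells = cells_out,
                 table = data.frame(patch_id = seq_len(nxt),
                                    n_cells = lengths(cells_out),
                                    area_km2 = lengths(cells_out) *
                                      patches$grid$cellsize^2,
                                    parent_id = parent)),
            class = "patch_set")
}

#' Assign patches that directly intersect a CEP
#'
#' Delta CEPs give deltaic units, estuary CEPs estuarine, lagoon CEPs
#' lagoonal; bay CEPs give open-coast units (open-coast mangroves are
#' those associated with bays or with no embayment at all). Zero-area
#' touching only counts as intersecting at the raster adjacency used by
#' [split_patches()].
#'
#' @param patches a post-split `patch_set`.
#' @param ceps a `cep_set` whose table carries final classes.
#' @return data.frame (patch_id, cep_id, type, method), NA rows for
#'   patches touching no CEP.
#' @export
assign_direct <- function(patches, ceps) {
  touch <- patch_cep_touch(patches, ceps)
  if (any(lengths(touch) > 1L))
    stop("internal error: patch intersects several CEPs after splitting")
  cep_id <- vapply(touch, function(t)
    if (length(t)) ceps$table$id[match(t, ceps$table$id)] else NA_integer_,
    integer(1))
  cls <- ceps$table$class[match(cep_id, ceps$table$id)]
  data.frame(patch_id = patches$table$patch_id,
             cep_id = cep_id,
             type = ifelse(is.na(cep_id), NA_character_,
                           cep_class_to_type(cls)),
             method = ifelse(is.na(cep_id), NA_character_, "direct"),
             stringsAsFactors = FALSE)
}

#' Assign orphan patches via catchments and distance
#'
#' Patches with no direct CEP contact inherit the type of the nearest CEP
#' whose catchment contains them; failing that, the nearest CEP within
#' `max_dist_km`; failing that they are open-coast with no CEP. Distance
#' ties prefer a catchment-sharing CEP, then the lower CEP id.
#'
#' @param assignments output of [assign_direct()].
#' @param patches a `patch_set`.
#' @param ceps a classified `cep_set`.
#' @param catchments list of [build_catchment()] results indexed like
#'   `ceps$table$id` (may be NULL: distance-only assignment).
#' @param max_dist_km fallback search radius.
#' @return updated assignments (method `catchment`, `distance` or
#'   `fallback`).
#' @export
assign_orphans <- function(assignments, patches, ceps, catchments = NULL,
                           max_dist_km = 20) {
  todo <- which(is.na(assignments$type))
  if (length(todo) == 0L) return(assignments)
  grid <- patches$grid
  cs <- grid$cellsize
  catch_mask <- NULL
  if (!is.null(catchments) && nrow(ceps$table) > 0L) {
    catch_mask <- lapply(catchments, function(ct) {
      if (is.null(ct) || length(ct$geometry) == 0L) return(NULL)
      m <- matrix(FALSE, grid$nrow, grid$ncol)
      for (g in ct$geometry) m <- m | rasterize_polygons(g, grid)
      m
    })
  }
  dist_to_cep <- list()
  cep_dist <- function(k) {
    key <- as.character(k)
    if (is.null(dist_to_cep[[key]])) {
      m <- matrix(FALSE, grid$nrow, grid$ncol)
      m[ceps$cells[[k]]] <- TRUE
      dist_to_cep[[key]] <<- distance_transform(m, cs)
    }
    dist_to_cep[[key]]
  }
  for (p in todo) {
    ck <- patches$cells[[p]]
    chosen <- NA_integer_; method <- "fallback"
    if (nrow(ceps$table) > 0L) {
      containing <- integer(0)
      if (!is.null(catch_mask)) {
        containing <- which(vapply(seq_along(catch_mask), function(k) {
          m <- catch_mask[[k]]
          !is.null(m) && mean(m[ck]) > 0.5
        }, logical(1)))
      }
      if (length(containing)) {
        d <- vapply(containing, function(k) min(cep_dist(k)[ck]), numeric(1))
        best <- d <= min(d) + 1e-9
        chosen <- ceps$table$id[containing[best][order(containing[best])][1L]]
        method <- "catchment"
      } else {
        d <- vapply(seq_len(nrow(ceps$table)), function(k)
          min(cep_dist(k)[ck]), numeric(1))
        ok <- which(d <= max_dist_km)
        if (length(ok)) {
          best <- ok[d[ok] <= min(d[ok]) + 1e-9]
          # tie-break: catchment-sharing CEP first, then lower id
          if (length(best) > 1L && !is.null(catch_mask)) {
            shares <- vapply(best, function(k) {
              m <- catch_mask[[k]]
              !is.null(m) && mean(m[ck]) > 0.5
            }, logical(1))
            if (any(shares)) best <- best[shares]
          }
          chosen <- ceps$table$id[min(best)]
          method <- "distance"
        }
      }
    }
    if (is.na(chosen)) {
      assignments$type[p] <- "open_coast"
      assignments$method[p] <- "fallback"
    } else {
      assignments$cep_id[p] <- chosen
      assignments$type[p] <-
        cep_class_to_type(ceps$table$class[match(chosen, ceps$table$id)])
      assignments$method[p] <- method
    }
  }
  assignments
}

#' Finalize typological units
#'
#' Merges same-type patches sharing a CEP (and delta CEPs sharing a delta
#' unit) into typological units, computes per-timestep areas by
#' intersection with each extent mask, and assigns each unit to the region
#' holding the majority of its area.
#'
#' @param assignments completed patch assignments (no NA types).
#' @param patches the `patch_set` the assignments refer to.
#' @param extents named list of logical extent masks per timestep.
#' @param regions optional polygon [vector_layer()] with a `region`
#'   attribute column.
#' @param delta_units optional data.frame (cep_id, unit_id) from
#'   [merge_delta_units()].
#' @return object of class `typology_units`: grid, label matrix, cells,
#'   and a table with unit_id, type, cep_id, region, n_cells and one
#'   `area_<timestep>` column per timestep.
#' @export
finalize_units <- function(assignments, patches, extents, regions = NULL,
                           delta_units = NULL) {
  if (anyNA(assignments$type))
    stop("unassigned patch remains: ",
         assignments$patch_id[which(is.na(assignments$type))[1L]])
  grid <- patches$grid
  cs <- grid$cellsize
  key <- ifelse(is.na(assignments$cep_id),
                paste0("orphan_", assignments$patch_id),
                paste0("cep_", assignments$cep_id))
  if (!is.null(delta_units) && nrow(delta_units)) {
    du <- match(assignments$cep_id, delta_units$cep_id)
    key[!is.na(du)] <- paste0("delta_", delta_units$unit_id[du[!is.na(du)]])
  }
  key <- paste(assignments$type, key, sep = "|")
  groups <- split(seq_len(nrow(assignments)), key)
  n <- length(groups)
  lab <- matrix(0L, grid$nrow, grid$ncol)
  cells <- vector("list", n)
  tab <- data.frame(unit_id = seq_len(n),
                    type = rep(NA_character_, n),
                    cep_id = rep(NA_integer_, n),
                    region = rep(NA_character_, n),
                    n_cells = rep(0L, n),
                    stringsAsFactors = FALSE)
  region_lab <- NULL; region_names <- NULL
  if (!is.null(regions) && length(regions$geometry)) {
    region_lab <- rasterize_polygons(regions, grid)
    region_names <- if (!is.null(regions$attrs$region)) regions$attrs$region
                    else paste0("region_", seq_along(regions$geometry))
  }
  ts_names <- names(extents)
  for (tsn in ts_names) tab[[paste0("area_", tsn)]] <- 0
  for (u in seq_len(n)) {
    rows <- groups[[u]]
    ck <- sort(unique(unlist(patches$cells[assignments$patch_id[rows]])))
    cells[[u]] <- ck
    lab[ck] <- u
    tab$type[u] <- assignments$type[rows[1L]]
    tab$cep_id[u] <- assignments$cep_id[rows[1L]]
    tab$n_cells[u] <- length(ck)
    for (tsn in ts_names)
      tab[[paste0("area_", tsn)]][u] <- sum(extents[[tsn]][ck]) * cs^2
    if (!is.null(region_lab)) {
      r <- region_lab[ck]
      r <- r[r > 0L]
      tab$region[u] <- if (length(r))
        region_names[as.integer(names(sort(table(r), decreasing = TRUE))[1L])]
      else NA_character_
    }
  }
  structure(list(grid = grid, label = lab, cells = cells, table = tab,
                 timesteps = ts_names),
            class = "typology_units")
}

#' @export
print.typology_units <- function(x, ...) {
  cat("<typology_units> ", nrow(x$table), " unit(s); types: ",
      paste(names(table(x$table$type)), table(x$table$type),
            sep = "=", collapse = ", "), "\n", sep = "")
  invisible(x)
}

# representative point: unit cell nearest the unit centroid
unit_rep_point <- function(units, u) {
  ck <- units$cells[[u]]
  xy <- grid_cell_xy(units$grid, ck)
  ctr <- colMeans(xy)
  d2 <- (xy[, 1L] - ctr[1L])^2 + (xy[, 2L] - ctr[2L])^2
  xy[which.min(d2), ]
}
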