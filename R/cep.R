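#' Generalize a coastline by morphological closing
#'
#' Dilates the land by `closing_radius` km and erodes it back, sealing
#' indents (embayments, channels, lagoons) narrower than the structuring
#' disc while leaving straight or convex coast unchanged. The generalized
#' land always contains the original land.
#'
#' @param land logical land mask, or a `coast_scene`.
#' @param closing_radius disc radius in km (> 0). Default 10 km targets
#'   macroscale embayments.
#' @param grid an [mt_grid()] (taken from the scene when given one).
#' @return logical generalized land mask.
#' @export
generalize_coastline <- function(land, closing_radius = 10, grid = NULL) {
  if (inherits(land, "coast_scene")) {
    grid <- land$grid
    land <- land$land
  }
  if (is.null(grid)) stop("grid required for a bare mask")
  if (closing_radius <= 0) stop("closing_radius must be > 0")
  close_mask(land, closing_radius, grid$cellsize)
}

#' Extract coastal embayment polygons (CEPs)
#'
#' CEPs are the connected components (4-connectivity at the working
#' resolution) of generalized-minus-actual land: water sealed off by the
#' coastline closing, i.e. indents in the coast. Channels narrower than the
#' cell size separate naturally into distinct CEPs, each keeping the mouth
#' segment nearest to it. Every CEP records its mouth (cells adjacent to
#' open sea), mouth length and width, and whether it touches the domain
#' edge.
#'
#' @param land logical land mask or `coast_scene`.
#' @param generalized output of [generalize_coastline()] on the same land.
#' @param grid an [mt_grid()] (from the scene when given one).
#' @param min_area_km2 smallest indent retained.
#' @return Object of class `cep_set`: grid, integer label matrix, a table
#'   (id, n_cells, area_km2, mouth_length_km, mouth_width_km, edge, class),
#'   and per-CEP cell/mouth-cell indices.
#' @export
extract_embayments <- function(land, generalized, grid = NULL,
                               min_area_km2 = 1) {
  if (inherits(land, "coast_scene")) {
    grid <- land$grid
    land <- land$land
  }
  if (is.null(grid)) stop("grid required for a bare mask")
  cs <- grid$cellsize
  indent <- generalized & !land
  lab <- label_components(indent, diagonal = FALSE)
  nlab <- max(lab)
  empty <- cep_set_empty(grid)
  if (nlab == 0L) return(empty)
  sizes <- tabulate(lab[lab > 0L], nlab)
  keep <- which(sizes * cs^2 >= min_area_km2)
  if (length(keep) == 0L) return(empty)
  relab <- integer(nlab); relab[keep] <- seq_along(keep)
  newlab <- matrix(0L, grid$nrow, grid$ncol)
  pos <- lab > 0L
  newlab[pos] <- relab[lab[pos]]
  lab <- newlab
  n <- length(keep)

  open_sea <- !generalized
  # mouth cells: indent cells 4-adjacent to open sea; count exposed edges
  shift <- function(m, di, dj) {
    out <- matrix(FALSE, nrow(m), ncol(m))
    i1 <- max(1, 1 + di):min(nrow(m), nrow(m) + di)
    j1 <- max(1, 1 + dj):min(ncol(m), ncol(m) + dj)
    out[i1, j1] <- m[i1 - di, j1 - dj]
    out
  }
  mouth_edges <- (lab > 0L) *
    (shift(open_sea, 1, 0) + shift(open_sea, -1, 0) +
       shift(open_sea, 0, 1) + shift(open_sea, 0, -1))
  mouth_mask <- mouth_edges > 0
  mouth_lab <- label_components(mouth_mask, diagonal = TRUE)

  cells <- split(which(lab > 0L), lab[lab > 0L])
  mouth_cells <- lapply(seq_len(n), function(k) {
    ck <- cells[[k]]
    ck[mouth_mask[ck]]
  })
  seg_width <- function(idx) {
    if (length(idx) == 0L) return(0)
    segs <- split(idx, mouth_lab[idx])
    w <- vapply(segs, function(s) {
      if (length(s) == 1L) return(cs)
      pts <- grid_cell_xy(grid, s)
      h <- grDevices::chull(pts)
      hp <- pts[h, , drop = FALSE]
      max(stats::dist(hp)) + cs
    }, numeric(1))
    max(w)
  }
  on_edge <- function(idx) {
    i <- ((idx - 1L) %% grid$nrow) + 1L
    j <- ((idx - 1L) %/% grid$nrow) + 1L
    any(i == 1L | i == grid$nrow | j == 1L | j == grid$ncol)
  }
  tab <- data.frame(
    id = seq_len(n),
    n_cells = lengths(cells),
    area_km2 = lengths(cells) * cs^2,
    mouth_length_km = vapply(seq_len(n), function(k)
      sum(mouth_edges[mouth_cells[[k]]]) * cs, numeric(1)),
    mouth_width_km = vapply(mouth_cells, seg_width, numeric(1)),
    edge = vapply(cells, on_edge, logical(1)),
    class = "unassigned",
    stringsAsFactors = FALSE)
  rownames(tab) <- NULL
  structure(list(grid = grid, label = lab, table = tab,
                 cells = unname(cells), mouth_cells = mouth_cells),
            class = "cep_set")
}

cep_set_empty <- function(grid) {
  structure(list(grid = grid,
                 label = matrix(0L, grid$nrow, grid$ncol),
                 table = data.frame(id = integer(0), n_cells = integer(0),
                                    area_km2 = numeric(0),
                                    mouth_length_km = numeric(0),
                                    mouth_width_km = numeric(0),
                                    edge = logical(0), class = character(0),
                                    stringsAsFactors = FALSE),
                 cells = list(), mouth_cells = list()),
            class = "cep_set")
}

#' @export
print.cep_set <- function(x, ...) {
  cat("<cep_set> ", nrow(x$table), " embayment(s)\n", sep = "")
  if (nrow(x$table)) print(utils::head(x$table, 10L))
  invisible(x)
}

# subset a cep_set to a vector of ids, renumbering 1..n
cep_subset <- function(ceps, ids) {
  keep <- match(ids, ceps$table$id)
  keep <- keep[!is.na(keep)]
  relab <- integer(max(ceps$table$id, 1L))
  relab[ceps$table$id[keep]] <- seq_along(keep)
  lab <- ceps$label
  pos <- lab > 0L
  lab[pos] <- ifelse(lab[pos] %in% ceps$table$id[keep], relab[lab[pos]], 0L)
  tab <- ceps$table[keep, , drop = FALSE]
  old_id <- tab$id
  tab$id <- seq_along(keep)
  rownames(tab) <- NULL
  tab$source_id <- old_id
  structure(list(grid = ceps$grid, label = lab, table = tab,
                 cells = ceps$cells[keep],
                 mouth_cells = ceps$mouth_cells[keep]),
            class = "cep_set")
}

#' Filter CEPs by landmass size and distance to mangrove
#'
#' Retains embayments on landmasses of at least `min_landmass_km2` and
#' within `max_dist_km` of the mangrove maximal extent; both thresholds
#' mirror the selection rule of the global analysis (30 km^2, 20 km).
#' Landmass and distance are recorded on the returned table.
#'
#' @param ceps a `cep_set`.
#' @param land logical land mask or `coast_scene`.
#' @param mangrove_union logical mask of the maximal mangrove extent.
#' @param min_landmass_km2,max_dist_km filter thresholds.
#' @return filtered `cep_set` (ids renumbered; original id kept as
#'   `source_id`).
#' @export
filter_ceps <- function(ceps, land, mangrove_union,
                        min_landmass_km2 = 30, max_dist_km = 20) {
  if (inherits(land, "coast_scene")) land <- land$land
  if (is.null(mangrove_union)) stop("missing mangrove extent layer")
  grid <- ceps$grid
  cs <- grid$cellsize
  if (nrow(ceps$table) == 0L) return(ceps)
  lm_lab <- label_components(land, diagonal = FALSE)
  lm_area <- tabulate(lm_lab[lm_lab > 0L]) * cs^2
  near_land <- allocate_nearest(lm_lab)
  dmang <- distance_transform(mangrove_union, cs)
  landmass <- numeric(nrow(ceps$table))
  dist_m <- numeric(nrow(ceps$table))
  for (k in seq_len(nrow(ceps$table))) {
    ck <- ceps$cells[[k]]
    lm <- near_land[ck]
    lm <- lm[lm > 0L]
    landmass[k] <- if (length(lm)) lm_area[as.integer(names(
      sort(table(lm), decreasing = TRUE))[1L])] else 0
    dist_m[k] <- min(dmang[ck])
  }
  ceps$table$landmass_km2 <- landmass
  ceps$table$dist_to_mangrove_km <- dist_m
  keep <- ceps$table$id[landmass >= min_landmass_km2 & dist_m <= max_dist_km]
  out <- cep_subset(ceps, keep)
  out
}

#' Export a CEP set as a polygon layer
#'
#' Traces each embayment's cells into boundary polygons and attaches the
#' CEP attribute table, ready for [write_vector()].
#'
#' @param ceps a `cep_set`.
#' @return polygon [vector_layer()].
#' @export
cep_to_layer <- function(ceps) {
  geoms <- lapply(seq_len(nrow(ceps$table)), function(k) {
    m <- matrix(FALSE, ceps$grid$nrow, ceps$grid$ncol)
    m[ceps$cells[[k]]] <- TRUE
    trace_mask(m, ceps$grid)
  })
  vector_layer(geoms, ceps$table, "polygon")
}

#' Match extracted CEPs against planted truth embayments
#'
#' Greedy one-to-one matching by intersection-over-union between CEP cells
#' and the planted indent cells of a synthetic scene.
#'
#' @param ceps a `cep_set`.
#' @param scene a `coast_scene` with truth.
#' @param min_iou IoU threshold counting as a match.
#' @return data.frame (truth_id, class, cep_id, iou, matched).
#' @export
match_truth_embayments <- function(ceps, scene, min_iou = 0.5) {
  emb <- scene$truth$embayments
  out <- data.frame(truth_id = emb$id, class = emb$class,
                    cep_id = NA_integer_, iou = 0, matched = FALSE,
                    stringsAsFactors = FALSE)
  if (nrow(emb) == 0L || nrow(ceps$table) == 0L) return(out)
  truth_cells <- lapply(emb$id, function(e) which(scene$truth$emb_mask == e))
  iou <- matrix(0, nrow(emb), nrow(ceps$table))
  for (a in seq_len(nrow(emb))) {
    for (b in seq_len(nrow(ceps$table))) {
      inter <- length(intersect(truth_cells[[a]], ceps$cells[[b]]))
      if (inter == 0L) next
      uni <- length(truth_cells[[a]]) + length(ceps$cells[[b]]) - inter
      iou[a, b] <- inter / uni
    }
  }
  taken <- rep(FALSE, nrow(ceps$table))
  repeat {
    best <- which(iou == max(iou), arr.ind = TRUE)
    if (max(iou) < min_iou) break
    a <- best[1L, 1L]; b <- best[1L, 2L]
    out$cep_id[a] <- ceps$table$id[b]
    out$iou[a] <- iou[a, b]
    out$matched[a] <- TRUE
    taken[b] <- TRUE
    iou[a, ] <- -1; iou[, b] <- -1
  }
  out
}
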