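#' Construct a polygon CEP for closed-form shape work
#'
#' Wraps an explicit polygon geometry and mouth polyline so shape metrics
#' can be computed on exact geometry (used for analytic checks and for
#' externally supplied embayment polygons).
#'
#' @param geometry polygon geometry (ring matrix, or nested ring lists).
#' @param mouth n x 2 polyline matrix along the embayment mouth.
#' @return object of class `cep_polygon`.
#' @export
cep_polygon <- function(geometry, mouth) {
  structure(list(geometry = geometry, mouth = mouth), class = "cep_polygon")
}

#' Shape covariates of an embayment
#'
#' The six shape descriptors used for landform classification:
#' * `v1_area_km2` polygon area;
#' * `v2_perimeter_km` boundary length;
#' * `v3_compactness` 4 * pi * A / P^2 (1 for a circle, small for slivers);
#' * `v4_mouth_width_km` mouth polyline length;
#' * `v5_elongation` minimum-area bounding rectangle length / width;
#' * `v6_closure_ratio` mouth extent / bounding-rectangle width (small for
#'   choked lagoons, around or above 1 for open bays).
#'
#' For raster-backed `cep_set`s the same quantities are computed from cell
#' counts, exposed cell edges and cell-corner hulls, so perimeter-based
#' metrics carry the usual staircase bias; they are self-consistent across
#' a scene, which is what the classifier needs.
#'
#' @param x a `cep_polygon` or a `cep_set`.
#' @param ... unused.
#' @return one-row (or per-CEP) data.frame of v1..v6.
#' @export
shape_metrics <- function(x, ...) UseMethod("shape_metrics")

#' @export
shape_metrics.cep_polygon <- function(x, ...) {
  if (is.null(x$mouth)) stop("CEP malformed upstream: mouth missing")
  A <- area_km2(x$geometry)
  rings <- unlist(flatten_rings(x$geometry), recursive = FALSE)
  P <- sum(vapply(rings, function(r) polyline_length_km(close_ring(r)),
                  numeric(1)))
  pts <- do.call(rbind, rings)
  mabr <- min_area_rect(pts)
  v4 <- polyline_length_km(x$mouth)
  mouth_w <- if (nrow(x$mouth) >= 2L) max(stats::dist(x$mouth)) else 0
  data.frame(
    v1_area_km2 = A,
    v2_perimeter_km = P,
    v3_compactness = if (P > 0) 4 * pi * A / P^2 else 0,
    v4_mouth_width_km = v4,
    v5_elongation = if (mabr$width > 0) mabr$length / mabr$width else Inf,
    v6_closure_ratio = if (mabr$width > 0) mouth_w / mabr$width else Inf)
}

#' @export
shape_metrics.cep_set <- function(x, ...) {
  n <- nrow(x$table)
  cs <- x$grid$cellsize
  if (n == 0L)
    return(cbind(data.frame(cep_id = integer(0)), shape_metrics_empty()))
  edges <- boundary_edges_cpp(x$label, n)
  rows <- lapply(seq_len(n), function(k) {
    A <- x$table$area_km2[k]
    P <- edges[k] * cs
    corners <- cell_corner_points(x$grid, x$cells[[k]])
    mabr <- min_area_rect(corners)
    mouth_w <- x$table$mouth_width_km[k]
    data.frame(
      v1_area_km2 = A, v2_perimeter_km = P,
      v3_compactness = if (P > 0) 4 * pi * A / P^2 else 0,
      v4_mouth_width_km = x$table$mouth_length_km[k],
      v5_elongation = if (mabr$width > 0) mabr$length / mabr$width else Inf,
      v6_closure_ratio = if (mabr$width > 0) mouth_w / mabr$width else 0)
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (is.null(out)) out <- shape_metrics_empty()
  cbind(data.frame(cep_id = x$table$id), out)
}

shape_metrics_empty <- function() {
  data.frame(v1_area_km2 = numeric(0), v2_perimeter_km = numeric(0),
             v3_compactness = numeric(0), v4_mouth_width_km = numeric(0),
             v5_elongation = numeric(0), v6_closure_ratio = numeric(0))
}

# densify a polyline to at most `step` km between consecutive points
densify_line <- function(m, step) {
  out <- list(m[1L, , drop = FALSE])
  for (s in seq_len(nrow(m) - 1L)) {
    a <- m[s, ]; b <- m[s + 1L, ]
    L <- sqrt(sum((b - a)^2))
    k <- max(1L, ceiling(L / step))
    t <- seq_len(k) / k
    out[[length(out) + 1L]] <- cbind(a[1L] + t * (b[1L] - a[1L]),
                                     a[2L] + t * (b[2L] - a[2L]))
  }
  do.call(rbind, out)
}

# which CEP (label id) each flowline touches; a flowline may touch several
flowline_cep_hits <- function(ceps, flowlines) {
  hits <- vector("list", length(flowlines$geometry))
  cs <- ceps$grid$cellsize
  for (f in seq_along(flowlines$geometry)) {
    pts <- densify_line(flowlines$geometry[[f]], cs / 2)
    rc <- grid_xy_cell(ceps$grid, pts[, 1L], pts[, 2L])
    rc <- rc[stats::complete.cases(rc), , drop = FALSE]
    if (nrow(rc) == 0L) { hits[[f]] <- integer(0); next }
    labs <- ceps$label[rc]
    hits[[f]] <- sort(unique(labs[labs > 0L]))
  }
  hits
}

# upstream closure over downstream pointers; errors on dangling ids
upstream_closure <- function(flow_attrs, start_ids) {
  ids <- flow_attrs$id
  down <- flow_attrs$downstream_id
  dangling <- which(!is.na(down) & !(down %in% ids))
  if (length(dangling))
    stop("topology error: flowline ", ids[dangling[1L]],
         " has dangling downstream pointer ", down[dangling[1L]])
  out <- start_ids
  frontier <- start_ids
  while (length(frontier)) {
    ups <- ids[!is.na(down) & down %in% frontier]
    ups <- setdiff(ups, out)
    out <- c(out, ups)
    frontier <- ups
  }
  sort(out)
}

#' Build the upstream catchment of a CEP
#'
#' Aggregates the watershed polygons of every river flowline that
#' intersects the embayment, plus all watersheds upstream of those
#' flowlines (whole polygons, never clipped; shared watersheds counted
#' once). `n_flowlines` counts the distinct flowlines touching the CEP.
#'
#' @param ceps a `cep_set`.
#' @param id CEP id.
#' @param flowlines polyline [vector_layer()] with attributes `id`,
#'   `downstream_id` (NA at terminal outlets).
#' @param watersheds polygon [vector_layer()] with attributes `ws_id`,
#'   `flowline_id`.
#' @param hits optional precomputed [flowline_cep_hits()] result.
#' @return list (class `catchment`): cep_id, flowline_ids, n_flowlines,
#'   ws_ids, area_km2, geometry (list of polygons).
#' @export
build_catchment <- function(ceps, id, flowlines, watersheds, hits = NULL) {
  if (is.null(hits)) hits <- flowline_cep_hits(ceps, flowlines)
  touching <- which(vapply(hits, function(h) id %in% h, logical(1)))
  fl_ids <- if (length(touching)) flowlines$attrs$id[touching] else integer(0)
  if (length(fl_ids) == 0L) {
    return(structure(list(cep_id = id, flowline_ids = integer(0),
                          n_flowlines = 0L, ws_ids = integer(0),
                          area_km2 = 0, geometry = list()),
                     class = "catchment"))
  }
  closure <- upstream_closure(flowlines$attrs, fl_ids)
  sel <- which(watersheds$attrs$flowline_id %in% closure)
  ws_ids <- unique(watersheds$attrs$ws_id[sel])
  sel <- sel[!duplicated(watersheds$attrs$ws_id[sel])]
  geoms <- watersheds$geometry[sel]
  structure(list(cep_id = id, flowline_ids = fl_ids,
                 n_flowlines = length(fl_ids), ws_ids = ws_ids,
                 area_km2 = sum(vapply(geoms, area_km2, numeric(1))),
                 geometry = geoms),
            class = "catchment")
}

#' Route monthly precipitation through a catchment to its CEP
#'
#' Catchment-masked mean of each of the 12 monthly bands; annual total is
#' their sum and seasonality the max/mean ratio. Nodata cells never enter
#' the means. An empty catchment routes nothing: `(0, 0)`.
#'
#' @param catchment a [build_catchment()] result.
#' @param precip 12-band [raster_field()] of monthly precipitation (mm).
#' @return named numeric `c(annual_mm, seasonality)`.
#' @export
route_precipitation <- function(catchment, precip) {
  if (rf_nbands(precip) != 12L)
    stop("precipitation raster must have 12 monthly bands, got ",
         rf_nbands(precip))
  if (length(catchment$geometry) == 0L)
    return(c(annual_mm = 0, seasonality = 0))
  mask <- matrix(FALSE, precip$grid$nrow, precip$grid$ncol)
  for (g in catchment$geometry) mask <- mask | rasterize_polygons(g, precip$grid)
  monthly <- vapply(1:12, function(b) {
    v <- rf_band(precip, b)
    ok <- mask & !is.na(v) & v != precip$nodata
    if (!any(ok)) return(NA_real_)
    mean(v[ok])
  }, numeric(1))
  monthly <- monthly[!is.na(monthly)]
  if (length(monthly) == 0L) return(c(annual_mm = 0, seasonality = 0))
  c(annual_mm = sum(monthly),
    seasonality = if (mean(monthly) > 0) max(monthly) / mean(monthly) else 0)
}

#' Assemble the ten-variable classification table
#'
#' One row per CEP: six shape metrics, catchment area, flowline count,
#' network-routed annual precipitation and its seasonality. CEPs with no
#' catchment carry zeros for v7-v10; no value is ever missing.
#'
#' @param ceps a `cep_set`.
#' @param flowlines,watersheds river network layers (see
#'   [build_catchment()]).
#' @param precip 12-band monthly precipitation [raster_field()].
#' @return data.frame with `cep_id` and columns v1..v10 in fixed order.
#' @export
covariate_table <- function(ceps, flowlines, watersheds, precip) {
  if (anyDuplicated(ceps$table$id))
    stop("duplicate cep_id in CEP table")
  shape <- shape_metrics(ceps)
  hits <- flowline_cep_hits(ceps, flowlines)
  extra <- lapply(ceps$table$id, function(id) {
    ct <- build_catchment(ceps, id, flowlines, watersheds, hits = hits)
    pr <- route_precipitation(ct, precip)
    data.frame(v7_catchment_area_km2 = ct$area_km2,
               v8_n_flowlines = ct$n_flowlines,
               v9_annual_precip_mm = unname(pr[1L]),
               v10_precip_seasonality = unname(pr[2L]))
  })
  extra <- if (length(extra)) do.call(rbind, c(extra, list(make.row.names = FALSE)))
           else data.frame(v7_catchment_area_km2 = numeric(0),
                           v8_n_flowlines = integer(0),
                           v9_annual_precip_mm = numeric(0),
                           v10_precip_seasonality = numeric(0))
  out <- cbind(shape, extra)
  stopifnot(!anyNA(out))
  out
}

covariate_names <- function() {
  c("v1_area_km2", "v2_perimeter_km", "v3_compactness", "v4_mouth_width_km",
    "v5_elongation", "v6_closure_ratio", "v7_catchment_area_km2",
    "v8_n_flowlines", "v9_annual_precip_mm", "v10_precip_seasonality")
}
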