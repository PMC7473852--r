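#' Minimum-area bounding rectangle of a point set
#'
#' Rotating calipers over the convex hull. The rectangle's long side is the
#' standard "length" of an elongated shape and the short side its "width";
#' the length/width ratio is the elongation used as a classification
#' covariate.
#'
#' @param pts n x 2 coordinate matrix.
#' @return list with `length`, `width` (km, length >= width) and `angle`
#'   (radians of the long axis).
#' @export
min_area_rect <- function(pts) {
  pts <- unique(pts[stats::complete.cases(pts), , drop = FALSE])
  if (nrow(pts) == 0L) return(list(length = 0, width = 0, angle = 0))
  if (nrow(pts) == 1L) return(list(length = 0, width = 0, angle = 0))
  h <- grDevices::chull(pts)
  hp <- pts[h, , drop = FALSE]
  n <- nrow(hp)
  if (n == 2L) {
    d <- sqrt(sum((hp[2L, ] - hp[1L, ])^2))
    return(list(length = d, width = 0,
                angle = atan2(hp[2L, 2L] - hp[1L, 2L], hp[2L, 1L] - hp[1L, 1L])))
  }
  best <- NULL
  for (k in seq_len(n)) {
    a <- hp[k, ]; b <- hp[if (k == n) 1L else k + 1L, ]
    e <- b - a
    len <- sqrt(sum(e^2))
    if (len == 0) next
    u <- e / len                    # edge direction
    v <- c(-u[2L], u[1L])           # normal
    pu <- hp %*% u; pv <- hp %*% v
    du <- diff(range(pu)); dv <- diff(range(pv))
    area <- du * dv
    if (is.null(best) || area < best$area) {
      best <- list(area = area,
                   length = max(du, dv), width = min(du, dv),
                   angle = if (du >= dv) atan2(u[2L], u[1L])
                           else atan2(v[2L], v[1L]))
    }
  }
  best[c("length", "width", "angle")]
}

# cell corner coordinates of a set of linear cell indices (used for convex
# hulls of raster regions: corners, not centres, so extreme cells count
# their full footprint)
cell_corner_points <- function(grid, idx) {
  xy <- grid_cell_xy(grid, idx)
  h <- grid$cellsize / 2
  rbind(cbind(xy[, 1L] - h, xy[, 2L] - h), cbind(xy[, 1L] + h, xy[, 2L] - h),
        cbind(xy[, 1L] - h, xy[, 2L] + h), cbind(xy[, 1L] + h, xy[, 2L] + h))
}
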