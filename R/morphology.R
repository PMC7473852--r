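#' Grid morphology primitives
#'
#' Exact Euclidean distance / nearest-feature ("allocation") transforms on
#' cell masks, and the binary morphology built from them. These back the
#' embayment delineation (closing of the coastline), the mouth-segment and
#' patch allocation steps, and all nearest-valid-cell sampling.
#'
#' @param mask logical matrix of feature cells.
#' @param cellsize cell edge length (km); distances come back in km.
#' @name morphology
NULL

#' @describeIn morphology Euclidean distance (km) from every cell to the
#'   nearest TRUE cell; Inf when the mask is empty.
#' @export
distance_transform <- function(mask, cellsize = 1) {
  if (!any(mask)) return(matrix(Inf, nrow(mask), ncol(mask)))
  near <- ft_nearest_cpp(mask)
  nr <- nrow(mask)
  idx <- seq_along(mask)
  i <- ((idx - 1L) %% nr); j <- ((idx - 1L) %/% nr)
  ni <- ((near - 1L) %% nr); nj <- ((near - 1L) %/% nr)
  matrix(sqrt((i - ni)^2 + (j - nj)^2) * cellsize, nr, ncol(mask))
}

#' @describeIn morphology index (1-based, column-major) of the nearest TRUE
#'   cell for every cell; NA when the mask is empty.
#' @export
nearest_feature <- function(mask) ft_nearest_cpp(mask)

#' @describeIn morphology nearest-seed Euclidean allocation: every cell of
#'   `within` (default: whole grid) receives the label (from `labels`, an
#'   integer matrix with 0 background) of the nearest labelled cell.
#' @param labels integer matrix of seed labels (0 = background).
#' @param within optional logical matrix restricting the output support.
#' @export
allocate_nearest <- function(labels, within = NULL) {
  near <- ft_nearest_cpp(labels > 0L)
  out <- matrix(0L, nrow(labels), ncol(labels))
  ok <- !is.na(near)
  out[ok] <- labels[near[ok]]
  if (!is.null(within)) out[!within] <- 0L
  out
}

#' @describeIn morphology binary dilation by a Euclidean disc of radius
#'   `radius` km.
#' @param radius structuring disc radius in km; must be positive.
#' @export
dilate <- function(mask, radius, cellsize = 1) {
  if (radius <= 0) stop("radius must be > 0")
  distance_transform(mask, cellsize) <= radius
}

#' @describeIn morphology binary erosion by a Euclidean disc.
#' @export
erode <- function(mask, radius, cellsize = 1) {
  if (radius <= 0) stop("radius must be > 0")
  !(distance_transform(!mask, cellsize) <= radius)
}

#' @describeIn morphology morphological closing (dilate then erode): fills
#'   concavities narrower than the disc, never removes original cells.
#' @export
close_mask <- function(mask, radius, cellsize = 1) {
  erode(dilate(mask, radius, cellsize), radius, cellsize)
}

#' @describeIn morphology connected components (1..n labels, 0 background).
#' @param diagonal use 8-connectivity (default FALSE: 4-connectivity).
#' @export
label_components <- function(mask, diagonal = FALSE) {
  label_components_cpp(mask, diagonal)
}
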