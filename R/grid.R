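#' @useDynLib mangrovetyper, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Define a planar analysis grid
#'
#' All pipeline rasters and masks share one grid: a planar equal-area frame
#' in kilometres, upper-left origin, half-open square cells. Row 1 of a
#' value matrix is the northernmost row.
#'
#' @param nrow,ncol grid dimensions (cells).
#' @param xll,yll coordinates (km) of the lower-left corner.
#' @param cellsize cell edge length in km; must be positive.
#' @return An object of class `mt_grid`.
#' @export
mt_grid <- function(nrow, ncol, xll = 0, yll = 0, cellsize = 0.5) {
  if (cellsize <= 0) stop("configuration error: cellsize must be > 0")
  if (nrow < 1 || ncol < 1) stop("configuration error: grid dimensions must be >= 1")
  structure(list(nrow = as.integer(nrow), ncol = as.integer(ncol),
                 xll = xll, yll = yll, cellsize = cellsize),
            class = "mt_grid")
}

# cell centre coordinates of linear (column-major) indices
grid_cell_xy <- function(grid, idx) {
  i <- ((idx - 1L) %% grid$nrow) + 1L
  j <- ((idx - 1L) %/% grid$nrow) + 1L
  cbind(x = grid$xll + (j - 0.5) * grid$cellsize,
        y = grid$yll + (grid$nrow - i + 0.5) * grid$cellsize)
}

# row/col of points; points outside the grid get NA
grid_xy_cell <- function(grid, x, y) {
  j <- floor((x - grid$xll) / grid$cellsize) + 1L
  i <- grid$nrow - floor((y - grid$yll) / grid$cellsize)
  bad <- i < 1L | i > grid$nrow | j < 1L | j > grid$ncol
  i[bad] <- NA_integer_; j[bad] <- NA_integer_
  cbind(row = as.integer(i), col = as.integer(j))
}

grid_index <- function(grid, rc) {
  as.integer(rc[, 1L] + (rc[, 2L] - 1L) * grid$nrow)
}

cell_area_km2 <- function(grid) grid$cellsize^2

#' Construct a raster field
#'
#' A raster field couples a matrix (or a 3-d array whose third dimension is
#' the band, e.g. 12 monthly layers) with an [mt_grid()] geotransform, a
#' nodata sentinel and a unit string.
#'
#' @param values numeric matrix or 3-d array; row 1 is north.
#' @param grid an [mt_grid()].
#' @param nodata sentinel value marking missing cells; never enters
#'   statistics.
#' @param units free-text unit label.
#' @return Object of class `raster_field`.
#' @export
raster_field <- function(values, grid, nodata = -9999, units = "") {
  d <- dim(values)
  if (is.null(d) || length(d) < 2L)
    stop("raster values must be a matrix or 3-d array")
  if (d[1L] != grid$nrow || d[2L] != grid$ncol)
    stop("raster values do not match grid dimensions")
  structure(list(values = values, grid = grid, nodata = nodata, units = units),
            class = "raster_field")
}

rf_nbands <- function(field) {
  d <- dim(field$values)
  if (length(d) == 3L) d[3L] else 1L
}

rf_band <- function(field, b) {
  if (length(dim(field$values)) == 3L) field$values[, , b] else field$values
}

rf_valid_mask <- function(field, band = 1L) {
  v <- rf_band(field, band)
  !is.na(v) & v != field$nodata
}

#' Read / write rasters as plain-text grids
#'
#' Single-band fields round-trip through the ESRI ASCII grid format
#' (`ncols/nrows/xllcorner/yllcorner/cellsize/NODATA_value` header followed
#' by north-to-south rows). Multi-band stacks add one non-standard `nbands`
#' header line and concatenate band blocks; this keeps the whole scene
#' serializable as text.
#'
#' @param path file path.
#' @param field a [raster_field()].
#' @param units unit label to attach on read (not stored in the format).
#' @return `read_raster` returns a [raster_field()]; `write_raster` is
#'   called for its side effect.
#' @export
read_raster <- function(path, units = "") {
  if (!file.exists(path)) stop("I/O error: cannot read raster at ", path)
  lines <- readLines(path)
  hdr <- list(); k <- 0L
  for (ln in lines) {
    parts <- strsplit(trimws(ln), "\\s+")[[1L]]
    if (length(parts) == 2L && tolower(parts[1L]) %in%
        c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize",
          "nodata_value", "nbands")) {
      hdr[[tolower(parts[1L])]] <- as.numeric(parts[2L]); k <- k + 1L
    } else break
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  if (!all(need %in% names(hdr)))
    stop("I/O error: ", path, " is not an ASCII grid (missing header)")
  nb <- if (is.null(hdr$nbands)) 1L else as.integer(hdr$nbands)
  nr <- as.integer(hdr$nrows); nc <- as.integer(hdr$ncols)
  nod <- if (is.null(hdr$nodata_value)) -9999 else hdr$nodata_value
  vals <- scan(text = paste(lines[-seq_len(k)], collapse = "\n"),
               quiet = TRUE)
  if (length(vals) != nr * nc * nb)
    stop("I/O error: ", path, " value count does not match header")
  g <- mt_grid(nr, nc, hdr$xllcorner, hdr$yllcorner, hdr$cellsize)
  if (nb == 1L) {
    m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  } else {
    m <- array(NA_real_, c(nr, nc, nb))
    for (b in seq_len(nb))
      m[, , b] <- matrix(vals[((b - 1L) * nr * nc + 1L):(b * nr * nc)],
                         nrow = nr, ncol = nc, byrow = TRUE)
  }
  raster_field(m, g, nodata = nod, units = units)
}

#' @rdname read_raster
#' @export
write_raster <- function(field, path) {
  if (!dir.exists(dirname(path)))
    stop("I/O error: directory does not exist: ", dirname(path))
  g <- field$grid
  nb <- rf_nbands(field)
  hdr <- c(sprintf("ncols %d", g$ncol), sprintf("nrows %d", g$nrow),
           sprintf("xllcorner %.10g", g$xll), sprintf("yllcorner %.10g", g$yll),
           sprintf("cellsize %.10g", g$cellsize),
           sprintf("NODATA_value %.10g", field$nodata))
  if (nb > 1L) hdr <- c(hdr, sprintf("nbands %d", nb))
  con <- file(path, "w"); on.exit(close(con))
  writeLines(hdr, con)
  for (b in seq_len(nb)) {
    m <- rf_band(field, b)
    m[is.na(m)] <- field$nodata
    writeLines(apply(m, 1L, function(r) paste(format(r, digits = 15,
                                                     trim = TRUE,
                                                     scientific = FALSE),
                                              collapse = " ")), con)
  }
  invisible(NULL)
}

#' Sample a raster at points, snapping to the nearest valid cell
#'
#' Point-in-cell sampling with no interpolation: each point takes the value
#' of the non-nodata cell whose centre is nearest, provided that centre lies
#' within `radius_km`. For multi-band stacks the across-band mean at that
#' cell is returned (bands with nodata at the cell are skipped).
#'
#' @param field a [raster_field()].
#' @param x,y point coordinates (km).
#' @param radius_km search radius for a valid cell; points with none get NA.
#' @param fun summary across bands, default [mean()].
#' @return numeric vector, one value per point (NA where unsampled).
#' @export
sample_raster <- function(field, x, y, radius_km = 10, fun = mean) {
  g <- field$grid
  valid <- rf_valid_mask(field, 1L)
  if (rf_nbands(field) > 1L) {
    for (b in 2:rf_nbands(field)) valid <- valid | rf_valid_mask(field, b)
  }
  if (!any(valid)) return(rep(NA_real_, length(x)))
  near <- ft_nearest_cpp(valid)
  out <- rep(NA_real_, length(x))
  rc <- grid_xy_cell(g, x, y)
  for (p in seq_along(x)) {
    if (is.na(rc[p, 1L])) {
      # off-grid point: fall back to brute nearest valid centre
      xy <- grid_cell_xy(g, which(valid))
      d2 <- (xy[, 1L] - x[p])^2 + (xy[, 2L] - y[p])^2
      best <- which.min(d2)
      if (sqrt(d2[best]) > radius_km) next
      idx <- which(valid)[best]
    } else {
      idx <- near[rc[p, 1L], rc[p, 2L]]
      if (is.na(idx)) next
      xy <- grid_cell_xy(g, idx)
      if (sqrt((xy[1L] - x[p])^2 + (xy[2L] - y[p])^2) > radius_km) next
    }
    i <- ((idx - 1L) %% g$nrow) + 1L
    j <- ((idx - 1L) %/% g$nrow) + 1L
    vals <- vapply(seq_len(rf_nbands(field)), function(b) {
      v <- rf_band(field, b)[i, j]
      if (is.na(v) || v == field$nodata) NA_real_ else v
    }, numeric(1))
    if (all(is.na(vals))) next
    out[p] <- fun(vals[!is.na(vals)])
  }
  out
}

#' Mean of a raster band over a cell mask
#'
#' @param field a [raster_field()].
#' @param mask logical matrix on the same grid.
#' @param band band index.
#' @return scalar mean over valid masked cells; errors when the mask covers
#'   no valid cell (an all-nodata mean is undefined, not zero).
#' @export
mask_mean <- function(field, mask, band = 1L) {
  v <- rf_band(field, band)
  ok <- mask & !is.na(v) & v != field$nodata
  if (!any(ok)) stop("undefined value: mask covers no valid raster cell")
  mean(v[ok])
}
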