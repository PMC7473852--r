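#' Construct a vector layer
#'
#' A lightweight in-memory vector container: a list of geometries of one
#' type plus a flat attribute table. Geometries are planar, 2-D, in km.
#'
#' Internal geometry encodings follow GeoJSON nesting:
#' * `"point"`: numeric `c(x, y)`;
#' * `"polyline"`: an n x 2 coordinate matrix;
#' * `"polygon"`: a list of parts, each part a list of rings, each ring an
#'   n x 2 matrix (first ring outer, others holes).
#'
#' @param geometry list of geometries (may be empty).
#' @param attrs data.frame of attributes, one row per geometry.
#' @param geometry_type one of `"polygon"`, `"polyline"`, `"point"`.
#' @return Object of class `vector_layer`.
#' @export
vector_layer <- function(geometry = list(),
                         attrs = data.frame(),
                         geometry_type = c("polygon", "polyline", "point")) {
  geometry_type <- match.arg(geometry_type)
  if (nrow(attrs) == 0L && length(geometry) > 0L)
    attrs <- data.frame(row.names = seq_along(geometry))
  if (length(geometry) != nrow(attrs))
    stop("attribute rows must match geometry count")
  structure(list(geometry = geometry, attrs = attrs,
                 geometry_type = geometry_type),
            class = "vector_layer")
}

#' @export
print.vector_layer <- function(x, ...) {
  cat("<vector_layer> ", length(x$geometry), " ", x$geometry_type,
      " feature(s), ", ncol(x$attrs), " attribute(s)\n", sep = "")
  invisible(x)
}

# close a ring (first point repeated) for serialization
close_ring <- function(m) {
  if (nrow(m) > 0L && !all(m[1L, ] == m[nrow(m), ])) m <- rbind(m, m[1L, ])
  m
}

open_ring <- function(m) {
  if (nrow(m) > 1L && all(m[1L, ] == m[nrow(m), ])) m <- m[-nrow(m), , drop = FALSE]
  m
}

# one repair pass: drop non-finite rows and consecutive duplicates
repair_ring <- function(m) {
  m <- m[stats::complete.cases(m) & is.finite(m[, 1L]) & is.finite(m[, 2L]), ,
         drop = FALSE]
  if (nrow(m) > 1L) {
    keep <- c(TRUE, rowSums(abs(diff(m))) > 0)
    m <- m[keep, , drop = FALSE]
  }
  m
}

shoelace <- function(ring) {
  ring <- open_ring(ring)
  n <- nrow(ring)
  if (n < 3L) return(0)
  x <- ring[, 1L]; y <- ring[, 2L]
  j <- c(2:n, 1L)
  sum(x * y[j] - x[j] * y) / 2
}

#' Planar polygon area in square kilometres
#'
#' Shoelace area in the equal-area frame: nonnegative, additive over
#' disjoint parts, holes subtracted. Degenerate rings (fewer than three
#' distinct vertices after one repair pass) contribute zero; rings with
#' non-finite coordinates that survive repair raise a geometry error.
#'
#' @param geometry a ring matrix, a polygon (list of parts of rings), or a
#'   `vector_layer` of polygons (returns per-feature areas).
#' @return numeric area(s), km^2.
#' @export
area_km2 <- function(geometry) {
  if (inherits(geometry, "vector_layer")) {
    if (geometry$geometry_type != "polygon")
      stop("geometry error: area_km2 needs polygons")
    return(vapply(geometry$geometry, area_km2, numeric(1)))
  }
  rings <- flatten_rings(geometry)
  total <- 0
  for (part in rings) {
    part_area <- 0
    for (k in seq_along(part)) {
      if (nrow(part[[k]]) > 0L && !all(is.finite(part[[k]])))
        stop("geometry error: ring has non-finite coordinates")
      ring <- repair_ring(part[[k]])
      a <- abs(shoelace(ring))
      part_area <- part_area + if (k == 1L) a else -a
    }
    total <- total + max(part_area, 0)
  }
  total
}

# normalize a geometry into list(parts -> list(rings))
flatten_rings <- function(geometry) {
  if (is.matrix(geometry)) return(list(list(geometry)))
  if (is.list(geometry)) {
    if (length(geometry) == 0L) return(list())
    if (is.matrix(geometry[[1L]])) return(list(geometry))   # one part
    return(geometry)                                        # multi-part
  }
  stop("geometry error: unrecognized polygon encoding")
}

#' Length of a polyline in kilometres
#' @param m an n x 2 coordinate matrix.
#' @return numeric length, km.
#' @export
polyline_length_km <- function(m) {
  if (!is.matrix(m) || nrow(m) < 2L) return(0)
  sum(sqrt(rowSums(diff(m)^2)))
}

# even-odd point-in-polygon over all rings of a geometry (vectorized over
# points); holes handled by parity
points_in_polygon <- function(geometry, x, y) {
  inside <- rep(FALSE, length(x))
  for (part in flatten_rings(geometry)) {
    for (ring in part) {
      ring <- open_ring(ring)
      n <- nrow(ring)
      if (n < 3L) next
      xr <- ring[, 1L]; yr <- ring[, 2L]
      j <- c(n, seq_len(n - 1L))
      for (k in seq_len(n)) {
        xi <- xr[k]; yi <- yr[k]; xj <- xr[j[k]]; yj <- yr[j[k]]
        cross <- ((yi > y) != (yj > y)) &
          (x < (xj - xi) * (y - yi) / (yj - yi) + xi)
        inside <- xor(inside, cross)
      }
    }
  }
  inside
}

#' Rasterize polygons onto a grid
#'
#' Cell-centre containment (even-odd rule); a cell belongs to a polygon when
#' its centre is inside.
#'
#' @param layer a polygon `vector_layer` or a single polygon geometry.
#' @param grid an [mt_grid()].
#' @return logical matrix (any polygon) when given one geometry, or integer
#'   matrix of 1-based feature indices (0 = none; later features win ties)
#'   for a layer.
#' @export
rasterize_polygons <- function(layer, grid) {
  idx_all <- seq_len(grid$nrow * grid$ncol)
  xy <- grid_cell_xy(grid, idx_all)
  if (inherits(layer, "vector_layer")) {
    out <- matrix(0L, grid$nrow, grid$ncol)
    for (f in seq_along(layer$geometry)) {
      inside <- points_in_polygon(layer$geometry[[f]], xy[, 1L], xy[, 2L])
      out[inside] <- f
    }
    return(out)
  }
  matrix(points_in_polygon(layer, xy[, 1L], xy[, 2L]), grid$nrow, grid$ncol)
}

#' Trace a cell mask into boundary polygons
#'
#' Follows exposed cell edges (interior kept on the left) and chains them
#' into closed rings: outer rings counter-clockwise, holes clockwise. The
#' traced staircase polygon reproduces the mask exactly under
#' [rasterize_polygons()] and its shoelace area equals cell count times
#' cell area.
#'
#' @param mask logical matrix.
#' @param grid an [mt_grid()].
#' @return polygon geometry (list of one part holding all rings; callers
#'   needing strict part nesting can regroup by ring sign).
#' @export
trace_mask <- function(mask, grid) {
  nr <- grid$nrow; nc <- grid$ncol; cs <- grid$cellsize
  cells <- which(mask)
  if (length(cells) == 0L) return(list())
  i <- ((cells - 1L) %% nr) + 1L
  j <- ((cells - 1L) %/% nr) + 1L
  inreg <- mask
  # corner (ic, jc) with ic in 0..nr, jc in 0..nc; key = ic + jc*(nr+1) + 1
  key <- function(ic, jc) ic + jc * (nr + 1L) + 1L
  from <- integer(0); to <- integer(0)
  add_edge <- function(f, t) { from[[length(from) + 1L]] <<- f; to[[length(to) + 1L]] <<- t }
  nb <- function(ii, jj) ii >= 1L & ii <= nr & jj >= 1L & jj <= nc &
    inreg[cbind(pmax(pmin(ii, nr), 1L), pmax(pmin(jj, nc), 1L))]
  # top edges: walk west (x1,ytop)->(x0,ytop); corners row index = i-1
  expo <- !nb(i - 1L, j); from <- c(from, key(i - 1L, j)[expo]); to <- c(to, key(i - 1L, j - 1L)[expo])
  # bottom edges: walk east
  expo <- !nb(i + 1L, j); from <- c(from, key(i, j - 1L)[expo]); to <- c(to, key(i, j)[expo])
  # left edges: walk south (top corner -> bottom corner)
  expo <- !nb(i, j - 1L); from <- c(from, key(i - 1L, j - 1L)[expo]); to <- c(to, key(i, j - 1L)[expo])
  # right edges: walk north
  expo <- !nb(i, j + 1L); from <- c(from, key(i, j)[expo]); to <- c(to, key(i - 1L, j)[expo])
  # chain edges into rings; at ambiguous corners take the latest unused edge
  edge_by_from <- split(seq_along(from), from)
  used <- rep(FALSE, length(from))
  rings <- list()
  for (e0 in seq_along(from)) {
    if (used[e0]) next
    ring_keys <- integer(0)
    e <- e0
    repeat {
      used[e] <- TRUE
      ring_keys <- c(ring_keys, from[e])
      nxt <- edge_by_from[[as.character(to[e])]]
      nxt <- nxt[!used[nxt]]
      if (length(nxt) == 0L) break
      e <- nxt[1L]
    }
    ic <- ((ring_keys - 1L) %% (nr + 1L))
    jc <- ((ring_keys - 1L) %/% (nr + 1L))
    rings[[length(rings) + 1L]] <-
      cbind(grid$xll + jc * cs, grid$yll + (nr - ic) * cs)
  }
  # group into parts: CCW rings are outers, CW rings are holes attached to
  # the outer containing their first vertex
  signs <- vapply(rings, shoelace, numeric(1))
  outers <- which(signs > 0); holes <- which(signs < 0)
  parts <- lapply(outers, function(o) list(rings[[o]]))
  for (hh in holes) {
    # probe point just inside the hole: midpoint of the first edge, offset
    # to the right of the direction of travel (hole rings run clockwise)
    r1 <- rings[[hh]]
    mid <- (r1[1L, ] + r1[2L, ]) / 2
    d <- r1[2L, ] - r1[1L, ]; d <- d / sqrt(sum(d^2))
    v <- mid + c(d[2L], -d[1L]) * cs / 4
    hit <- which(vapply(outers, function(o)
      points_in_polygon(list(list(rings[[o]])), v[1L], v[2L]), logical(1)))
    if (length(hit)) {
      parts[[hit[1L]]] <- c(parts[[hit[1L]]], list(rings[[hh]]))
    }
  }
  parts
}

#' Read / write vector layers as GeoJSON
#'
#' Point, LineString, Polygon and MultiPolygon features with flat
#' properties. Coordinates round-trip at full double precision. Layers with
#' mixed geometry types are rejected with the offending feature named.
#'
#' @param path file path.
#' @param layer a [vector_layer()].
#' @return `read_vector` returns a [vector_layer()].
#' @export
read_vector <- function(path) {
  if (!file.exists(path)) stop("I/O error: cannot read vector file ", path)
  js <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                 error = function(e) stop("I/O error: ", path,
                                          " is not valid GeoJSON: ",
                                          conditionMessage(e)))
  if (is.null(js$type) || js$type != "FeatureCollection")
    stop("I/O error: ", path, " is not a GeoJSON FeatureCollection")
  feats <- js$features
  geometry <- vector("list", length(feats))
  props <- vector("list", length(feats))
  gtype <- NULL
  as_mat <- function(coords)
    do.call(rbind, lapply(coords, function(p) c(p[[1L]], p[[2L]])))
  for (f in seq_along(feats)) {
    gj <- feats[[f]]$geometry
    ty <- switch(gj$type,
                 Point = "point", LineString = "polyline",
                 Polygon = "polygon", MultiPolygon = "polygon",
                 stop("I/O error: unsupported geometry type '", gj$type,
                      "' in feature ", f, " of ", path))
    if (is.null(gtype)) gtype <- ty
    else if (ty != gtype)
      stop("I/O error: mixed geometry types in ", path,
           "; feature ", f, " is ", ty, " but layer is ", gtype)
    geometry[[f]] <- switch(gj$type,
      Point = c(gj$coordinates[[1L]], gj$coordinates[[2L]]),
      LineString = as_mat(gj$coordinates),
      Polygon = list(lapply(gj$coordinates, as_mat)),
      MultiPolygon = lapply(gj$coordinates, function(pp) lapply(pp, as_mat)))
    pr <- feats[[f]]$properties
    props[[f]] <- if (is.null(pr) || length(pr) == 0L)
      data.frame(row.names = 1L) else as.data.frame(pr, stringsAsFactors = FALSE)
  }
  attrs <- if (length(props)) do.call(rbind, props) else data.frame()
  if (!is.null(attrs)) rownames(attrs) <- NULL
  vector_layer(geometry, attrs,
               if (is.null(gtype)) "polygon" else gtype)
}

#' @rdname read_vector
#' @export
write_vector <- function(layer, path) {
  if (!dir.exists(dirname(path)))
    stop("I/O error: directory does not exist: ", dirname(path))
  feats <- vector("list", length(layer$geometry))
  for (f in seq_along(layer$geometry)) {
    g <- layer$geometry[[f]]
    gj <- switch(layer$geometry_type,
      point = list(type = "Point", coordinates = c(g[1L], g[2L])),
      polyline = list(type = "LineString",
                      coordinates = lapply(seq_len(nrow(g)),
                                           function(r) c(g[r, 1L], g[r, 2L]))),
      polygon = {
        parts <- flatten_rings(g)
        coords <- lapply(parts, function(part)
          lapply(part, function(ring) {
            ring <- close_ring(ring)
            lapply(seq_len(nrow(ring)), function(r) c(ring[r, 1L], ring[r, 2L]))
          }))
        if (length(parts) == 1L)
          list(type = "Polygon", coordinates = coords[[1L]])
        else list(type = "MultiPolygon", coordinates = coords)
      })
    pr <- if (ncol(layer$attrs) == 0L) structure(list(), names = character(0))
          else as.list(layer$attrs[f, , drop = FALSE])
    feats[[f]] <- list(type = "Feature", geometry = gj, properties = pr)
  }
  out <- list(type = "FeatureCollection", features = feats)
  writeLines(jsonlite::toJSON(out, auto_unbox = TRUE, digits = NA,
                              null = "null"), path)
  invisible(NULL)
}
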