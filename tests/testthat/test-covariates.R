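test_that("shape metrics match closed forms on exact geometry", {
  # near-circle: area pi, compactness 1, point mouth
  circ <- cep_polygon(circle_ring(1, 512),
                      mouth = matrix(c(1, 0), 1, 2))
  m <- shape_metrics(circ)
  expect_equal(m$v1_area_km2, pi, tolerance = 1e-3)
  expect_equal(m$v3_compactness, 1, tolerance = 1e-3)
  expect_equal(m$v4_mouth_width_km, 0)

  # 1 x 10 rectangle, mouth on a short side
  rect <- cep_polygon(rect_ring(0, 0, 10, 1),
                      mouth = cbind(c(0, 0), c(0, 1)))
  m <- shape_metrics(rect)
  expect_equal(m$v1_area_km2, 10)
  expect_equal(m$v2_perimeter_km, 22)
  expect_equal(m$v3_compactness, 4 * pi * 10 / 484, tolerance = 1e-9)
  expect_equal(m$v4_mouth_width_km, 1)
  expect_equal(m$v5_elongation, 10, tolerance = 1e-9)
  expect_equal(m$v6_closure_ratio, 1, tolerance = 1e-9)

  # square with a full-side mouth: closure ratio 1
  sq <- cep_polygon(rect_ring(0, 0, 4, 4), mouth = cbind(c(0, 4), c(0, 0)))
  expect_equal(shape_metrics(sq)$v6_closure_ratio, 1, tolerance = 1e-9)

  expect_error(shape_metrics(cep_polygon(rect_ring(0, 0, 1, 1), NULL)),
               "mouth")
})

test_that("shape metrics scale correctly", {
  base <- cep_polygon(rect_ring(0, 0, 8, 2), cbind(c(0, 0), c(0, 2)))
  k <- 3
  scaled <- cep_polygon(rect_ring(0, 0, 8 * k, 2 * k),
                        cbind(c(0, 0), c(0, 2 * k)))
  m0 <- shape_metrics(base); m1 <- shape_metrics(scaled)
  expect_equal(m1$v1_area_km2, k^2 * m0$v1_area_km2)
  expect_equal(m1$v2_perimeter_km, k * m0$v2_perimeter_km)
  expect_equal(m1$v4_mouth_width_km, k * m0$v4_mouth_width_km)
  expect_equal(m1$v3_compactness, m0$v3_compactness)
  expect_equal(m1$v5_elongation, m0$v5_elongation)
  expect_equal(m1$v6_closure_ratio, m0$v6_closure_ratio)
})

make_river_world <- function() {
  # one notch CEP fed by a 3-segment chained river
  w <- flat_world(nr = 60, nc = 60, cs = 0.5)
  notch <- abs(w$X - 15) <= 2 & w$Y >= w$coast_y & w$Y <= w$coast_y + 5
  land <- (w$Y >= w$coast_y) & !notch
  gen <- generalize_coastline(land, 6, w$grid)
  ceps <- extract_embayments(land, gen, w$grid)
  head_y <- w$coast_y + 4
  fl <- vector_layer(
    list(rbind(c(15, head_y + 5), c(15, head_y)),        # 1: enters the CEP
         rbind(c(15, head_y + 10), c(15, head_y + 5)),   # 2: upstream of 1
         rbind(c(15, head_y + 15), c(15, head_y + 10))), # 3: upstream of 2
    data.frame(id = 1:3, downstream_id = c(NA, 1L, 2L),
               outlet_x = c(15, NA, NA), outlet_y = c(head_y, NA, NA)),
    "polyline")
  ws <- vector_layer(
    list(list(list(rect_ring(10, head_y, 10, 5))),       # 50 km^2 -> fl 1
         list(list(rect_ring(10, head_y + 5, 10, 5))),   # 50 km^2 -> fl 2
         list(list(rect_ring(10, head_y + 10, 10, 5)))), # 50 km^2 -> fl 3
    data.frame(ws_id = 1:3, flowline_id = 1:3), "polygon")
  list(w = w, ceps = ceps, fl = fl, ws = ws)
}

test_that("catchments aggregate whole upstream watersheds", {
  rw <- make_river_world()
  expect_equal(nrow(rw$ceps$table), 1)
  ct <- build_catchment(rw$ceps, 1, rw$fl, rw$ws)
  expect_equal(ct$n_flowlines, 1)       # only segment 1 touches the CEP
  expect_equal(sort(ct$ws_ids), 1:3)    # but the whole chain drains in
  expect_equal(ct$area_km2, 150)

  # no intersecting flowline: empty catchment
  far <- rw$fl
  far$geometry <- lapply(far$geometry, function(m)
    cbind(m[, 1] + 20, m[, 2]))
  far$attrs$outlet_x <- far$attrs$outlet_x + 20
  ct0 <- build_catchment(rw$ceps, 1, far, rw$ws)
  expect_equal(ct0$n_flowlines, 0)
  expect_equal(ct0$area_km2, 0)

  # two distributaries sharing one watershed: counted twice as flowlines,
  # once as area
  w <- rw$w
  fl2 <- vector_layer(
    list(rbind(c(14, w$coast_y + 6), c(14, w$coast_y + 2)),
         rbind(c(16, w$coast_y + 6), c(16, w$coast_y + 2))),
    data.frame(id = 1:2, downstream_id = c(NA, NA),
               outlet_x = c(14, 16), outlet_y = rep(w$coast_y + 2, 2)),
    "polyline")
  ws2 <- vector_layer(
    list(list(list(rect_ring(10, w$coast_y + 5, 10, 5))),
         list(list(rect_ring(10, w$coast_y + 5, 10, 5)))),
    data.frame(ws_id = c(7L, 7L), flowline_id = 1:2), "polygon")
  ct2 <- build_catchment(rw$ceps, 1, fl2, ws2)
  expect_equal(ct2$n_flowlines, 2)
  expect_equal(ct2$area_km2, 50)

  # dangling downstream pointer names the flowline
  bad <- rw$fl
  bad$attrs$downstream_id[2] <- 99L
  expect_error(build_catchment(rw$ceps, 1, bad, rw$ws), "flowline 2")
})

test_that("precipitation routes as catchment-masked monthly means", {
  rw <- make_river_world()
  ct <- build_catchment(rw$ceps, 1, rw$fl, rw$ws)
  g <- rw$w$grid
  uniform <- raster_field(array(100, c(g$nrow, g$ncol, 12)), g)
  pr <- route_precipitation(ct, uniform)
  expect_equal(unname(pr), c(1200, 1))

  spiky <- array(0, c(g$nrow, g$ncol, 12)); spiky[, , 7] <- 1200
  pr <- route_precipitation(ct, raster_field(spiky, g))
  expect_equal(unname(pr), c(1200, 12))

  # nodata half: statistics over valid cells only
  half <- array(100, c(g$nrow, g$ncol, 12))
  half[, 1:30, ] <- -9999
  pr <- route_precipitation(ct, raster_field(half, g, nodata = -9999))
  expect_equal(unname(pr[1]), 1200)

  expect_error(route_precipitation(ct, raster_field(
    array(1, c(g$nrow, g$ncol, 3)), g)), "12 monthly bands")
  # empty catchment: nothing routed
  ct0 <- build_catchment(rw$ceps, 1, vector_layer(list(), data.frame(),
                                                  "polyline"), rw$ws)
  expect_equal(unname(route_precipitation(ct0, uniform)), c(0, 0))
})

test_that("the covariate table is complete, finite and class-separating", {
  pr <- world_processed()
  sc <- world_scene()
  cov <- pr$cov
  expect_equal(nrow(cov), nrow(pr$ceps$table))
  expect_true(all(is.finite(as.matrix(cov))))
  expect_named(cov, c("cep_id", mangrovetyper:::covariate_names()))
  # planted geometry contrast: lagoons are choked, bays are open
  cls <- pr$truth_class[as.character(cov$cep_id)]
  v6_lag <- cov$v6_closure_ratio[cls == "lagoon"]
  v6_bay <- cov$v6_closure_ratio[cls == "bay"]
  expect_lt(max(v6_lag), min(v6_bay))
  # estuaries and deltas have rivers; bays and lagoons do not
  expect_true(all(cov$v8_n_flowlines[cls %in% c("estuary", "delta")] >= 1))
  expect_true(all(cov$v8_n_flowlines[cls %in% c("bay", "lagoon")] == 0))
  # catchment monotonicity: v7/v9 positive exactly when a river drains in
  expect_true(all((cov$v7_catchment_area_km2 > 0) ==
                    (cov$v8_n_flowlines > 0)))

  # zero CEPs: header-only table
  empty <- mangrovetyper:::cep_set_empty(sc$grid)
  cov0 <- covariate_table(empty, sc$flowlines, sc$watersheds, sc$precip)
  expect_equal(nrow(cov0), 0)
  expect_named(cov0, c("cep_id", mangrovetyper:::covariate_names()))
})

test_that("raster shape metrics are cellsize-equivariant", {
  w <- flat_world(nr = 60, nc = 60, cs = 0.5)
  notch <- abs(w$X - 15) <= 2 & w$Y >= w$coast_y & w$Y <= w$coast_y + 6
  land <- (w$Y >= w$coast_y) & !notch
  gen <- generalize_coastline(land, 6, w$grid)
  ceps1 <- extract_embayments(land, gen, w$grid)
  g2 <- mt_grid(60, 60, 0, 0, 1)   # same cells, doubled cell size
  ceps2 <- extract_embayments(land, gen, g2)
  m1 <- shape_metrics(ceps1); m2 <- shape_metrics(ceps2)
  expect_equal(m2$v1_area_km2, 4 * m1$v1_area_km2)
  expect_equal(m2$v2_perimeter_km, 2 * m1$v2_perimeter_km)
  expect_equal(m2$v3_compactness, m1$v3_compactness)
  expect_equal(m2$v5_elongation, m1$v5_elongation)
  expect_equal(m2$v6_closure_ratio, m1$v6_closure_ratio, tolerance = 1e-9)
})
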