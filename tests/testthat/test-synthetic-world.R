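test_that("configuration is validated", {
  expect_error(scene_config(n_bay = -1), "configuration error")
  expect_error(scene_config(cellsize_km = 0), "configuration error")
  expect_error(scene_config(loss_rates = c(deltaic = 1.2, estuarine = 0,
                                           lagoonal = 0, open_coast = 0)),
               "configuration error")
  expect_error(scene_config(delta_distributaries = 2), "configuration error")
})

test_that("a world with no embayments is a straight coast with empty truth", {
  cfg <- scene_config(n_delta = 0, n_estuary = 0, n_lagoon = 0, n_bay = 0,
                      n_open_strips = 0)
  sc <- generate_scene(cfg, seed = 3)
  expect_equal(nrow(sc$truth$embayments), 0)
  expect_equal(nrow(sc$truth$units), 0)
  gen <- generalize_coastline(sc)
  expect_equal(gen, sc$land)                       # nothing to seal
  ceps <- extract_embayments(sc, gen)
  expect_equal(nrow(ceps$table), 0)
})

test_that("planted deltas carry the configured distributary count", {
  cfg <- scene_config(n_delta = 3, n_estuary = 0, n_lagoon = 0, n_bay = 0,
                      delta_distributaries = 4, n_open_strips = 0)
  sc <- generate_scene(cfg, seed = 2)
  expect_equal(sum(sc$truth$embayments$class == "delta"), 3)
  pr <- process_scene(sc)
  tm <- pr$truth_match
  expect_true(all(tm$matched))
  counts <- pr$outlets[as.character(tm$cep_id)]
  expect_equal(unname(counts), rep(4L, 3))
})

test_that("seeds vary geometry but not structure; same seed is identical", {
  cfg <- scene_config()
  s1 <- generate_scene(cfg, seed = 1)
  s2 <- generate_scene(cfg, seed = 2)
  expect_equal(table(s1$truth$embayments$class),
               table(s2$truth$embayments$class))
  expect_false(identical(s1$truth$embayments$xc, s2$truth$embayments$xc))
  s1b <- generate_scene(cfg, seed = 1)
  expect_identical(s1$land, s1b$land)
  expect_identical(s1$truth$unit_mask, s1b$truth$unit_mask)
  expect_identical(s1$extents, s1b$extents)
  expect_identical(s1$sites, s1b$sites)
})

test_that("scene invariants hold on the default world", {
  sc <- world_scene()
  # all rasters share one geotransform
  for (f in list(sc$precip, sc$tide, sc$spm, sc$agb))
    expect_equal(f$grid, sc$grid)
  # extents are nested subsets of the baseline union
  base <- Reduce(`|`, sc$extents)
  ts <- names(sc$extents)
  expect_identical(sc$extents[[1]], base)
  for (t in seq_along(ts)[-1])
    expect_true(all(sc$extents[[ts[t]]] <= sc$extents[[ts[t - 1]]]))
  # flowline outlets lie on/near the coastal boundary (grid tolerance)
  at <- sc$flowlines$attrs
  ox <- at$outlet_x[!is.na(at$outlet_x)]
  oy <- at$outlet_y[!is.na(at$outlet_x)]
  shoredist <- distance_transform(sc$land, sc$grid$cellsize)
  rc <- mangrovetyper:::grid_xy_cell(sc$grid, ox, oy)
  expect_true(all(shoredist[rc] <= 3 * sc$grid$cellsize))
  # watersheds all linked to a flowline
  expect_true(all(sc$watersheds$attrs$flowline_id %in% at$id))
  # per-type truth areas sum to total extent area
  um <- sc$truth$unit_mask
  expect_equal(sum(um > 0), sum(base))
})

test_that("timestep erosion realizes planted loss rates exactly per unit", {
  sc <- world_scene()
  rates <- sc$config$loss_rates
  um <- sc$truth$unit_mask
  for (r in seq_len(nrow(sc$truth$units))) {
    u <- sc$truth$units[r, ]
    cells <- which(um == u$unit_id)
    removed <- sum(sc$extents[[1]][cells]) -
      sum(sc$extents[[length(sc$extents)]][cells])
    expect_equal(removed, round(rates[[u$class]] * length(cells)))
  }
})

test_that("loss-rate edge cases: identity, annihilation, bounds", {
  sc <- world_scene()
  zero <- generate_timesteps(sc, c(deltaic = 0, estuarine = 0,
                                   lagoonal = 0, open_coast = 0), seed = 5)
  expect_true(all(vapply(zero$extents, identical, logical(1),
                         y = zero$extents[[1]])))
  gone <- generate_timesteps(sc, c(deltaic = 1, estuarine = 0,
                                   lagoonal = 0, open_coast = 0), seed = 5)
  dcells <- which(sc$truth$unit_mask %in%
                    sc$truth$units$unit_id[sc$truth$units$class == "deltaic"])
  expect_equal(sum(gone$extents[["2016"]][dcells]), 0)
  expect_error(generate_timesteps(sc, c(deltaic = -0.1, estuarine = 0,
                                        lagoonal = 0, open_coast = 0)),
               "loss_rate")
})

test_that("a 100 km^2 lagoonal unit losing 6.9% ends near 93.1 km^2", {
  # minimal scene stub: one 400-cell (100 km^2) lagoonal unit
  g <- mt_grid(40, 40, 0, 0, 0.5)
  um <- matrix(0L, 40, 40); um[11:30, 11:30] <- 1L
  sc <- structure(list(
    grid = g, config = scene_config(),
    truth = list(unit_mask = um,
                 units = data.frame(unit_id = 1L, class = "lagoonal"))),
    class = "coast_scene")
  out <- generate_timesteps(sc, c(deltaic = 0, estuarine = 0,
                                  lagoonal = 0.069, open_coast = 0),
                            seed = 9)
  a2016 <- sum(out$extents[["2016"]]) * 0.25
  expect_lt(abs(a2016 - 93.1), 0.25 + 1e-9)   # within one raster cell
})

test_that("sediment truth follows the planted logistic model", {
  # saturated intercept: every unit terrigenous
  sc <- generate_sediment_fields(world_scene(), beta = c(50, 0, 0),
                                 seed = 7)
  expect_true(all(sc$truth$units$sediment == "terrigenous"))
  # symmetric model: site labels are a fair coin among non-riverine sites
  sc0 <- generate_sediment_fields(world_scene(), beta = c(0, 0, 0),
                                  seed = 11)
  lab <- sc0$sites$sediment_label[sc0$sites$typological_status ==
                                    "non_riverine"]
  expect_gt(mean(lab == "terrigenous"), 0.3)
  expect_lt(mean(lab == "terrigenous"), 0.7)
  # deltaic/estuarine truth is terrigenous regardless of the fields
  sc1 <- generate_sediment_fields(world_scene(), beta = c(-50, 0, 0),
                                  seed = 7)
  riv <- sc1$truth$units$class %in% c("deltaic", "estuarine")
  expect_true(all(sc1$truth$units$sediment[riv] == "terrigenous"))
  expect_true(all(sc1$truth$units$sediment[!riv] == "carbonate"))
})

test_that("scenes serialize to plain text and reload", {
  dir <- withr::local_tempdir()
  sc <- world_scene()
  files <- write_scene(sc, dir)
  expect_true(all(file.exists(files)))
  tide <- read_raster(file.path(dir, "tide.asc"))
  expect_equal(tide$values, sc$tide$values, tolerance = 1e-9)
  fl <- read_vector(file.path(dir, "flowlines.geojson"))
  expect_equal(length(fl$geometry), length(sc$flowlines$geometry))
})
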