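# two classified notch CEPs with a mangrove band touching both
two_cep_world <- function() {
  w <- flat_world(nr = 80, nc = 100, cs = 0.5)
  n1 <- abs(w$X - 12) <= 2 & w$Y >= w$coast_y & w$Y <= w$coast_y + 5
  n2 <- abs(w$X - 28) <= 2 & w$Y >= w$coast_y & w$Y <= w$coast_y + 5
  land <- (w$Y >= w$coast_y) & !(n1 | n2)
  gen <- generalize_coastline(land, 6, w$grid)
  ceps <- extract_embayments(land, gen, w$grid)
  ceps$table$class <- c("estuary", "lagoon")
  list(w = w, land = land, ceps = ceps)
}

test_that("patch splitting partitions straddlers and conserves area", {
  tw <- two_cep_world()
  w <- tw$w
  # a coastal band touching both CEPs
  band <- tw$land & w$Y <= w$coast_y + 0.5 & w$X >= 10 & w$X <= 30
  patches <- extract_patches(band, w$grid)
  expect_equal(nrow(patches$table), 1)
  split <- split_patches(patches, tw$ceps)
  expect_equal(nrow(split$table), 2)
  expect_equal(sum(split$table$area_km2), sum(patches$table$area_km2))
  # each half is nearer its own CEP
  a1 <- assign_direct(split, tw$ceps)
  expect_setequal(a1$type, c("estuarine", "lagoonal"))

  # a patch inside one CEP's reach is unchanged; zero CEPs change nothing
  lone <- tw$land & w$Y <= w$coast_y + 0.5 & w$X >= 10 & w$X <= 15
  lp <- extract_patches(lone, w$grid)
  expect_equal(nrow(split_patches(lp, tw$ceps)$table), nrow(lp$table))
  none <- mangrovetyper:::cep_set_empty(w$grid)
  expect_equal(split_patches(lp, none)$table$n_cells, lp$table$n_cells)
})

test_that("direct assignment maps embayment classes to unit types", {
  tw <- two_cep_world()
  w <- tw$w
  tw$ceps$table$class <- c("delta", "bay")
  frL <- tw$land & w$Y <= w$coast_y + 0.5 & w$X >= 8 & w$X <= 9.9
  frR <- tw$land & w$Y <= w$coast_y + 0.5 & w$X >= 30.2 & w$X <= 32
  far <- tw$land & w$Y >= w$coast_y + 15 & w$Y <= w$coast_y + 16 &
    w$X >= 40 & w$X <= 44
  patches <- extract_patches(frL | frR | far, w$grid)
  a <- assign_direct(patches, tw$ceps)
  got <- a$type[order(a$patch_id)]
  expect_true("deltaic" %in% got && "open_coast" %in% got)
  # the distant patch does not intersect (touching tolerance is one cell)
  expect_true(any(is.na(a$type)))
})

test_that("orphans fall back through catchment, distance, open coast", {
  tw <- two_cep_world()
  w <- tw$w
  # orphan A inside CEP 1's catchment, orphan B far from everything
  orphA <- tw$land & w$Y >= w$coast_y + 8 & w$Y <= w$coast_y + 9 &
    w$X >= 10 & w$X <= 13
  orphB <- tw$land & w$Y >= w$coast_y + 15 & w$Y <= w$coast_y + 16 &
    w$X >= 44 & w$X <= 48
  patches <- extract_patches(orphA | orphB, w$grid)
  a <- assign_direct(patches, tw$ceps)
  expect_true(all(is.na(a$type)))
  catchments <- list(
    structure(list(cep_id = 1, geometry = list(list(list(
      rect_ring(8, w$coast_y, 8, 12))))), class = "catchment"),
    structure(list(cep_id = 2, geometry = list()), class = "catchment"))
  a2 <- assign_orphans(a, patches, tw$ceps, catchments, max_dist_km = 4)
  # A is in CEP 1's catchment -> estuarine; B beyond reach -> open coast
  ax <- a2[order(a2$patch_id), ]
  expect_setequal(ax$method, c("catchment", "fallback"))
  expect_equal(ax$type[ax$method == "catchment"], "estuarine")
  expect_equal(ax$type[ax$method == "fallback"], "open_coast")
  expect_true(is.na(ax$cep_id[ax$method == "fallback"]))

  # distance fallback with a tie: catchment-sharing CEP wins
  mid <- tw$land & w$Y >= w$coast_y + 8 & w$Y <= w$coast_y + 8.5 &
    abs(w$X - 20) <= 1    # equidistant between the two CEPs
  pm <- extract_patches(mid, w$grid)
  am <- assign_direct(pm, tw$ceps)
  am2 <- assign_orphans(am, pm, tw$ceps, catchments = NULL,
                        max_dist_km = 20)
  expect_equal(am2$cep_id, 1L)   # tie broken by lower cep id
  am3 <- assign_orphans(am, pm, tw$ceps, catchments, max_dist_km = 20)
  expect_equal(am3$cep_id, 1L)   # catchment-sharing CEP
})

test_that("units finalize with timestep areas and majority regions", {
  tw <- two_cep_world()
  w <- tw$w
  band <- tw$land & w$Y <= w$coast_y + 0.5 & w$X >= 14.2 & w$X <= 18
  patches <- extract_patches(band, w$grid)
  a <- assign_direct(patches, tw$ceps)
  expect_false(anyNA(a$type))
  exts <- list("t0" = band, "t1" = band)
  # patch overlapping two regions 70/30 goes to the 70% one
  split_x <- stats::quantile(w$X[band], 0.3)
  regions <- vector_layer(
    list(list(list(rect_ring(0, 0, split_x, 40))),
         list(list(rect_ring(split_x, 0, 50 - split_x, 40)))),
    data.frame(region = c("minor", "major")), "polygon")
  units <- finalize_units(a, patches, exts, regions)
  expect_equal(nrow(units$table), 1)
  expect_equal(units$table$region, "major")
  expect_equal(units$table$area_t0, units$table$area_t1)

  # unassigned patch is a pipeline error
  a_bad <- a; a_bad$type <- NA_character_
  expect_error(finalize_units(a_bad, patches, exts), "unassigned")
})

test_that("the pipeline partitions the union extent exactly into units", {
  res <- world_pipeline()
  union_ext <- Reduce(`|`, res$scene$extents)
  total_unit <- sum(res$units$table$n_cells)
  expect_equal(total_unit, sum(union_ext))
  # every union cell carries exactly one unit label
  expect_equal(sum(res$units$label > 0), sum(union_ext))
  first_ts <- names(res$scene$extents)[1]
  expect_equal(sum(res$units$table[[paste0("area_", first_ts)]]),
               sum(union_ext) * res$scene$grid$cellsize^2,
               tolerance = 1e-9)
  # reassignment with identical labels is idempotent
  a <- assign_direct(res$patches, res$ceps)
  a2 <- assign_orphans(a, res$patches, res$ceps, NULL, 20)
  u2 <- finalize_units(a2, res$patches, res$scene$extents,
                       default_regions(res$scene$grid),
                       merge_delta_units(res$ceps, res$delta_flags$delta_ids))
  expect_equal(sort(u2$table$n_cells), sort(res$units$table$n_cells))
  expect_equal(table(u2$table$type), table(res$units$table$type))
})
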