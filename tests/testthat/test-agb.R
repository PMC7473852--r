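test_that("unit mean AGB averages cell-centre points inside each unit", {
  g <- mt_grid(10, 10, 0, 0, 1)
  lab <- matrix(0L, 10, 10)
  lab[2:3, 2:3] <- 1L          # unit 1: 4 cells
  lab[6, 6:7] <- 2L            # unit 2: cells {50, 150}
  lab[9, 9] <- 3L              # unit 3: off the valid raster
  units <- structure(list(
    grid = g, label = lab,
    cells = list(which(lab == 1L), which(lab == 2L), which(lab == 3L)),
    table = data.frame(unit_id = 1:3, type = "deltaic"),
    timesteps = character(0)), class = "typology_units")
  v <- matrix(100, 10, 10)
  v[6, 6] <- 50; v[6, 7] <- 150
  v[9, 9] <- -9999
  agb <- raster_field(v, g, nodata = -9999)
  expect_message(out <- unit_mean_agb(units, agb), "excluded")
  expect_equal(out$table$mean_agb[1], 100)
  expect_equal(out$table$mean_agb[2], 100)      # mean of 50 and 150
  expect_true(is.na(out$table$mean_agb[3]))
  expect_equal(out$table$n_agb_points, c(4L, 2L, 0L))
})

test_that("GLS fitting: contracts, df identity, degenerate input", {
  d <- simulate_agb_units(c(deltaic = 30, estuarine = 40, lagoonal = 25,
                            open_coast = 50), seed = 2)
  m <- fit_agb_gls(d)
  expect_equal(m$df_num, 3)
  expect_equal(m$df_den, nrow(d) - 4)
  expect_equal(unname(m$variance_multipliers[1]), 1)
  expect_gte(nagelkerke_r2(m), 0)

  single <- rbind(data.frame(unit_id = 1, type = "deltaic", mean_agb = 50),
                  data.frame(unit_id = 2:6, type = "estuarine",
                             mean_agb = c(60, 61, 62, 63, 64)))
  expect_error(fit_agb_gls(single), "deltaic")
  flat <- data.frame(unit_id = 1:8, type = rep(c("a", "b"), 4),
                     mean_agb = 100)
  expect_error(fit_agb_gls(flat), "zero-variance")

  # REML fits are rejected by the likelihood R2
  mr <- fit_agb_gls(d, method = "REML")
  expect_error(nagelkerke_r2(mr), "REML")
})

test_that("GLS estimates agree with the closed-form group statistics", {
  # with a saturated one-way mean structure and per-type variances, the
  # ML solution is the per-group means and (MLE) variances: an
  # independent oracle for the gls route
  d <- simulate_agb_units(c(lagoonal = 40, open_coast = 60), seed = 3)
  m <- fit_agb_gls(d)
  s <- sqrt(d$mean_agb)
  for (ty in c("lagoonal", "open_coast"))
    expect_equal(unname(m$emm[ty]), mean(s[d$type == ty]), tolerance = 1e-6)
  sd_ml <- vapply(c("lagoonal", "open_coast"), function(ty) {
    x <- s[d$type == ty]
    sqrt(mean((x - mean(x))^2))
  }, numeric(1))
  got_ratio <- m$variance_multipliers[["open_coast"]]
  expect_equal(got_ratio, sd_ml[["open_coast"]] / sd_ml[["lagoonal"]],
               tolerance = 1e-3)
  # F equals the two-group Wald statistic built from the group summaries
  n <- table(d$type)[c("lagoonal", "open_coast")]
  mdiff <- mean(s[d$type == "lagoonal"]) - mean(s[d$type == "open_coast"])
  F_oracle <- mdiff^2 / sum(sd_ml^2 / as.numeric(n))
  expect_equal(m$F_stat, F_oracle, tolerance = 0.05)
})

test_that("Nagelkerke R2: null and signal regimes", {
  # no planted effect: R2 stays near zero at n = 1000
  r2s <- vapply(1:5, function(s) {
    flat <- simulate_agb_units(
      c(deltaic = 250, estuarine = 250, lagoonal = 250, open_coast = 250),
      mean = c(deltaic = 100, estuarine = 100, lagoonal = 100,
               open_coast = 100),
      sd = c(deltaic = 70, estuarine = 70, lagoonal = 70, open_coast = 70),
      seed = s)
    nagelkerke_r2(fit_agb_gls(flat))
  }, numeric(1))
  expect_lt(mean(r2s), 0.02)
  # strong effect at tiny SDs approaches 1
  sharp <- simulate_agb_units(
    c(deltaic = 100, estuarine = 100, lagoonal = 100, open_coast = 100),
    sd = c(deltaic = 1, estuarine = 1, lagoonal = 1, open_coast = 1),
    seed = 1)
  expect_gt(nagelkerke_r2(fit_agb_gls(sharp)), 0.9)
  # identical likelihoods give exactly zero
  fake <- list(method = "ML", n = 100, logLik_fit = -50, logLik_null = -50)
  expect_equal(nagelkerke_r2(fake), 0)
})

test_that("homoscedastic data yields variance multipliers near one", {
  d <- simulate_agb_units(
    c(deltaic = 200, estuarine = 200, lagoonal = 200, open_coast = 200),
    mean = c(deltaic = 110, estuarine = 120, lagoonal = 80,
             open_coast = 100),
    sd = c(deltaic = 60, estuarine = 62.7, lagoonal = 51.2,
           open_coast = 57.2),   # equal sqrt-scale sd by the delta method
    seed = 4)
  m <- fit_agb_gls(d)
  expect_true(all(abs(m$variance_multipliers - 1) < 0.25))
})

test_that("post-hoc contrasts: identical groups share letters; alpha = 1 splits all", {
  d <- simulate_agb_units(c(lagoonal = 60, open_coast = 60),
                          mean = c(lagoonal = 100, open_coast = 100),
                          sd = c(lagoonal = 60, open_coast = 60), seed = 5)
  m <- fit_agb_gls(d)
  ph <- posthoc_contrasts(m)
  expect_lt(abs(ph$contrasts$estimate[1]), 0.5)
  expect_false(ph$contrasts$significant[1])
  expect_equal(unname(ph$letters["lagoonal"]), unname(ph$letters["open_coast"]))

  d4 <- simulate_agb_units(c(deltaic = 100, estuarine = 100,
                             lagoonal = 100, open_coast = 100), seed = 6)
  m4 <- fit_agb_gls(d4)
  ph_all <- posthoc_contrasts(m4, alpha = 1)
  expect_true(all(ph_all$contrasts$significant))
  expect_equal(length(unique(ph_all$letters)), 4)
  # six pairwise contrasts for four types
  expect_equal(nrow(ph_all$contrasts), 6)
})

test_that("scene AGB raster reproduces planted unit means", {
  res <- world_pipeline()
  units <- res$units
  tu <- res$scene$truth$units
  planted <- res$scene$config$agb_mean
  for (u in seq_len(nrow(units$table))) {
    ty <- units$table$type[u]
    expect_lt(abs(units$table$mean_agb[u] - planted[[ty]]) / planted[[ty]],
              0.15)
  }
})
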