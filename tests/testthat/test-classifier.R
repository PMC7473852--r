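# quick covariate-row simulator used where the real pipeline would be
# overkill (e.g. checking that the published training composition is
# accepted): class structure lives in v6 and v8, the rest is noise
sim_cov_rows <- function(n_bay, n_estuary, n_lagoon, seed = 1) {
  withr::local_seed(seed)
  one <- function(n, cls, v6, v8) {
    d <- as.data.frame(matrix(stats::runif(n * 10), n, 10))
    names(d) <- mangrovetyper:::covariate_names()
    d$v6_closure_ratio <- stats::runif(n, v6[1], v6[2])
    d$v8_n_flowlines <- rep(v8, n)
    d$class <- rep(cls, n)
    d
  }
  rbind(one(n_bay, "bay", c(0.8, 2), 0L),
        one(n_estuary, "estuary", c(0.5, 1.2), 1L),
        one(n_lagoon, "lagoon", c(0.02, 0.3), 0L))
}

test_that("outlet counting matches planted river structure", {
  sc <- world_scene()
  pr <- world_processed()
  tm <- pr$truth_match
  for (cls in c("delta", "estuary", "lagoon", "bay")) {
    ids <- tm$cep_id[tm$class == cls & tm$matched]
    got <- unname(pr$outlets[as.character(ids)])
    want <- switch(cls, delta = sc$config$delta_distributaries,
                   estuary = 1L, 0L)
    expect_equal(got, rep(want, length(ids)), info = cls)
  }
  # >2 outlets is the delta candidacy line
  expect_true(all(pr$outlets[as.character(tm$cep_id[tm$class == "delta"])] > 2))
  expect_true(all(pr$outlets[as.character(tm$cep_id[tm$class != "delta"])] <= 2))
})

test_that("delta flagging honours the list, the rule and the hook", {
  sc <- world_scene()
  pr <- world_processed()
  tm <- pr$truth_match
  truth_deltas <- sort(tm$cep_id[tm$class == "delta"])

  fl <- flag_deltas(pr$ceps, sc$flowlines)
  expect_equal(sort(fl$delta_ids), truth_deltas)
  expect_equal(sort(c(fl$delta_ids, fl$remaining_ids)),
               sort(pr$ceps$table$id))

  # a candidate rejected by the hook returns to the forest pool
  fl0 <- flag_deltas(pr$ceps, sc$flowlines,
                     confirm = function(ids) rep(FALSE, length(ids)))
  expect_length(fl0$delta_ids, 0)
  expect_setequal(fl0$remaining_ids, pr$ceps$table$id)

  # listed ids are unioned in; unknown listed ids warn
  fl1 <- flag_deltas(pr$ceps, sc$flowlines,
                     known_delta_ids = pr$ceps$table$id[1])
  expect_true(pr$ceps$table$id[1] %in% fl1$delta_ids)
  expect_warning(flag_deltas(pr$ceps, sc$flowlines,
                             known_delta_ids = 999L), "not found")

  # no rivers, no list: nothing flagged
  empty_fl <- vector_layer(list(), data.frame(), "polyline")
  expect_length(flag_deltas(pr$ceps, empty_fl)$delta_ids, 0)
})

test_that("delta units merge by extent with overlap tie-breaking", {
  pr <- world_processed()
  ids <- pr$ceps$table$id[1:3]
  # no extents: one unit per CEP
  m0 <- merge_delta_units(pr$ceps, ids)
  expect_equal(nrow(m0), 3)
  expect_equal(length(unique(m0$unit_id)), 3)
  # one extent covering all three: a single unit
  g <- pr$ceps$grid
  all_ext <- vector_layer(list(list(list(rect_ring(
    g$xll, g$yll, g$ncol * g$cellsize, g$nrow * g$cellsize)))),
    data.frame(name = "everything"), "polygon")
  m1 <- merge_delta_units(pr$ceps, ids, all_ext)
  expect_equal(length(unique(m1$unit_id)), 1)
  # empty id set
  expect_equal(nrow(merge_delta_units(pr$ceps, integer(0))), 0)
})

test_that("forest training contracts: separability, chance, composition", {
  # perfectly separable one-variable toy
  toy <- sim_cov_rows(30, 0, 30, seed = 2)
  toy$v6_closure_ratio[toy$class == "bay"] <- stats::runif(30, 0.9, 1)
  toy$v6_closure_ratio[toy$class == "lagoon"] <- stats::runif(30, 0, 0.1)
  run <- train_rf(toy, n_trees = 100, seed = 3)
  expect_equal(run$validation_accuracy, 1)

  # shuffled labels: holdout accuracy near chance for 3 balanced classes
  noise <- sim_cov_rows(60, 60, 60, seed = 4)
  noise$v6_closure_ratio <- stats::runif(180)
  noise$v8_n_flowlines <- 0L
  noise$class <- sample(noise$class)
  runn <- train_rf(noise, n_trees = 200, seed = 5)
  expect_gt(runn$validation_accuracy, 0.05)
  expect_lt(runn$validation_accuracy, 0.65)

  # the published composition (800/71/300, n = 1171) is accepted and logged
  big <- sim_cov_rows(800, 300, 71, seed = 6)
  runb <- train_rf(big, n_trees = 50, seed = 7)
  expect_equal(runb$training_counts,
               list(bay = 800L, estuary = 300L, lagoon = 71L))
  expect_gt(runb$validation_accuracy, 0.9)

  # class with < 2 rows errors, naming the class
  tiny <- sim_cov_rows(5, 5, 1, seed = 8)
  expect_error(train_rf(tiny, n_trees = 10), "lagoon")
  expect_error(train_rf(big, n_trees = 10, holdout_fraction = 1.2),
               "holdout_fraction")
})

test_that("classification returns labels with votes and strict contracts", {
  train <- sim_cov_rows(40, 40, 40, seed = 9)
  run <- train_rf(train, n_trees = 200, seed = 10)
  # a row identical to a training lagoon is a lagoon with a vote majority
  lag_row <- train[train$class == "lagoon", ][1, ]
  lag_row$cep_id <- 1L
  out <- classify_ceps(run, lag_row)
  expect_equal(out$class, "lagoon")
  expect_gte(out$vote_lagoon, 0.5)
  # empty input: empty output
  out0 <- classify_ceps(run, train[0, ])
  expect_equal(nrow(out0), 0)
  # covariate mismatch errors
  expect_error(classify_ceps(run, data.frame(cep_id = 1, bogus = 2)),
               "mismatch")
})

test_that("the review hook is a truth oracle with a controlled error rate", {
  truth <- stats::setNames(rep(c("bay", "lagoon"), each = 50), 1:100)
  r0 <- review_hook(1:100, truth, error_rate = 0, seed = 1)
  expect_equal(r0$class, unname(truth))
  r1 <- review_hook(1:100, truth, error_rate = 1, seed = 1,
                    classes = c("bay", "lagoon"))
  expect_true(all(r1$class != truth))           # two classes: complement
  r01 <- review_hook(1:100, truth, error_rate = 0.1, seed = 2)
  flips <- sum(r01$class != truth)
  expect_gte(flips, 2); expect_lte(flips, 20)   # Binomial(100, .1) bounds
  expect_error(review_hook(1:3, NULL), "truth")
})

test_that("the second pass honours corrections, flags disagreements and is deterministic", {
  train <- sim_cov_rows(40, 40, 40, seed = 11)
  run1 <- train_rf(train, n_trees = 200, seed = 12)
  pool <- sim_cov_rows(20, 20, 20, seed = 13)
  truth_pool <- stats::setNames(pool$class, seq_len(nrow(pool)))
  pool$class <- NULL
  pool$cep_id <- seq_len(nrow(pool))
  labels1 <- classify_ceps(run1, pool)

  # review everything with a perfect hook: final labels equal truth
  corr <- review_hook(pool$cep_id, truth_pool, error_rate = 0, seed = 1)
  fin <- second_pass(run1, train, corr, pool, labels1, n_trees2 = 200,
                     seed = 14)
  expect_equal(fin$class[match(pool$cep_id, fin$cep_id)],
               unname(truth_pool))
  expect_true(all(fin$provenance == "review"))
  expect_false(any(fin$flagged))

  # review nothing: warning, and agreement between passes leaves no flags
  expect_warning(
    fin2 <- second_pass(run1, train, NULL, pool, labels1, n_trees2 = 200,
                        seed = 14),
    "empty corrections")
  agree <- fin2$provenance == "pass1"
  expect_false(any(fin2$flagged[agree]))

  # determinism under identical seeds
  fin3 <- second_pass(run1, train, corr, pool, labels1, n_trees2 = 200,
                      seed = 14)
  expect_identical(fin, fin3)
})

# heavily overlapping covariate classes: a deliberately fallible model,
# the regime where expert review is worth its error rate
sim_overlap_rows <- function(n_per_class, seed = 1) {
  withr::local_seed(seed)
  one <- function(n, cls, v6_range) {
    d <- as.data.frame(matrix(stats::runif(n * 10), n, 10))
    names(d) <- mangrovetyper:::covariate_names()
    d$v6_closure_ratio <- stats::runif(n, v6_range[1], v6_range[2])
    d$v8_n_flowlines <- stats::rbinom(n, 1L, 0.5)
    d$class <- rep(cls, n)
    d
  }
  rbind(one(n_per_class, "bay", c(0.3, 1.2)),
        one(n_per_class, "estuary", c(0.25, 1.1)),
        one(n_per_class, "lagoon", c(0.1, 0.9)))
}

test_that("an imperfect review still lifts a fallible first pass", {
  # overlapping classes keep the first pass well below the hook's 90%
  # accuracy; reviewing everything with a 10%-error hook then improves
  # the final labelling in aggregate over 20 replicate pools
  acc1 <- accF <- 0; n_tot <- 0
  for (s in 1:20) {
    train <- sim_overlap_rows(40, seed = 200 + s)
    run1 <- train_rf(train, n_trees = 150, seed = s)
    pool <- sim_overlap_rows(15, seed = 400 + s)
    truth <- stats::setNames(pool$class, seq_len(nrow(pool)))
    pool$class <- NULL
    pool$cep_id <- seq_len(nrow(pool))
    labels1 <- classify_ceps(run1, pool)
    corr <- review_hook(pool$cep_id, truth, error_rate = 0.1,
                        seed = 500 + s)
    fin <- second_pass(run1, train, corr, pool, labels1, n_trees2 = 150,
                       seed = s)
    fcls <- fin$class[match(pool$cep_id, fin$cep_id)]
    acc1 <- acc1 + sum(labels1$class == truth)
    accF <- accF + sum(fcls == truth)
    n_tot <- n_tot + nrow(pool)
  }
  expect_gte(accF / n_tot, acc1 / n_tot)
})
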