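#' Run the embayment stages on a scene
#'
#' Generalizes the coastline, extracts and filters embayments against the
#' maximal mangrove extent, computes covariates, counts outlets and (for
#' synthetic scenes) matches CEPs to the planted truth.
#'
#' @param scene a `coast_scene`.
#' @param closing_radius,min_area_km2,min_landmass_km2,max_dist_km stage
#'   parameters; defaults from the scene config.
#' @return list: `generalized`, `ceps`, `cov` (covariate table),
#'   `outlets`, `truth_match`, `truth_class` (named by cep id, synthetic
#'   scenes only).
#' @export
process_scene <- function(scene,
                          closing_radius = scene$config$closing_radius_km,
                          min_area_km2 = scene$config$min_cep_area_km2,
                          min_landmass_km2 = scene$config$min_landmass_km2,
                          max_dist_km = scene$config$max_mangrove_dist_km) {
  gen <- generalize_coastline(scene, closing_radius)
  ceps <- extract_embayments(scene, gen, min_area_km2 = min_area_km2)
  union_ext <- Reduce(`|`, scene$extents)
  ceps <- filter_ceps(ceps, scene, union_ext,
                      min_landmass_km2 = min_landmass_km2,
                      max_dist_km = max_dist_km)
  cov <- covariate_table(ceps, scene$flowlines, scene$watersheds,
                         scene$precip)
  outlets <- count_outlets(ceps, id = NULL, flowlines = scene$flowlines)
  tm <- match_truth_embayments(ceps, scene)
  truth_class <- stats::setNames(rep(NA_character_, nrow(ceps$table)),
                                 ceps$table$id)
  hit <- tm[tm$matched, , drop = FALSE]
  truth_class[as.character(hit$cep_id)] <- hit$class
  list(generalized = gen, ceps = ceps, cov = cov, outlets = outlets,
       truth_match = tm, truth_class = truth_class,
       extent_union = union_ext)
}

#' Labelled covariate rows harvested from synthetic scenes
#'
#' Generates `n_scenes` scenes (seeds `seed`, `seed + 1`, ...), runs the
#' embayment stages on each and keeps the truth-labelled bay / estuary /
#' lagoon rows (delta CEPs are removed before forest training, as in the
#' published procedure).
#'
#' @param n_scenes scenes to harvest.
#' @param config a [scene_config()] shared by all scenes.
#' @param seed base seed.
#' @return data.frame: `class` plus the v1..v10 covariates.
#' @export
training_covariates <- function(n_scenes = 2L, config = scene_config(),
                                seed = 1L) {
  rows <- list()
  for (s in seq_len(n_scenes)) {
    sc <- generate_scene(config, seed = seed + s - 1L)
    pr <- process_scene(sc)
    cls <- pr$truth_class[as.character(pr$cov$cep_id)]
    keep <- !is.na(cls) & cls != "delta"
    if (!any(keep)) next
    block <- pr$cov[keep, , drop = FALSE]
    block$class <- ifelse(cls[keep] == "bay", "bay",
                          ifelse(cls[keep] == "estuary", "estuary", "lagoon"))
    rows[[s]] <- block
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Default two-region layer for a grid
#'
#' Splits the domain at mid-longitude into `west` and `east` rectangles —
#' a stand-in for a config-supplied region layer.
#'
#' @param grid an [mt_grid()].
#' @return polygon [vector_layer()] with a `region` attribute.
#' @export
default_regions <- function(grid) {
  w <- grid$ncol * grid$cellsize
  h <- grid$nrow * grid$cellsize
  rect <- function(x0, x1) list(list(cbind(c(x0, x1, x1, x0) + grid$xll,
                                           c(0, 0, h, h) + grid$yll)))
  vector_layer(list(rect(0, w / 2), rect(w / 2, w)),
               data.frame(region = c("west", "east"),
                          stringsAsFactors = FALSE), "polygon")
}

#' Run the full typology pipeline on a synthetic scene
#'
#' End-to-end orchestration: scene generation, embayment delineation and
#' filtering, delta flagging by the outlet rule, two-pass random-forest
#' classification (trained on covariates harvested from independent
#' scenes, with the mechanised review hook playing the visual-inspection
#' role), patch assignment, sedimentary classification, extent-change
#' accounting and the AGB attribution.
#'
#' @param config a [scene_config()].
#' @param seed integer seed driving every stage.
#' @param n_trees forest size per pass (toy scale; hundreds of trees are
#'   statistically indistinguishable from the published 100,000 here).
#' @param n_training_scenes scenes harvested for forest training.
#' @param review_error_rate error rate of the mechanised review hook.
#' @param out_dir optional directory; when given, tables and layers are
#'   written there as CSV / GeoJSON / ASCII grids.
#' @return list with every intermediate product (scene, ceps, labels,
#'   units, sediment model, change table, agb fit when estimable).
#' @export
run_pipeline <- function(config = scene_config(), seed = 1L,
                         n_trees = 500L, n_training_scenes = 2L,
                         review_error_rate = 0, out_dir = NULL) {
  t0 <- Sys.time()
  log_stage <- function(...) message(sprintf("[%5.1fs] ",
    as.numeric(difftime(Sys.time(), t0, units = "secs"))), ...)

  scene <- generate_scene(config, seed)
  log_stage("scene: ", nrow(scene$truth$embayments), " embayments, ",
            nrow(scene$truth$units), " units")
  pr <- process_scene(scene)
  ceps <- pr$ceps
  log_stage("ceps: ", nrow(ceps$table), " retained")

  fl <- flag_deltas(ceps, scene$flowlines)
  train <- training_covariates(n_training_scenes, config,
                               seed = seed + 5000L)
  run1 <- train_rf(train, n_trees = n_trees, seed = seed + 11L)
  pool <- pr$cov[pr$cov$cep_id %in% fl$remaining_ids, , drop = FALSE]
  labels1 <- classify_ceps(run1, pool)

  truth <- pr$truth_class
  truth[is.na(truth)] <- "bay"   # unmatched spurious indents review as bays
  reviewed_ids <- pool$cep_id[labels1$class != "bay" |
                                seq_len(nrow(pool)) %in%
                                seq_len(min(500L, nrow(pool)))]
  corrections <- review_hook(reviewed_ids, truth,
                             error_rate = review_error_rate,
                             seed = seed + 12L)
  final <- second_pass(run1, train, corrections, pool, labels1,
                       n_trees2 = n_trees, seed = seed + 13L,
                       review = function(ids)
                         review_hook(ids, truth,
                                     error_rate = review_error_rate,
                                     seed = seed + 14L))
  ceps$table$class <- "unassigned"
  ceps$table$class[match(fl$delta_ids, ceps$table$id)] <- "delta"
  ceps$table$class[match(final$cep_id, ceps$table$id)] <- final$class
  log_stage("classified: ",
            paste(names(table(ceps$table$class)), table(ceps$table$class),
                  sep = "=", collapse = ", "))

  patches <- extract_patches(pr$extent_union, scene$grid)
  patches <- split_patches(patches, ceps)
  hits <- flowline_cep_hits(ceps, scene$flowlines)
  catchments <- lapply(ceps$table$id, function(id)
    build_catchment(ceps, id, scene$flowlines, scene$watersheds,
                    hits = hits))
  assign <- assign_direct(patches, ceps)
  assign <- assign_orphans(assign, patches, ceps, catchments,
                           max_dist_km = config$max_mangrove_dist_km)
  delta_map <- merge_delta_units(ceps, fl$delta_ids)
  units <- finalize_units(assign, patches, scene$extents,
                          regions = default_regions(scene$grid),
                          delta_units = delta_map)
  log_stage("units: ", nrow(units$table))

  sites <- sample_fields_at_sites(scene$sites, scene$tide, scene$spm)
  sed_model <- fit_sediment_glm(sites)
  units <- classify_sediment(sed_model, units, scene$tide, scene$spm)

  change <- tabulate_areas(units)
  ts <- names(scene$extents)
  shares <- type_shares(change, ts[length(ts)])
  changes <- percent_change(change, ts[1L], ts[length(ts)], "type")

  units <- unit_mean_agb(units, scene$agb)
  agb_fit <- tryCatch(
    fit_agb_gls(units$table[, c("type", "mean_agb")]),
    error = function(e) {
      log_stage("AGB model not estimable at this scale: ",
                conditionMessage(e))
      NULL
    })

  out <- list(scene = scene, process = pr, ceps = ceps,
              delta_flags = fl, rf_run = run1, labels = final,
              patches = patches, units = units, sediment_model = sed_model,
              change_table = change, type_shares = shares,
              type_changes = changes, agb_model = agb_fit)
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    utils::write.csv(ceps$table, file.path(out_dir, "ceps.csv"),
                     row.names = FALSE)
    utils::write.csv(cbind(pr$cov), file.path(out_dir, "covariates.csv"),
                     row.names = FALSE)
    utils::write.csv(data.frame(final), file.path(out_dir, "labels.csv"),
                     row.names = FALSE)
    utils::write.csv(units$table, file.path(out_dir, "units.csv"),
                     row.names = FALSE)
    utils::write.csv(change, file.path(out_dir, "change_table.csv"),
                     row.names = FALSE)
    write_vector(cep_to_layer(ceps), file.path(out_dir, "ceps.geojson"))
    log_stage("outputs written to ", out_dir)
  }
  log_stage("done")
  out
}
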