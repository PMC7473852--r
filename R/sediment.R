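#' Sample tide and SPM fields at training sites
#'
#' Each site takes the M2 amplitude and the across-band mean SPM of the
#' nearest valid (non-nodata) raster cell within `radius_km`; sites with no
#' valid cell in reach are dropped with a warning.
#'
#' @param sites data.frame with `x`, `y` (km) and any label columns.
#' @param tide single-band [raster_field()] (m).
#' @param spm [raster_field()] of SPM (g m^-3); multi-band stacks (e.g.
#'   240 monthly rasters) are averaged across bands per cell.
#' @param radius_km search radius for a valid cell.
#' @return `sites` with `tide_m` and `spm_gm3` columns appended.
#' @export
sample_fields_at_sites <- function(sites, tide, spm, radius_km = 10) {
  tv <- sample_raster(tide, sites$x, sites$y, radius_km)
  sv <- sample_raster(spm, sites$x, sites$y, radius_km)
  drop <- is.na(tv) | is.na(sv)
  if (any(drop))
    warning(sum(drop), " site(s) dropped: no valid raster cell within ",
            radius_km, " km")
  out <- sites[!drop, , drop = FALSE]
  out$tide_m <- tv[!drop]
  out$spm_gm3 <- sv[!drop]
  rownames(out) <- NULL
  out
}

#' Fit the sedimentary-setting logistic model
#'
#' Riverine (estuarine/deltaic) sites are removed, then a binomial GLM
#' with logit link is fitted to the remaining sites:
#' `terrigenous ~ tide_m + spm_gm3`, terrigenous coded 1. Both predictors
#' are always retained regardless of significance. The deviance pseudo-R^2
#' is (null deviance - residual deviance) / null deviance, and the
#' confusion matrix at the classification threshold is recorded.
#'
#' @param sites data.frame with `typological_status`
#'   (riverine/non_riverine), `sediment_label` (terrigenous/carbonate),
#'   `tide_m`, `spm_gm3`.
#' @param threshold probability cut for the recorded confusion matrix.
#' @return object of class `sediment_model`: coefficients, standard
#'   errors, z and p values, deviances, pseudo_r2, n_fit, confusion,
#'   separation flag and the underlying `glm` fit.
#' @export
fit_sediment_glm <- function(sites, threshold = 0.5) {
  dat <- sites[sites$typological_status != "riverine", , drop = FALSE]
  if (nrow(dat) == 0L) stop("no non-riverine sites to fit")
  yy <- as.integer(dat$sediment_label == "terrigenous")
  if (length(unique(yy)) < 2L)
    stop("single-class input: both terrigenous and carbonate sites required")
  separation <- FALSE
  fit <- withCallingHandlers(
    stats::glm(yy ~ tide_m + spm_gm3, data = dat, family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1",
                conditionMessage(w))) {
        separation <<- TRUE
        invokeRestart("muffleWarning")
      }
    })
  beta <- stats::coef(fit)
  cap <- 50
  if (separation) {
    warning("complete or quasi-complete separation: coefficients capped at |",
            cap, "| and flagged")
    beta <- pmin(pmax(beta, -cap), cap)
  }
  sm <- summary(fit)$coefficients
  p_hat <- stats::fitted(fit)
  pred <- ifelse(p_hat >= threshold, 1L, 0L)
  confusion <- table(truth = factor(yy, c(0, 1),
                                    c("carbonate", "terrigenous")),
                     predicted = factor(pred, c(0, 1),
                                        c("carbonate", "terrigenous")))
  structure(list(
    beta = c(intercept = unname(beta[1L]), tide = unname(beta[2L]),
             spm = unname(beta[3L])),
    se = stats::setNames(sm[, "Std. Error"], c("intercept", "tide", "spm")),
    z = stats::setNames(sm[, "z value"], c("intercept", "tide", "spm")),
    p = stats::setNames(sm[, "Pr(>|z|)"], c("intercept", "tide", "spm")),
    D_null = fit$null.deviance, D_resid = fit$deviance,
    pseudo_r2 = deviance_pseudo_r2(fit$null.deviance, fit$deviance),
    n_fit = nrow(dat), confusion = confusion, threshold = threshold,
    separation = separation, fit = fit), class = "sediment_model")
}

#' Deviance pseudo-R-squared
#'
#' `(D_null - D_resid) / D_null`; zero when the predictors explain no
#' deviance.
#'
#' @param d_null,d_resid null and residual deviance.
#' @return proportion of null deviance explained.
#' @export
deviance_pseudo_r2 <- function(d_null, d_resid) {
  if (d_null <= 0) stop("null deviance must be positive")
  (d_null - d_resid) / d_null
}

#' @export
print.sediment_model <- function(x, ...) {
  cat("<sediment_model> n =", x$n_fit, " pseudo-R2 =",
      round(x$pseudo_r2, 3), if (x$separation) "(separation flagged)" else "",
      "\n")
  print(round(cbind(beta = x$beta, se = x$se, z = x$z, p = x$p), 4))
  invisible(x)
}

#' Classify units as terrigenous or carbonate
#'
#' Deltaic and estuarine units are terrigenous unconditionally (river-fed
#' minerogenic settings); lagoonal and open-coast units are terrigenous
#' when the fitted probability at their representative point reaches the
#' threshold (inclusive: ties go to the majority class, terrigenous).
#' Units with no valid raster cell in reach are flagged and classed
#' terrigenous with a warning.
#'
#' @param model a [fit_sediment_glm()] result.
#' @param units a `typology_units` object.
#' @param tide,spm the environmental rasters.
#' @param threshold probability cut on P(terrigenous), default 0.5.
#' @param radius_km sampling radius at the representative point.
#' @return `units` with `sediment`, `p_terrigenous` and `sediment_flag`
#'   columns on the table.
#' @export
classify_sediment <- function(model, units, tide, spm, threshold = 0.5,
                              radius_km = 10) {
  n <- nrow(units$table)
  sed <- character(n); pterr <- rep(NA_real_, n); flag <- logical(n)
  reps <- t(vapply(seq_len(n), function(u) unit_rep_point(units, u),
                   numeric(2)))
  tv <- sample_raster(tide, reps[, 1L], reps[, 2L], radius_km)
  sv <- sample_raster(spm, reps[, 1L], reps[, 2L], radius_km)
  b <- model$beta
  for (u in seq_len(n)) {
    ty <- units$table$type[u]
    if (ty %in% c("deltaic", "estuarine")) {
      sed[u] <- "terrigenous"
      next
    }
    if (is.na(tv[u]) || is.na(sv[u])) {
      flag[u] <- TRUE
      sed[u] <- "terrigenous"
      next
    }
    pterr[u] <- stats::plogis(b[["intercept"]] + b[["tide"]] * tv[u] +
                                b[["spm"]] * sv[u])
    sed[u] <- if (pterr[u] >= threshold) "terrigenous" else "carbonate"
  }
  if (any(flag))
    warning(sum(flag), " unit(s) unsampled; classed terrigenous ",
            "(majority class) and flagged")
  units$table$sediment <- sed
  units$table$p_terrigenous <- pterr
  units$table$sediment_flag <- flag
  units
}

#' Simulate sedimentary training sites from the logistic model
#'
#' Independent site generator for parameter-recovery work: tide and SPM
#' drawn uniformly over realistic coastal ranges, labels Bernoulli under
#' the supplied logit coefficients (terrigenous = 1).
#'
#' @param n site count.
#' @param beta (intercept, tide, SPM) on the logit scale.
#' @param seed integer seed.
#' @param tide_range,spm_range uniform sampling ranges (m, g m^-3).
#' @return data.frame ready for [fit_sediment_glm()].
#' @export
simulate_sediment_sites <- function(n, beta = c(-2, 1.5, 0.1), seed = 1L,
                                    tide_range = c(0.2, 3.5),
                                    spm_range = c(2, 8)) {
  with_seed(seed, {
    tide <- stats::runif(n, tide_range[1L], tide_range[2L])
    spm <- stats::runif(n, spm_range[1L], spm_range[2L])
    p <- stats::plogis(beta[1L] + beta[2L] * tide + beta[3L] * spm)
    data.frame(site_id = seq_len(n), x = NA_real_, y = NA_real_,
               typological_status = "non_riverine",
               sediment_label = ifelse(stats::rbinom(n, 1L, p) == 1L,
                                       "terrigenous", "carbonate"),
               tide_m = tide, spm_gm3 = spm, stringsAsFactors = FALSE)
  })
}
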