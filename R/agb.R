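#' Attribute mean above-ground biomass to units
#'
#' The AGB raster is treated as points at cell centres; each unit's mean
#' is taken over the valid cells falling inside it. Units covering no
#' valid cell get NA (excluded from modelling; count reported via
#' message).
#'
#' @param units a `typology_units` object.
#' @param agb single-band [raster_field()] (Mg ha^-1).
#' @return `units` with `mean_agb` and `n_agb_points` columns.
#' @export
unit_mean_agb <- function(units, agb) {
  v <- rf_band(agb, 1L)
  n <- nrow(units$table)
  m <- rep(NA_real_, n); np <- integer(n)
  for (u in seq_len(n)) {
    vals <- v[units$cells[[u]]]
    vals <- vals[!is.na(vals) & vals != agb$nodata]
    np[u] <- length(vals)
    if (length(vals)) m[u] <- mean(vals)
  }
  if (any(np == 0L))
    message(sum(np == 0L), " unit(s) cover no AGB cell; excluded downstream")
  units$table$mean_agb <- m
  units$table$n_agb_points <- np
  units
}

#' Simulate per-unit mean AGB under the variance-structured model
#'
#' The analysis models the square root of unit mean AGB as Gaussian with a
#' type-specific mean and variance, so the generator draws on that scale:
#' `sqrt(AGB) ~ N(sqrt(m_type), s_type)` with `s_type = sd_type /
#' (2 sqrt(m_type))` (delta method), which reproduces the requested
#' data-scale mean and standard deviation. Draws are truncated just above
#' zero. Defaults are the published per-type means and SDs (Mg ha^-1).
#'
#' @param n_per_type named unit counts per type.
#' @param mean,sd named data-scale means and standard deviations.
#' @param seed integer seed.
#' @return data.frame (unit_id, type, mean_agb).
#' @export
simulate_agb_units <- function(n_per_type = c(deltaic = 84, estuarine = 907,
                                              lagoonal = 591,
                                              open_coast = 2193),
                               mean = c(deltaic = 117.3, estuarine = 126.3,
                                        lagoonal = 73.5, open_coast = 111.5),
                               sd = c(deltaic = 73.6, estuarine = 76.3,
                                      lagoonal = 59.8, open_coast = 73.7),
                               seed = 1L) {
  with_seed(seed, {
    rows <- lapply(names(n_per_type), function(ty) {
      n <- n_per_type[[ty]]
      mu <- sqrt(mean[[ty]])
      s <- sd[[ty]] / (2 * sqrt(mean[[ty]]))
      r <- pmax(stats::rnorm(n, mu, s), 0.05)
      data.frame(type = ty, mean_agb = r^2, stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    out <- cbind(unit_id = seq_len(nrow(out)), out)
    rownames(out) <- NULL
    out
  })
}

#' Variance-structured GLS of AGB by mangrove type
#'
#' Fits `sqrt(mean AGB) ~ type` by generalized least squares with a
#' distinct residual variance per type (`nlme::varIdent`), by maximum
#' likelihood so the fit is comparable with its intercept-only null (same
#' variance structure) for the Nagelkerke pseudo-R^2. The overall type
#' effect is the Wald F with `df_num = k - 1` and `df_den = N - k`.
#'
#' @param data data.frame with `type` and `mean_agb` (data scale); NA
#'   rows dropped.
#' @param method `"ML"` (required for likelihood-based R^2) or `"REML"`.
#' @return object of class `agb_model`: per-type estimated marginal means
#'   on the square-root scale, back-transformed means, variance
#'   multipliers (reference type 1), F statistic with df and p, group
#'   counts, log-likelihoods and the underlying `gls` fits.
#' @export
fit_agb_gls <- function(data, method = "ML") {
  dat <- data[!is.na(data$mean_agb), , drop = FALSE]
  dat$type <- factor(dat$type)
  cnt <- table(dat$type)
  if (length(cnt) < 2L) stop("need at least two types")
  if (any(cnt < 2L))
    stop("type '", names(cnt)[which(cnt < 2L)[1L]], "' has a single unit")
  dat$sqrt_agb <- sqrt(dat$mean_agb)
  if (stats::var(dat$sqrt_agb) == 0)
    stop("zero-variance response: F statistic undefined")
  fit <- nlme::gls(sqrt_agb ~ type, data = dat,
                   weights = nlme::varIdent(form = ~ 1 | type),
                   method = method)
  null <- nlme::gls(sqrt_agb ~ 1, data = dat,
                    weights = nlme::varIdent(form = ~ 1 | type),
                    method = method)
  k <- length(cnt)
  N <- nrow(dat)
  beta <- stats::coef(fit)
  V <- stats::vcov(fit)
  # Wald F of the k-1 type contrasts
  sel <- 2:k
  Cb <- beta[sel]
  F_stat <- drop(t(Cb) %*% solve(V[sel, sel, drop = FALSE]) %*% Cb) / (k - 1)
  df_num <- k - 1L
  df_den <- N - k
  # estimated marginal means per type on the sqrt scale
  L <- cbind(1, rbind(0, diag(k - 1)))
  emm <- drop(L %*% beta)
  emm_v <- L %*% V %*% t(L)
  names(emm) <- levels(dat$type)
  vm <- stats::coef(fit$modelStruct$varStruct, unconstrained = FALSE,
                    allCoef = TRUE)
  vm <- vm[match(levels(dat$type), names(vm))]
  structure(list(
    transform = "sqrt",
    emm = emm, emm_vcov = emm_v,
    means_backtransformed = stats::setNames(emm^2, levels(dat$type)),
    variance_multipliers = vm,
    sigma = fit$sigma,
    F_stat = F_stat, df_num = df_num, df_den = df_den,
    p_value = stats::pf(F_stat, df_num, df_den, lower.tail = FALSE),
    group_counts = as.list(cnt), n = N, method = method,
    logLik_fit = as.numeric(stats::logLik(fit)),
    logLik_null = as.numeric(stats::logLik(null)),
    fit = fit, null = null, levels = levels(dat$type)),
    class = "agb_model")
}

#' @export
print.agb_model <- function(x, ...) {
  cat("<agb_model> sqrt(mean AGB) ~ type, varIdent by type (",
      x$method, ")\n", sep = "")
  cat(sprintf("  F(%d, %d) = %.2f, p = %.3g\n", x$df_num, x$df_den,
              x$F_stat, x$p_value))
  cat("  back-transformed means:",
      paste(names(x$means_backtransformed),
            round(x$means_backtransformed, 1), sep = "=", collapse = ", "),
      "\n")
  invisible(x)
}

#' Nagelkerke pseudo-R-squared of the type effect
#'
#' `[1 - (L0/L1)^(2/n)] / [1 - L0^(2/n)]` with ML likelihoods of the null
#' and fitted models. REML fits are rejected: their likelihoods are not
#' comparable across mean structures.
#'
#' @param model an [fit_agb_gls()] result (or any list with
#'   `logLik_fit`, `logLik_null`, `n`, `method`).
#' @return pseudo-R^2 in \[0, 1\].
#' @export
nagelkerke_r2 <- function(model) {
  if (!identical(model$method, "ML"))
    stop("Nagelkerke pseudo-R2 requires ML (not REML) fits")
  n <- model$n
  l0 <- model$logLik_null; l1 <- model$logLik_fit
  num <- 1 - exp((2 / n) * (l0 - l1))
  den <- 1 - exp((2 / n) * l0)
  r2 <- num / den
  min(max(r2, 0), 1)
}

#' Pairwise post-hoc contrasts with a compact letter display
#'
#' All pairwise differences of the estimated marginal means on the
#' square-root scale, multiplicity-adjusted over the Tukey family
#' (studentized range with `k` means and the model's denominator df;
#' `"bonferroni"` and `"none"` available). Groups that cannot be
#' distinguished at `alpha` share a letter.
#'
#' @param model an [fit_agb_gls()] result.
#' @param alpha significance level.
#' @param adjust multiplicity adjustment.
#' @return list: `contrasts` data.frame (pair, estimate, se, t, p_adj,
#'   significant) and `letters` (named by type).
#' @export
posthoc_contrasts <- function(model, alpha = 0.05,
                              adjust = c("tukey", "bonferroni", "none")) {
  adjust <- match.arg(adjust)
  lev <- model$levels
  k <- length(lev)
  pairs <- utils::combn(k, 2)
  m <- ncol(pairs)
  est <- se <- tval <- padj <- numeric(m)
  lab <- character(m)
  for (c0 in seq_len(m)) {
    a <- pairs[1L, c0]; b <- pairs[2L, c0]
    est[c0] <- model$emm[a] - model$emm[b]
    se[c0] <- sqrt(model$emm_vcov[a, a] + model$emm_vcov[b, b] -
                     2 * model$emm_vcov[a, b])
    tval[c0] <- est[c0] / se[c0]
    praw <- 2 * stats::pt(abs(tval[c0]), model$df_den, lower.tail = FALSE)
    padj[c0] <- switch(adjust,
      tukey = stats::ptukey(abs(tval[c0]) * sqrt(2), k, model$df_den,
                            lower.tail = FALSE),
      bonferroni = min(1, praw * m),
      none = praw)
    lab[c0] <- paste(lev[a], lev[b], sep = " - ")
  }
  contrasts <- data.frame(pair = lab, estimate = est, se = se, t = tval,
                          p_adj = padj, significant = padj < alpha,
                          stringsAsFactors = FALSE)
  letters_out <- compact_letters(lev, pairs, padj >= alpha,
                                 order(model$emm))
  list(contrasts = contrasts, letters = letters_out)
}

# compact letter display: maximal cliques of the "not significantly
# different" graph, lettered in increasing-mean order (brute-force subset
# enumeration; fine for the handful of groups used here)
compact_letters <- function(lev, pairs, nonsig, mean_order) {
  k <- length(lev)
  adj <- diag(TRUE, k)
  for (c0 in seq_len(ncol(pairs)))
    adj[pairs[1L, c0], pairs[2L, c0]] <- adj[pairs[2L, c0], pairs[1L, c0]] <-
      nonsig[c0]
  subsets <- list()
  for (size in k:1) {
    for (combo in utils::combn(k, size, simplify = FALSE)) {
      if (all(adj[combo, combo])) {
        covered <- any(vapply(subsets, function(s) all(combo %in% s),
                              logical(1)))
        if (!covered) subsets[[length(subsets) + 1L]] <- combo
      }
    }
  }
  # order cliques by the smallest mean rank they contain
  rank_of <- match(seq_len(k), mean_order)
  cl_rank <- vapply(subsets, function(s) min(rank_of[s]), numeric(1))
  subsets <- subsets[order(cl_rank)]
  out <- stats::setNames(rep("", k), lev)
  for (s in seq_along(subsets))
    out[subsets[[s]]] <- paste0(out[subsets[[s]]], letters[s])
  out
}
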