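#' Mixed-effects models for richness and CFD along the income gradient
#'
#' Fits the inferential models of the analysis: the response (`richness`,
#' `cfd_cultural` or `cfd_regulating`) against the interaction of
#' within-country standardized median income (`z_income`) and community type
#' (`non-invaded` vs `invaded`), an additive country term, and a random
#' intercept per functional urban area. Counts use a negative-binomial
#' distribution with log link (variance `mu + mu^2/theta`, theta estimated
#' jointly, Laplace-approximated ML via glmmTMB); CFD responses use a
#' Gaussian model fitted by REML. Per-term tests are marginal
#' (Type-III-style): Wald chi-square for the negative-binomial model,
#' approximate F with Satterthwaite denominator df for the Gaussian one.
#'
#' Terms with a single observed level (e.g. `country` in a one-country
#' simulation) are dropped automatically. Singular random-effect variances
#' are reported as 0 with a warning; non-convergence sets the `converged`
#' flag, never fails silently.
#'
#' @param data analysis table with columns `fua`, `country`, `type`,
#'   `z_income` and the response (see [assemble_analysis()]).
#' @param response `"richness"`, `"cfd_cultural"` or `"cfd_regulating"`.
#' @param family override the response-implied family: `"nbinom"` or
#'   `"gaussian"` (or `"poisson"`, used by [overdispersion_test()]).
#' @return A `luxury_fit` object: the fitted model plus coefficient table,
#'   per-term tests, random-intercept variance, dispersion parameter and
#'   convergence flag.
#' @export
fit_mixed <- function(data, response = c("richness", "cfd_cultural", "cfd_regulating"),
                      family = NULL) {
  response <- if (is.character(response)) response[1] else response
  if (!response %in% names(data)) stopf("response '%s' not in data", response)
  need <- c("fua", "z_income")
  if (!all(need %in% names(data))) stopf("data needs columns %s", paste(need, collapse = ", "))
  if (length(unique(data$fua)) < 2) stopf("need >= 2 FUAs for a random intercept")
  if (anyNA(data[, intersect(c(need, "type", "country", response), names(data))])) {
    stopf("missing covariates; drop incomplete rows first")
  }
  family <- family %||% if (response == "richness") "nbinom" else "gaussian"
  fixed <- "z_income"
  if ("type" %in% names(data) && length(unique(data$type)) > 1) {
    fixed <- "z_income * type"
  }
  if ("country" %in% names(data) && length(unique(data$country)) > 1) {
    fixed <- paste(fixed, "+ country")
  }
  fml <- stats::as.formula(paste(response, "~", fixed, "+ (1 | fua)"))
  converged <- TRUE
  if (family == "gaussian") {
    mod <- lmerTest::lmer(fml, data = data, REML = TRUE)
    if (lme4::isSingular(mod)) warnf("singular random-effect variance; reported as 0")
    vc <- as.data.frame(lme4::VarCorr(mod))
    ranvar <- vc$vcov[vc$grp == "fua"][1]
    dispersion <- stats::sigma(mod)^2
    co <- summary(mod)$coefficients
    coefs <- data.frame(
      term = rownames(co), estimate = co[, "Estimate"], se = co[, "Std. Error"],
      statistic = co[, "t value"], p = co[, "Pr(>|t|)"],
      stringsAsFactors = FALSE, row.names = NULL
    )
    an <- stats::anova(mod, type = 3)
    tests <- data.frame(
      term = rownames(an), statistic = an[, "F value"], df = an[, "NumDF"],
      den_df = an[, "DenDF"], p = an[, "Pr(>F)"], stat_type = "F",
      stringsAsFactors = FALSE, row.names = NULL
    )
  } else {
    tmb_family <- switch(family,
      nbinom = glmmTMB::nbinom2(), poisson = stats::poisson(),
      stopf("unknown family '%s'", family)
    )
    mod <- glmmTMB::glmmTMB(fml, data = data, family = tmb_family)
    converged <- isTRUE(mod$fit$convergence == 0) && isTRUE(mod$sdr$pdHess)
    if (!converged) warnf("model did not converge cleanly")
    vc <- glmmTMB::VarCorr(mod)$cond$fua
    ranvar <- if (is.null(vc)) 0 else as.numeric(vc[1, 1])
    dispersion <- if (family == "nbinom") stats::sigma(mod) else NA_real_
    co <- summary(mod)$coefficients$cond
    coefs <- data.frame(
      term = rownames(co), estimate = co[, "Estimate"], se = co[, "Std. Error"],
      statistic = co[, "z value"], p = co[, "Pr(>|z|)"],
      stringsAsFactors = FALSE, row.names = NULL
    )
    an <- car::Anova(mod, type = "III")
    tests <- data.frame(
      term = rownames(an), statistic = an[, "Chisq"], df = an[, "Df"],
      den_df = NA_real_, p = an[, "Pr(>Chisq)"], stat_type = "Wald chi-square",
      stringsAsFactors = FALSE, row.names = NULL
    )
  }
  structure(
    list(
      model = mod, response = response, family = family, formula = fml,
      coefficients = coefs, tests = tests, ranef_variance = ranvar,
      dispersion = dispersion, converged = converged,
      n = nrow(data), n_fua = length(unique(data$fua))
    ),
    class = "luxury_fit"
  )
}

#' @export
print.luxury_fit <- function(x, ...) {
  cat(sprintf(
    "Mixed model for %s (%s), %d cells in %d FUAs%s\n",
    x$response, x$family, x$n, x$n_fua,
    if (!x$converged) " [NOT CONVERGED]" else ""
  ))
  cat(sprintf("  FUA random-intercept variance: %0.4f", x$ranef_variance))
  if (!is.na(x$dispersion)) cat(sprintf("; dispersion: %0.3f", x$dispersion))
  cat("\nCoefficients:\n")
  print(x$coefficients, digits = 4)
  invisible(x)
}

#' @export
summary.luxury_fit <- function(object, ...) {
  print(object)
  cat(sprintf("\nPer-term %s tests (marginal):\n", object$tests$stat_type[1]))
  print(object$tests, digits = 4)
  invisible(object)
}

#' @export
coef.luxury_fit <- function(object, ...) {
  stats::setNames(object$coefficients$estimate, object$coefficients$term)
}

#' @export
residuals.luxury_fit <- function(object, type = c("response", "pearson"), ...) {
  type <- match.arg(type)
  stats::residuals(object$model, type = type)
}

#' Overdispersion check for the count model
#'
#' Fits the Poisson analogue of the richness model and compares the sum of
#' squared Pearson residuals to a chi-square with the residual degrees of
#' freedom. A ratio well above 1 (small p) indicates the variance exceeds
#' the Poisson mean, and a negative-binomial family is recommended.
#'
#' @param data analysis table (see [fit_mixed()]).
#' @param response count response column (default `"richness"`).
#' @return List: `statistic` (Pearson chi-square), `df`, `ratio`, `p`,
#'   `recommend_nb`.
#' @export
overdispersion_test <- function(data, response = "richness") {
  y <- data[[response]]
  if (is.null(y) || any(y < 0) || any(y != round(y))) {
    stopf("overdispersion test needs a count response")
  }
  fit <- fit_mixed(data, response = response, family = "poisson")
  pr <- stats::residuals(fit$model, type = "pearson")
  stat <- sum(pr^2)
  df <- stats::df.residual(fit$model)
  p <- stats::pchisq(stat, df, lower.tail = FALSE)
  list(statistic = stat, df = df, ratio = stat / df, p = p,
       recommend_nb = p < 0.05)
}

#' Paired difference between invaded and invaded-no-alien communities
#'
#' Tests whether the per-cell difference (invaded minus its no-alien
#' counterpart) in CFD (or richness) differs from zero, with an
#' intercept-only fixed part and a random intercept per FUA. Pairs are
#' matched by cell id; both members must have passed the minimum-richness
#' filter.
#'
#' @param x_invaded,x_no_alien named numeric vectors (names are cell ids).
#' @param fua named vector/factor of FUA ids per cell.
#' @return A `paired_cfd_test` list: `intercept`, `se`, `statistic`, `df`,
#'   `p`, `n_pairs`.
#' @export
paired_difference_test <- function(x_invaded, x_no_alien, fua) {
  cells <- intersect(names(x_invaded), names(x_no_alien))
  cells <- cells[!is.na(x_invaded[cells]) & !is.na(x_no_alien[cells])]
  if (length(cells) == 0) stopf("no matched pairs")
  d <- x_invaded[cells] - x_no_alien[cells]
  f <- factor(fua[cells])
  if (stats::sd(d) < 1e-12) {
    # degenerate: all differences identical
    est <- mean(d)
    out <- list(intercept = est, se = 0,
                statistic = if (est == 0) 0 else Inf, df = length(d) - 1,
                p = if (est == 0) 1 else 0, n_pairs = length(d))
  } else if (nlevels(f) < 2) {
    tt <- stats::t.test(d)
    out <- list(intercept = unname(tt$estimate), se = unname(tt$stderr),
                statistic = unname(tt$statistic), df = unname(tt$parameter),
                p = tt$p.value, n_pairs = length(d))
  } else {
    df_ <- data.frame(d = as.numeric(d), fua = f)
    mod <- suppressMessages(lmerTest::lmer(d ~ 1 + (1 | fua), data = df_))
    co <- summary(mod)$coefficients
    out <- list(intercept = co[1, "Estimate"], se = co[1, "Std. Error"],
                statistic = co[1, "t value"], df = co[1, "df"],
                p = co[1, "Pr(>|t|)"], n_pairs = length(d))
    out$model <- mod
  }
  class(out) <- "paired_cfd_test"
  out
}

#' @export
print.paired_cfd_test <- function(x, ...) {
  cat(sprintf(
    "Paired invaded vs no-alien difference: %d pairs\n  intercept %0.4f (se %0.4f), t = %0.3f, df = %0.1f, p = %0.4g\n",
    x$n_pairs, x$intercept, x$se, x$statistic, x$df, x$p
  ))
  invisible(x)
}

#' Distance-binned spatial correlogram with bootstrap confidence intervals
#'
#' Nonparametric check for residual spatial autocorrelation: model residuals
#' are standardized, pair products are averaged within distance bins
#' (a binned Moran-type estimate), lightly smoothed across adjacent bins,
#' and 95% percentile confidence intervals are obtained by bootstrapping
#' cells. No spatial autocorrelation is concluded when the confidence
#' interval includes zero at every evaluated distance.
#'
#' @param residuals numeric vector of model residuals, one per cell.
#' @param coords two-column matrix of cell centroid coordinates.
#' @param n_bins number of distance bins (default 10).
#' @param max_dist largest distance evaluated (default 2/3 of the maximum
#'   pairwise distance, the usual correlogram range).
#' @param n_boot bootstrap resamples (default 1000).
#' @param seed integer seed.
#' @return A `spatial_correlogram` object: per-bin `distance`, `n_pairs`,
#'   `estimate`, `lower`, `upper`, plus the `no_autocorrelation` verdict.
#' @export
spatial_correlogram <- function(residuals, coords, n_bins = 10,
                                max_dist = NULL, n_boot = 1000, seed = 1) {
  coords <- as.matrix(coords)
  n <- length(residuals)
  if (n < 30) stopf("need >= 30 cells with coordinates")
  if (nrow(coords) != n) stopf("coords and residuals lengths differ")
  D <- as.matrix(stats::dist(coords))
  if (max(D) == 0) stopf("all cells are collocated")
  max_dist <- max_dist %||% (2 / 3 * max(D))
  breaks <- seq(0, max_dist, length.out = n_bins + 1)
  mids <- (breaks[-1] + breaks[-length(breaks)]) / 2
  ut <- upper.tri(D)
  bin_of <- matrix(cut(D, breaks, labels = FALSE, include.lowest = TRUE),
                   n, n)
  binned_est <- function(idx) {
    z <- residuals[idx]
    z <- (z - mean(z)) / stats::sd(z)
    zz <- tcrossprod(z)[ut]
    b <- bin_of[idx, idx][ut]
    same <- outer(idx, idx, "==")[ut]  # duplicated cells: self-pairs carry no information
    ok <- !is.na(b) & !same
    est <- rep(NA_real_, n_bins)
    agg <- tapply(zz[ok], b[ok], mean)
    est[as.integer(names(agg))] <- agg
    # moving-average smoothing across adjacent bins
    sm <- est
    for (i in seq_len(n_bins)) {
      w <- c(if (i > 1) est[i - 1], est[i], if (i < n_bins) est[i + 1])
      sm[i] <- mean(w, na.rm = TRUE)
    }
    sm
  }
  est <- binned_est(seq_len(n))
  boot <- with_seed(as.integer(seed), {
    vapply(seq_len(n_boot), function(b) binned_est(sample.int(n, replace = TRUE)),
           numeric(n_bins))
  })
  lower <- apply(boot, 1, stats::quantile, 0.025, na.rm = TRUE)
  upper <- apply(boot, 1, stats::quantile, 0.975, na.rm = TRUE)
  counts <- tabulate(bin_of[ut], nbins = n_bins)
  out <- data.frame(distance = mids, n_pairs = counts, estimate = est,
                    lower = lower, upper = upper)
  structure(
    list(bins = out,
         no_autocorrelation = all(is.na(est) | (lower <= 0 & upper >= 0)),
         n_boot = n_boot),
    class = "spatial_correlogram"
  )
}

#' @export
print.spatial_correlogram <- function(x, ...) {
  cat(sprintf(
    "Spatial correlogram (%d bootstrap resamples): %s\n",
    x$n_boot,
    if (x$no_autocorrelation) "no autocorrelation (all 95% CIs include zero)"
    else "autocorrelation detected (some 95% CI excludes zero)"
  ))
  print(x$bins, digits = 3)
  invisible(x)
}

#' @export
plot.spatial_correlogram <- function(x, ...) {
  b <- x$bins
  graphics::plot(b$distance, b$estimate, type = "b", ylim = range(c(b$lower, b$upper, 0), na.rm = TRUE),
                 xlab = "distance", ylab = "correlation", ...)
  graphics::lines(b$distance, b$lower, lty = 2)
  graphics::lines(b$distance, b$upper, lty = 2)
  graphics::abline(h = 0, col = "grey50")
  invisible(x)
}
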