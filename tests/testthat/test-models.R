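# direct simulators for the model layer (bypassing the full generator)
sim_mixed_data <- function(n_fua = 10, per = 10, b0 = log(20), b = 0,
                           fua_sd = 0.3, theta = Inf, gaussian = FALSE,
                           seed = 1) {
  set.seed(seed)
  fua <- rep(sprintf("f%02d", seq_len(n_fua)), each = per)
  z <- rnorm(n_fua * per)
  u <- rnorm(n_fua, 0, fua_sd)[rep(seq_len(n_fua), each = per)]
  if (gaussian) {
    y <- b * z + u + rnorm(n_fua * per)
  } else {
    mu <- exp(b0 + b * z + u)
    y <- if (is.infinite(theta)) rpois(length(mu), mu)
         else rnbinom(length(mu), mu = mu, size = theta)
  }
  data.frame(fua = fua, z_income = z, richness = if (gaussian) NA else y,
             cfd = if (gaussian) y else NA)
}

test_that("the negative-binomial mixed model recovers a known income slope", {
  est <- vapply(1:9, function(r) {
    d <- sim_mixed_data(n_fua = 20, per = 25, b = 0.3, theta = 5, seed = 200 + r)
    fit <- fit_mixed(d, "richness")
    unname(coef(fit)["z_income"])
  }, numeric(1))
  expect_lt(abs(median(est) - 0.3), 0.1)
})

test_that("with no income effect the income term is rarely significant", {
  pvals <- vapply(1:15, function(r) {
    d <- sim_mixed_data(n_fua = 10, per = 10, b = 0, theta = 5, seed = 300 + r)
    fit <- fit_mixed(d, "richness")
    fit$coefficients$p[fit$coefficients$term == "z_income"]
  }, numeric(1))
  expect_gte(mean(pvals > 0.05), 0.8)
})

test_that("a zero FUA variance is estimated as (near) zero, with warning not failure", {
  d <- sim_mixed_data(n_fua = 12, per = 100, b = 0.2, fua_sd = 0, gaussian = TRUE,
                      seed = 5)
  fit <- suppressWarnings(fit_mixed(d, "cfd"))
  expect_lt(fit$ranef_variance, 0.01)
  expect_equal(fit$family, "gaussian")
  expect_equal(fit$tests$stat_type[1], "F")
})

test_that("fit results expose recomputable Wald statistics and residuals", {
  d <- sim_mixed_data(n_fua = 8, per = 15, b = 0.3, theta = 3, seed = 9)
  d$type <- factor(rep(c("non-invaded", "invaded"), length.out = nrow(d)))
  fit <- fit_mixed(d, "richness")
  co <- fit$coefficients
  expect_equal(co$statistic, co$estimate / co$se, tolerance = 1e-10)
  expect_equal(length(residuals(fit)), nrow(d))
  expect_equal(fit$tests$stat_type[1], "Wald chi-square")
  expect_true(all(c("z_income", "type", "z_income:type") %in% fit$tests$term))
  expect_output(print(fit), "Mixed model for richness")
})

test_that("overdispersion check is calibrated under Poisson and powerful under NB", {
  d <- sim_mixed_data(n_fua = 20, per = 50, b = 0.2, fua_sd = 0.2, seed = 31)
  od <- overdispersion_test(d)
  expect_gt(od$ratio, 0.85)
  expect_lt(od$ratio, 1.15)

  hits <- vapply(1:10, function(r) {
    d2 <- sim_mixed_data(n_fua = 10, per = 30, b = 0.2, theta = 0.5, seed = 400 + r)
    overdispersion_test(d2)$p < 0.001
  }, logical(1))
  expect_gte(mean(hits), 0.95)

  # constant response equal to its fitted mean: statistic ~ 0
  d3 <- data.frame(fua = rep(c("f1", "f2", "f3"), each = 10),
                   z_income = rnorm(30), richness = 20L)
  od3 <- suppressWarnings(overdispersion_test(d3))
  expect_lt(od3$statistic, 1e-4)
  expect_error(overdispersion_test(data.frame(fua = "f", z_income = 1, richness = 0.5)),
               "count")
})

test_that("the paired difference model behaves at its fixed points", {
  cells <- sprintf("c%02d", 1:50)
  fua <- setNames(rep(sprintf("f%d", 1:5), each = 10), cells)

  zero <- setNames(rep(1.3, 50), cells)
  out <- paired_difference_test(zero, zero, fua)
  expect_equal(out$intercept, 0)
  expect_equal(out$p, 1)
  expect_equal(out$statistic, 0)

  set.seed(21)
  a <- setNames(rnorm(50, 1, 0.3), cells)
  b <- a - rnorm(50, 0.5, 0.1)
  out2 <- paired_difference_test(a, b, fua)
  expect_gt(out2$intercept, 0.4)
  expect_lt(out2$intercept, 0.6)
  expect_lt(out2$p, 0.001)
  expect_equal(out2$n_pairs, 50)

  flipped <- paired_difference_test(b, a, fua)
  expect_equal(flipped$intercept, -out2$intercept, tolerance = 1e-8)
  expect_equal(abs(flipped$statistic), abs(out2$statistic), tolerance = 1e-8)

  expect_error(paired_difference_test(setNames(1, "x"), setNames(1, "y"), fua),
               "no matched pairs")
})

test_that("balanced random-intercept fits match closed-form one-way ANOVA estimates", {
  set.seed(15)
  a <- 8; n_per <- 12
  fua <- setNames(rep(sprintf("f%d", 1:a), each = n_per),
                  sprintf("c%02d", 1:(a * n_per)))
  y <- setNames(rnorm(a * n_per, 2, 1) + rep(rnorm(a, 0, 0.8), each = n_per),
                names(fua))
  zero <- setNames(rep(0, a * n_per), names(fua))
  out <- paired_difference_test(y, zero, fua)
  gm <- tapply(y, fua, mean)
  msb <- n_per * sum((gm - mean(y))^2) / (a - 1)
  msw <- sum((y - gm[fua])^2) / (a * (n_per - 1))
  expect_equal(out$intercept, mean(y), tolerance = 1e-6)
  vc <- as.data.frame(lme4::VarCorr(out$model))
  expect_equal(vc$vcov[vc$grp == "fua"], max((msb - msw) / n_per, 0), tolerance = 1e-6)
  expect_equal(vc$vcov[vc$grp == "Residual"], msw, tolerance = 1e-6)
})

test_that("the spatial correlogram flags structure and clears iid noise", {
  set.seed(77)
  coords <- cbind(runif(80, 0, 10), runif(80, 0, 10))

  verdicts <- vapply(1:10, function(r) {
    set.seed(500 + r)
    spatial_correlogram(rnorm(80), coords, n_boot = 199, seed = r)$no_autocorrelation
  }, logical(1))
  expect_gte(mean(verdicts), 0.8)

  # residuals that are a smooth function of x: short-range CI excludes zero
  trend <- spatial_correlogram(sin(coords[, 1] / 2) + rnorm(80, 0, 0.05),
                               coords, n_boot = 199, seed = 3)
  expect_false(trend$no_autocorrelation)
  expect_gt(trend$bins$lower[1], 0)

  # permuting the residuals destroys the detected structure
  set.seed(81)
  perm <- spatial_correlogram(sample(sin(coords[, 1] / 2)), coords,
                              n_boot = 199, seed = 4)
  expect_true(perm$no_autocorrelation)

  expect_error(spatial_correlogram(rnorm(10), coords[1:10, ]), ">= 30")
  expect_error(spatial_correlogram(rnorm(30), matrix(1, 30, 2)), "collocated")
})
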