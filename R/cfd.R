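#' Phylogenetic correction of functional dispersion
#'
#' Fits a linear model of functional dispersion (FD) on phylogenetic
#' dispersion (PD) across communities, with intercept, and returns its
#' residuals: the component of functional dispersion not explained by shared
#' evolutionary history. The residuals are exactly orthogonal to PD
#' (Pearson r = 0 up to floating point), the defining property of the
#' correction.
#'
#' @param fd,pd named numeric vectors of per-community dispersion, matching
#'   community ids, length >= 3.
#' @return Named residual vector, one per community.
#' @export
phylo_correct <- function(fd, pd) {
  if (length(fd) != length(pd)) stopf("fd and pd lengths differ")
  if (length(fd) < 3) stopf("need at least 3 communities")
  if (!is.null(names(fd)) && !is.null(names(pd))) {
    if (!identical(names(fd), names(pd))) stopf("fd and pd community ids differ")
  }
  fit <- stats::lm(fd ~ pd)
  r <- as.numeric(stats::residuals(fit))
  names(r) <- names(fd)
  r
}

# draw n_iter permutations of n labels, reproducibly from one master seed
draw_permutations <- function(n, n_iter, seed) {
  with_seed(as.integer(seed), {
    lapply(seq_len(n_iter), function(i) sample.int(n))
  })
}

#' Null distributions of phylogenetically corrected dispersion
#'
#' Tip-label randomization null model: in each iteration every species is
#' assigned a random position in the functional and phylogenetic trees (one
#' shared permutation by default, so a species' functional and phylogenetic
#' positions move together, which is equivalent to randomizing community
#' membership against the species pool). Functional and phylogenetic
#' dispersion are recomputed for every community, the FD~PD linear model is
#' refit on that iteration's values, and its residuals are stored as that
#' iteration's 'expected' values.
#'
#' @param ftree functional tree (`phylo`) or its patristic matrix.
#' @param ptree phylogenetic tree (`phylo`) or its patristic matrix.
#' @param communities a [community_matrix()]; all cells must hold >= 3
#'   species (apply [min_richness_filter()] first).
#' @param n_iter number of null iterations (>= 1; 999 by default).
#' @param seed integer seed for the permutation stream.
#' @param shared_permutation apply one permutation to both trees (default);
#'   `FALSE` draws independent permutations for the two trees.
#' @param permutations optional list of explicit permutations (each a
#'   permutation of the species indices), overriding the random stream; used
#'   e.g. to force the identity null.
#' @return List with matrices `resid`, `fd`, `pd` (communities x iterations).
#' @export
null_distributions <- function(ftree, ptree, communities, n_iter = 999,
                               seed = 1, shared_permutation = TRUE,
                               permutations = NULL) {
  stopifnot(inherits(communities, "community_matrix"))
  if (n_iter < 1) stopf("n_iter must be >= 1")
  M <- communities$pa
  k <- rowSums(M)
  if (any(k < 3)) stopf("communities with < 3 species must be filtered out before the null model")
  sp <- colnames(M)
  Df <- align_patristic(ftree, sp)
  Dp <- align_patristic(ptree, sp)
  n <- length(sp)
  if (is.null(permutations)) {
    perms <- draw_permutations(n, if (shared_permutation) n_iter else 2L * n_iter, seed)
  } else {
    perms <- permutations
    if (length(perms) < n_iter * (if (shared_permutation) 1L else 2L)) {
      stopf("not enough permutations supplied")
    }
  }
  resid_m <- fd_m <- pd_m <- matrix(
    NA_real_, nrow(M), n_iter, dimnames = list(rownames(M), NULL)
  )
  for (it in seq_len(n_iter)) {
    pf <- perms[[if (shared_permutation) it else 2L * it - 1L]]
    pp <- if (shared_permutation) pf else perms[[2L * it]]
    fd <- dispersion_profile(M, Df, pf)
    pd <- dispersion_profile(M, Dp, pp)
    fd_m[, it] <- fd
    pd_m[, it] <- pd
    resid_m[, it] <- ols_residuals(fd, pd)
  }
  list(resid = resid_m, fd = fd_m, pd = pd_m)
}

# closed-form simple-regression residuals (the null loop is hot; equals
# residuals(lm(y ~ x)), with the constant-x degenerate case matching lm)
ols_residuals <- function(y, x) {
  vx <- stats::var(x)
  if (!is.finite(vx) || vx < .Machine$double.eps) return(y - mean(y))
  b <- stats::cov(x, y) / vx
  y - (mean(y) - b * mean(x)) - b * x
}

# patristic matrix (from tree or matrix) reordered to the given species
align_patristic <- function(tree, sp) {
  d <- if (inherits(tree, "phylo")) patristic(tree) else as.matrix(tree)
  missing <- setdiff(sp, rownames(d))
  if (length(missing)) stopf("species missing from tree: %s", paste(missing, collapse = ", "))
  d[sp, sp]
}

#' Standardized effect size against a null matrix
#'
#' `SES_i = (obs_i - mean(null_i)) / sd(null_i)` with the sample (n-1)
#' standard deviation. Communities whose null distribution is degenerate
#' (sd = 0) get `NA` with the `degenerate` flag set, never infinity.
#'
#' @param observed named vector of observed corrected residuals.
#' @param null matrix of null residuals (communities x iterations).
#' @return Data frame: `community`, `observed`, `null_mean`, `null_sd`,
#'   `ses`, `degenerate`.
#' @export
ses <- function(observed, null) {
  null <- as.matrix(null)
  if (length(observed) != nrow(null)) stopf("observed and null dimensions differ")
  mu <- rowMeans(null)
  sdv <- apply(null, 1, stats::sd)
  degenerate <- sdv == 0
  s <- ifelse(degenerate, NA_real_, (observed - mu) / sdv)
  data.frame(
    community = names(observed) %||% rownames(null) %||% seq_along(observed),
    observed = as.numeric(observed), null_mean = mu, null_sd = sdv,
    ses = s, degenerate = degenerate,
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Corrected functional dispersion (CFD)
#'
#' The central estimator. For every community (>= 3 species) it computes
#' functional dispersion (FD) on the functional tree and phylogenetic
#' dispersion (PD) on the phylogeny, regresses FD on PD across communities
#' and takes the residuals ('observed' values), builds a tip-label
#' randomization null (`n_iter` iterations, each refitting the FD~PD model
#' to give 'expected' values), and returns the standardized effect size of
#' the observed residual against its null distribution. A CFD of 0 means
#' dispersion as expected given the community's species richness; positive
#' values mark overdispersed communities (ecosystem-service provision higher
#' than expected), negative values underdispersed ones.
#'
#' @param communities a [community_matrix()] (all cells >= 3 species).
#' @param functional_tree functional tree (`phylo`) or patristic matrix over
#'   the species pool.
#' @param phylo_tree phylogenetic tree or patristic matrix.
#' @param n_iter null iterations (default 999).
#' @param seed integer seed.
#' @param shared_permutation see [null_distributions()].
#' @param service optional label ("cultural"/"regulating") carried in the
#'   result.
#' @return A `cfd` object; its `$table` holds, per community: `fd`, `pd`,
#'   observed residual `resid`, `null_mean`, `null_sd`, `ses`, `degenerate`.
#' @seealso [phylo_correct()], [null_distributions()], [ses()]
#' @export
cfd <- function(communities, functional_tree, phylo_tree, n_iter = 999,
                seed = 1, shared_permutation = TRUE, service = NULL) {
  stopifnot(inherits(communities, "community_matrix"))
  M <- communities$pa
  if (any(rowSums(M) < 3)) stopf("all communities must hold >= 3 species; apply min_richness_filter() first")
  sp <- colnames(M)
  Df <- align_patristic(functional_tree, sp)
  Dp <- align_patristic(phylo_tree, sp)
  fd <- dispersion_profile(M, Df)
  pd <- dispersion_profile(M, Dp)
  obs_fit <- stats::lm(fd ~ pd)
  obs_resid <- as.numeric(stats::residuals(obs_fit))
  names(obs_resid) <- rownames(M)
  nulls <- null_distributions(
    Df, Dp, communities, n_iter = n_iter, seed = seed,
    shared_permutation = shared_permutation
  )
  tab <- ses(obs_resid, nulls$resid)
  tab <- data.frame(
    community = tab$community, fd = as.numeric(fd), pd = as.numeric(pd),
    resid = tab$observed, null_mean = tab$null_mean, null_sd = tab$null_sd,
    ses = tab$ses, degenerate = tab$degenerate,
    stringsAsFactors = FALSE
  )
  structure(
    list(
      table = tab, n_iter = n_iter, seed = seed,
      shared_permutation = shared_permutation, service = service,
      fd_pd_fit = obs_fit, call = match.call()
    ),
    class = "cfd"
  )
}

#' @export
print.cfd <- function(x, ...) {
  cat(sprintf(
    "Corrected functional dispersion%s: %d communities, %d null iterations\n",
    if (!is.null(x$service)) paste0(" (", x$service, ")") else "",
    nrow(x$table), x$n_iter
  ))
  s <- x$table$ses[!x$table$degenerate]
  cat(sprintf(
    "  SES: mean %0.3f, sd %0.3f; %d underdispersed (< -1.96), %d overdispersed (> 1.96)\n",
    mean(s, na.rm = TRUE), stats::sd(s, na.rm = TRUE),
    sum(s < -1.96, na.rm = TRUE), sum(s > 1.96, na.rm = TRUE)
  ))
  if (any(x$table$degenerate)) {
    cat(sprintf("  %d communities with degenerate (sd = 0) null flagged NA\n", sum(x$table$degenerate)))
  }
  invisible(x)
}

#' @export
summary.cfd <- function(object, ...) {
  print(object)
  cat("\nFD ~ PD regression (observed):\n")
  print(summary(object$fd_pd_fit)$coefficients)
  cat("\nSES quantiles:\n")
  print(stats::quantile(object$table$ses, c(0.025, 0.25, 0.5, 0.75, 0.975), na.rm = TRUE))
  invisible(object)
}

#' @export
residuals.cfd <- function(object, ...) {
  r <- object$table$resid
  names(r) <- object$table$community
  r
}

#' @export
as.data.frame.cfd <- function(x, ...) x$table

#' @export
plot.cfd <- function(x, ...) {
  s <- x$table$ses[!x$table$degenerate & !is.na(x$table$ses)]
  graphics::hist(s, breaks = 30, freq = FALSE, main = "Corrected functional dispersion",
                 xlab = "SES (CFD)", ...)
  graphics::abline(v = 0, lty = 2)
  graphics::curve(stats::dnorm(x), add = TRUE, col = "grey40")
  invisible(x)
}
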