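# a small ready-to-use study: pool, trees, filtered communities
small_setup <- function(seed = 1, n_species = 25, n_fuas = 5, cells = 8) {
  cfg <- sim_config(n_species = n_species, n_nonnative = 2, n_fuas = n_fuas,
                    cells_per_fua = cells, seed = seed)
  pool <- generate_species_pool(cfg)
  prep <- prepare_traits(pool)
  land <- generate_landscape(cfg)
  m <- min_richness_filter(generate_communities(cfg, pool, land$income))
  ftree <- nj_tree(gower_distance(prep, "cultural"))
  ptree <- generate_phylogeny(n_species, seed, labels = pool$species)
  list(m = m, ftree = ftree, ptree = ptree)
}

test_that("phylogenetic correction returns orthogonal OLS residuals", {
  pd <- c(a = 1, b = 2, c = 3, d = 4)
  expect_equal(phylo_correct(2 * pd, pd), setNames(rep(0, 4), names(pd)),
               tolerance = 1e-12)

  # 4-point toy against the closed-form simple-regression oracle
  fd <- c(a = 1, b = 3, c = 2, d = 4)
  beta <- sum((pd - mean(pd)) * (fd - mean(fd))) / sum((pd - mean(pd))^2)
  expected <- fd - (mean(fd) - beta * mean(pd)) - beta * pd
  expect_equal(phylo_correct(fd, pd), expected, tolerance = 1e-12)

  # orthogonality on a real-sized random case
  s <- small_setup(3)
  fdv <- vapply(rownames(s$m$pa), function(cl) {
    dispersion(s$ftree, colnames(s$m$pa)[s$m$pa[cl, ] == 1])
  }, numeric(1))
  pdv <- vapply(rownames(s$m$pa), function(cl) {
    dispersion(s$ptree, colnames(s$m$pa)[s$m$pa[cl, ] == 1])
  }, numeric(1))
  r <- phylo_correct(fdv, pdv)
  expect_lt(abs(cor(r, pdv)), 1e-10)

  expect_error(phylo_correct(1:3, 1:2), "lengths differ")
  expect_error(phylo_correct(c(x = 1, y = 2), c(x = 1, y = 2)), "at least 3")
})

test_that("the identity permutation reproduces the observed residuals", {
  s <- small_setup(5)
  n <- ncol(s$m$pa)
  nulls <- null_distributions(s$ftree, s$ptree, s$m, n_iter = 1,
                              permutations = list(seq_len(n)))
  fd <- dispersion_profile(s$m$pa, patristic(s$ftree)[colnames(s$m$pa), colnames(s$m$pa)])
  pd <- dispersion_profile(s$m$pa, patristic(s$ptree)[colnames(s$m$pa), colnames(s$m$pa)])
  expect_equal(as.numeric(nulls$resid[, 1]), unname(phylo_correct(fd, pd)),
               tolerance = 1e-10)
})

test_that("null distributions are seed-deterministic and refuse tiny communities", {
  s <- small_setup(7)
  a <- null_distributions(s$ftree, s$ptree, s$m, n_iter = 5, seed = 3)
  b <- null_distributions(s$ftree, s$ptree, s$m, n_iter = 5, seed = 3)
  expect_identical(a$resid, b$resid)
  bad <- s$m
  bad$pa[1, ] <- 0
  bad$pa[1, 1:2] <- 1L
  expect_error(null_distributions(s$ftree, s$ptree, bad, n_iter = 2), "< 3 species")
})

test_that("exchangeable star trees give degenerate nulls, flagged not infinite", {
  lab <- sprintf("s%d", 1:6)
  star <- ape::read.tree(text = paste0("(", paste0(lab, ":1", collapse = ","), ");"))
  pa <- matrix(0L, 3, 6, dimnames = list(c("c1", "c2", "c3"), lab))
  pa[1, 1:3] <- 1L; pa[2, 2:4] <- 1L; pa[3, c(1, 5, 6)] <- 1L
  m <- make_cm(pa)
  out <- cfd(m, star, star, n_iter = 19, seed = 1)
  expect_true(all(out$table$degenerate))
  expect_true(all(is.na(out$table$ses)))
})

test_that("the null label-permutation distribution matches exhaustive relabeling", {
  # 5-species pool, one 3-species community: compare the set of achievable
  # null FD values against brute-force enumeration of all 5! relabelings
  set.seed(17)
  tr <- ape::rtree(5)
  d <- patristic(tr)
  sp <- rownames(d)
  pa <- matrix(0L, 3, 5, dimnames = list(c("c1", "c2", "c3"), sp))
  pa[1, 1:3] <- 1L; pa[2, 2:4] <- 1L; pa[3, c(1, 4, 5)] <- 1L
  m <- make_cm(pa)
  perms <- as.matrix(expand.grid(rep(list(1:5), 5)))
  perms <- perms[apply(perms, 1, function(p) length(unique(p)) == 5), , drop = FALSE]
  expect_equal(nrow(perms), 120)
  exact <- vapply(seq_len(nrow(perms)), function(i) {
    dp <- d[perms[i, ], perms[i, ]]
    mean(dp[1:3, 1:3][upper.tri(matrix(0, 3, 3))])
  }, numeric(1))
  nulls <- null_distributions(tr, tr, m, n_iter = 400, seed = 2)
  drawn <- nulls$fd[1, ]
  expect_true(all(round(drawn, 10) %in% round(exact, 10)))
  # every atom of the exact distribution appears among 400 draws
  expect_setequal(round(unique(drawn), 10), round(unique(exact), 10))
})

test_that("standardized effect sizes follow the (obs - mean) / sd formula", {
  nullm <- matrix(c(1, 2, 3), 1, 3)
  out <- ses(c(c1 = 3), nullm)
  expect_equal(out$ses, 1)           # mean 2, sample sd 1
  expect_equal(ses(c(c1 = 2), nullm)$ses, 0)
  expect_equal(ses(c(c1 = 4), nullm)$ses, 2)
  degen <- ses(c(c1 = 5), matrix(2, 1, 4))
  expect_true(degen$degenerate)
  expect_true(is.na(degen$ses))
  expect_error(ses(1:2, nullm), "dimensions differ")
})

test_that("cfd objects carry coherent tables and methods", {
  s <- small_setup(9)
  out <- cfd(s$m, s$ftree, s$ptree, n_iter = 49, seed = 4, service = "cultural")
  tab <- out$table
  expect_equal(nrow(tab), nrow(s$m$pa))
  # SES recomputable from stored pieces
  expect_equal(tab$ses, (tab$resid - tab$null_mean) / tab$null_sd, tolerance = 1e-12)
  # corrected residuals orthogonal to PD
  expect_lt(abs(cor(tab$resid, tab$pd)), 1e-10)
  expect_equal(unname(residuals(out)), tab$resid)
  expect_s3_class(as.data.frame(out), "data.frame")
  expect_output(print(out), "Corrected functional dispersion")
  # deterministic under seed
  out2 <- cfd(s$m, s$ftree, s$ptree, n_iter = 49, seed = 4)
  expect_equal(out2$table$ses, tab$ses)
})
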