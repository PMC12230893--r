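test_that("invasion classification follows the at-least-one-alien rule", {
  pa <- rbind(
    c1 = c(1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 0),
    c2 = c(1, 1, 1, 0, 0, 0, 0, 0, 0, 0, 0, 0),
    c3 = rep(0, 12)
  )
  colnames(pa) <- sprintf("s%02d", 1:12)
  m <- make_cm(pa, nonnative = c(rep(FALSE, 11), TRUE))
  m$pa["c1", "s12"] <- 1L
  lab <- classify_communities(m)
  expect_equal(as.character(lab[c("c1", "c2", "c3")]),
               c("invaded", "non-invaded", "non-invaded"))
  expect_equal(attr(lab, "empty_cells"), "c3")
})

test_that("the no-alien derivation zeroes aliens, keeps pairing, and composes with filters", {
  pa <- rbind(
    inv = c(1, 1, 1, 1, 1, 1, 1),  # 5 natives + 2 aliens
    thin = c(1, 1, 0, 0, 0, 1, 1), # 2 natives + 2 aliens -> below 3 without aliens
    nat = c(1, 1, 1, 1, 0, 0, 0)
  )
  colnames(pa) <- sprintf("s%d", 1:7)
  flags <- c(rep(FALSE, 5), TRUE, TRUE)
  m <- make_cm(pa, nonnative = flags)
  na <- derive_no_alien(m)
  expect_setequal(rownames(na$pa), c("inv", "thin"))
  expect_equal(unname(rowSums(na$pa)[c("inv", "thin")]), c(5, 2))
  expect_true(all(rowSums(na$pa) <= rowSums(m$pa[rownames(na$pa), ])))
  # the thin cell drops out of dispersion and the paired comparison
  kept <- min_richness_filter(na, 3)
  expect_equal(rownames(kept$pa), "inv")
  expect_equal(attr(kept, "dropped_cells"), "thin")
  expect_error(derive_no_alien(m, cells = "nat"), "invaded")
})

test_that("occurrence thresholds reproduce the printed per-country values", {
  expect_equal(occurrence_threshold(709), 7L)
  expect_equal(occurrence_threshold(111), 1L)
  expect_error(occurrence_threshold(100, fraction = 0), "fraction")
})

test_that("the occurrence filter keeps boundary species and acts per country", {
  # country A: 10 cells, fraction .2 -> threshold 2; country B: 5 cells -> 1
  set.seed(3)
  pa <- matrix(0L, 15, 3, dimnames = list(sprintf("c%02d", 1:15), c("s1", "s2", "s3")))
  pa[1:2, "s1"] <- 1L      # exactly at threshold in A: retained
  pa[3, "s2"] <- 1L        # below threshold in A: zeroed there
  pa[11, "s2"] <- 1L       # at threshold in B: retained
  pa[, "s3"] <- 1L
  m <- make_cm(pa, country = rep(c("A", "B"), c(10, 5)))
  out <- occurrence_filter(m, fraction = 0.2)
  expect_equal(unname(attr(out, "thresholds")[c("A", "B")]), c(2L, 1L))
  expect_equal(sum(out$pa[1:10, "s1"]), 2)
  expect_equal(sum(out$pa[1:10, "s2"]), 0)
  expect_equal(sum(out$pa[11:15, "s2"]), 1)
})

test_that("minimum-richness filtering is a boundary-inclusive identity above k", {
  pa <- rbind(a = c(1, 1, 0, 0), b = c(1, 1, 1, 0), c = c(1, 1, 1, 1))
  colnames(pa) <- sprintf("s%d", 1:4)
  m <- make_cm(pa)
  out <- min_richness_filter(m, 3)
  expect_setequal(rownames(out$pa), c("b", "c"))
  all3 <- min_richness_filter(cm_full <- make_cm(pa[c("b", "c"), ]), 3)
  expect_identical(all3$pa, cm_full$pa)
})

test_that("richness filtering commutes with classification on random matrices", {
  set.seed(11)
  for (r in 1:5) {
    pa <- matrix(rbinom(20 * 8, 1, 0.4), 20, 8,
                 dimnames = list(sprintf("c%02d", 1:20), sprintf("s%d", 1:8)))
    m <- make_cm(pa, nonnative = c(rep(FALSE, 6), TRUE, TRUE))
    f <- min_richness_filter(m, 3)
    lab_then_filter <- classify_communities(m)[rownames(f$pa)]
    filter_then_lab <- classify_communities(f)
    expect_equal(as.character(lab_then_filter), as.character(filter_then_lab))
  }
})

test_that("FUA overlap filtering keeps the 50% boundary and assigns by largest overlap", {
  cells <- data.frame(
    cell = c("inside", "half", "almost", "split"),
    xmin = c(1, 10, 20, 30), xmax = c(2, 12, 22, 32),
    ymin = 0, ymax = 1
  )
  eps <- 1e-6
  fuas <- data.frame(
    fua = c("f1", "f2", "f3a", "f3b"),
    xmin = c(0, 10, 20, 30.8), xmax = c(5, 11, 21 - eps, 32),
    ymin = -1, ymax = 2
  )
  kept <- fua_overlap_filter(cells, fuas, min_frac = 0.5)
  expect_true(all(c("inside", "half", "split") %in% kept$cell))
  expect_false("almost" %in% kept$cell)   # overlap 0.5 - eps/2
  expect_equal(kept$fua[kept$cell == "split"], "f3b") # 1.2 vs 0.2 - eps overlap
})

test_that("rectangle union area handles overlap without double counting", {
  r <- data.frame(xmin = c(0, 1), xmax = c(2, 3), ymin = c(0, 0), ymax = c(1, 2))
  expect_equal(rect_union_area(r), 2 + 4 - 1)
  expect_equal(rect_union_area(r[1, ]), 2)
  expect_equal(rect_union_area(r[0, ]), 0)
})

test_that("cell income is the overlap-area-weighted neighbourhood mean", {
  cell <- data.frame(cell = "c1", xmin = 0, xmax = 4, ymin = 0, ymax = 1)
  nbs <- data.frame(
    nb = c("n1", "n2"), income = c(10000, 20000),
    xmin = c(0, 3), xmax = c(3, 4), ymin = 0, ymax = 1
  )
  expect_equal(cell_income(cell, nbs)$income, 12500)  # weights 3:1
  # equal-area overlaps average the incomes
  nbs2 <- data.frame(nb = c("a", "b"), income = c(10000, 20000),
                     xmin = c(0, 2), xmax = c(2, 4), ymin = 0, ymax = 1)
  expect_equal(cell_income(cell, nbs2)$income, 15000)
  # single full-cover neighbourhood passes through
  nb3 <- data.frame(nb = "solo", income = 31415, xmin = -1, xmax = 5, ymin = -1, ymax = 2)
  expect_equal(cell_income(cell, nb3)$income, 31415)
  # splitting a neighbourhood into two pieces changes nothing
  nb_split <- data.frame(nb = c("solo_a", "solo_b"), income = 31415,
                         xmin = c(-1, 2), xmax = c(2, 5), ymin = -1, ymax = 2)
  expect_equal(cell_income(cell, nb_split)$income, 31415)
  # no overlap -> missing, not zero
  far <- data.frame(nb = "far", income = 9999, xmin = 100, xmax = 101, ymin = 0, ymax = 1)
  expect_true(is.na(cell_income(cell, far)$income))
  expect_error(cell_income(cell, data.frame(nb = "bad", income = -5, xmin = 0,
                                            xmax = 1, ymin = 0, ymax = 1)), "positive")
})

test_that("income standardization is per country, unit variance, affine invariant", {
  g <- data.frame(cell = sprintf("c%d", 1:6),
                  country = rep(c("A", "B"), each = 3),
                  income = c(1, 2, 3, 100, 300, 200))
  z <- standardize_income(g)
  expect_equal(z$z_income[1:3], c(-1, 0, 1))
  for (ctry in c("A", "B")) {
    expect_lt(abs(mean(z$z_income[z$country == ctry])), 1e-12)
    expect_equal(sd(z$z_income[z$country == ctry]), 1, tolerance = 1e-12)
  }
  g2 <- g; g2$income <- g2$income * 166.386 + 0  # currency conversion
  expect_equal(standardize_income(g2)$z_income, z$z_income, tolerance = 1e-10)
  expect_error(standardize_income(data.frame(cell = "c", country = "A", income = 5)),
               "fewer than 2")
})

test_that("the assembly pipeline logs counts at every stage", {
  cfg <- sim_config(n_species = 25, n_nonnative = 3, n_fuas = 4,
                    cells_per_fua = 6, seed = 14)
  st <- simulate_study(cfg)
  asm <- assemble_analysis(st$communities, st$landscape)
  log <- attr(asm$table, "filter_log")
  expect_named(log, c("start", "after_overlap_filter", "after_occurrence_filter",
                      "after_min_richness", "after_income_join", "invaded",
                      "non_invaded"))
  expect_true(all(diff(log[1:5]) <= 0))  # filters never add cells
  expect_equal(unname(log["invaded"] + log["non_invaded"]), unname(log["after_income_join"]))
  expect_setequal(names(asm$table), c("cell", "fua", "country", "richness",
                                      "type", "z_income"))
})
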