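#' Simulation configuration
#'
#' Bundles the parameters of the synthetic study generator. The generator
#' emulates the data a breeding-bird atlas / income-register analysis needs:
#' a species pool with cultural and regulating traits, a pure-birth
#' phylogeny, an income landscape of neighbourhood polygons overlapping atlas
#' grid cells, and presence/absence communities whose richness, invasion
#' status and trait composition respond to the income gradient.
#'
#' Slopes are on the scales the downstream models use: `richness_income_slope`
#' is the log-scale change in expected richness per within-country standard
#' deviation of income; `invasion_income_slope` is the logit-scale change in a
#' non-native species' occurrence probability; `service_income_slope` weights
#' species sampling by functional originality (negative values make
#' higher-income cells draw functionally ordinary, mutually similar species,
#' depressing dispersion there).
#'
#' @param n_species total species pool size (>= 4).
#' @param n_nonnative number of non-native species (<= `n_species`).
#' @param n_fuas number of functional urban areas.
#' @param cells_per_fua atlas grid cells per FUA (>= 1).
#' @param richness_income_slope log-scale richness effect per income SD.
#' @param invasion_income_slope logit-scale invasion effect per income SD.
#' @param service_income_slope trait-selection gradient (see Details).
#' @param baseline_richness expected richness at average income (>= 3).
#' @param seed integer master seed; every generator stage derives its stream
#'   from it, so a config is fully reproducible.
#' @param fua_sd standard deviation of the log-scale FUA random intercept on
#'   richness (default 0.2, a moderate between-city effect).
#' @param invasion_intercept baseline logit of non-native occurrence at
#'   average income (default `qlogis(0.2)`).
#' @param nonnative_colour_boost how strongly non-native species' colour
#'   diversity/elaboration is shifted towards the attractive extreme
#'   (0 = no shift; default 2 makes aliens culturally distinctive, the
#'   colourful-escapee situation typical of urban invaders).
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_species = 80, n_nonnative = 8, n_fuas = 20,
                       cells_per_fua = 10, richness_income_slope = 0.15,
                       invasion_income_slope = 0.8,
                       service_income_slope = -0.5,
                       baseline_richness = 25, seed = 1,
                       fua_sd = 0.2, invasion_intercept = stats::qlogis(0.2),
                       nonnative_colour_boost = 2) {
  cfg <- list(
    n_species = as.integer(n_species), n_nonnative = as.integer(n_nonnative),
    n_fuas = as.integer(n_fuas), cells_per_fua = as.integer(cells_per_fua),
    richness_income_slope = richness_income_slope,
    invasion_income_slope = invasion_income_slope,
    service_income_slope = service_income_slope,
    baseline_richness = as.integer(baseline_richness),
    seed = as.integer(seed), fua_sd = fua_sd,
    invasion_intercept = invasion_intercept,
    nonnative_colour_boost = nonnative_colour_boost
  )
  counts <- c("n_species", "n_nonnative", "n_fuas", "cells_per_fua", "baseline_richness")
  for (nm in counts) if (is.na(cfg[[nm]]) || cfg[[nm]] < 0) stopf("%s must be a nonnegative count", nm)
  if (cfg$n_species < 4) stopf("n_species must be >= 4 (neighbour joining needs >= 4 taxa)")
  if (cfg$n_nonnative > cfg$n_species) stopf("n_nonnative must not exceed n_species")
  if (cfg$cells_per_fua < 1) stopf("cells_per_fua must be >= 1")
  if (cfg$n_fuas < 1) stopf("n_fuas must be >= 1")
  if (cfg$baseline_richness < 3) stopf("baseline_richness must be >= 3")
  if (cfg$fua_sd < 0) stopf("fua_sd must be >= 0")
  class(cfg) <- "sim_config"
  cfg
}

species_ids <- function(n) sprintf("sp%03d", seq_len(n))

# Bernoulli draws for one binary trait group; every species keeps at least one
# category present (the group's commonest category is switched on if none drew).
draw_binary_group <- function(n, probs) {
  m <- vapply(probs, function(p) stats::rbinom(n, 1L, p), integer(n))
  if (is.null(dim(m))) m <- matrix(m, nrow = n)
  empty <- rowSums(m) == 0
  if (any(empty)) m[empty, which.max(probs)] <- 1L
  m
}

#' Generate a synthetic species pool with cultural and regulating traits
#'
#' Draws one row per species: five continuous/ordinal cultural traits (tail
#' length and body mass on their raw scales, colour diversity and elaboration
#' as 0-1 scores, crest as an ordinal 0-3), and 22 binary regulating traits in
#' four groups (social degree 3, nesting strategy 5, diet 6, foraging
#' technique 8) plus body mass. Binary categories are not mutually exclusive;
#' each is drawn independently with at least one category forced present per
#' group. Body mass is lognormal, tail length allometric in mass with
#' lognormal noise, colour scores are beta-distributed. The last
#' `n_nonnative` species are flagged non-native and get their colour scores
#' shifted towards the attractive extreme by `nonnative_colour_boost`.
#'
#' @param cfg a [sim_config()].
#' @return A raw [trait_table()] (unscaled; see [prepare_traits()]).
#' @export
generate_species_pool <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  n <- cfg$n_species
  with_seed(cfg$seed + 101L, {
    body_mass <- stats::rlnorm(n, meanlog = log(30), sdlog = 1)
    tail_length <- 2.5 * body_mass^(1 / 3) * stats::rlnorm(n, 0, 0.25)
    colour_diversity <- stats::rbeta(n, 2, 2)
    colour_elaboration <- stats::rbeta(n, 2, 5)
    crest <- sample(0:3, n, replace = TRUE, prob = c(0.80, 0.10, 0.07, 0.03))
    nonnative <- c(rep(FALSE, n - cfg$n_nonnative), rep(TRUE, cfg$n_nonnative))
    if (cfg$nonnative_colour_boost > 0 && any(nonnative)) {
      b <- 1 + cfg$nonnative_colour_boost
      colour_diversity[nonnative] <- 1 - (1 - colour_diversity[nonnative])^b
      colour_elaboration[nonnative] <- 1 - (1 - colour_elaboration[nonnative])^b
    }
    groups <- list(
      social = list(
        cols = c("social_solitary", "social_semicolonial", "social_colonial"),
        probs = c(0.70, 0.20, 0.15)
      ),
      nesting = list(
        cols = c("nest_ground", "nest_cavity", "nest_open", "nest_close_ground", "nest_closed_arboreal"),
        probs = c(0.30, 0.25, 0.45, 0.20, 0.30)
      ),
      diet = list(
        cols = c("diet_granivore", "diet_folivore", "diet_frugivore",
                 "diet_invertebrates", "diet_vertebrates", "diet_carrion"),
        probs = c(0.40, 0.10, 0.20, 0.70, 0.15, 0.05)
      ),
      foraging = list(
        cols = c("forage_air_aquatic_pursuit", "forage_sally", "forage_foliage_glean",
                 "forage_pounce", "forage_peck", "forage_dig", "forage_overturn", "forage_probe"),
        probs = c(0.10, 0.20, 0.45, 0.15, 0.50, 0.10, 0.05, 0.10)
      )
    )
    df <- data.frame(
      species = species_ids(n), nonnative = nonnative,
      tail_length = tail_length, colour_diversity = colour_diversity,
      colour_elaboration = colour_elaboration, crest = crest,
      body_mass = body_mass, stringsAsFactors = FALSE
    )
    meta <- data.frame(
      trait = c("tail_length", "colour_diversity", "colour_elaboration", "crest", "body_mass"),
      group = c("relative_tail_length", "colour_diversity", "colour_elaboration", "crest", "body_mass"),
      service = c(rep("cultural", 4), "regulating"),
      type = "continuous", stringsAsFactors = FALSE
    )
    for (g in names(groups)) {
      m <- draw_binary_group(n, groups[[g]]$probs)
      colnames(m) <- groups[[g]]$cols
      df <- cbind(df, as.data.frame(m))
      meta <- rbind(meta, data.frame(
        trait = groups[[g]]$cols, group = g, service = "regulating",
        type = "binary", stringsAsFactors = FALSE
      ))
    }
    trait_table(df, meta)
  })
}

#' Generate a pure-birth phylogeny over the species pool
#'
#' Simulates a Yule (pure-birth) tree and labels its tips with the species
#' ids, standing in for a real supertree. Branch lengths are strictly
#' positive. Traits are, by default, generated independently of this tree, so
#' the phylogenetic correction has a signal-free ground truth.
#'
#' @param n_species number of tips (>= 4).
#' @param seed integer seed.
#' @param labels optional tip labels (defaults to `sp001`, `sp002`, ...).
#' @return An [ape::rphylo()]-style `phylo` object.
#' @export
generate_phylogeny <- function(n_species, seed = 1, labels = NULL) {
  if (n_species < 4) stopf("n_species must be >= 4")
  labels <- labels %||% species_ids(n_species)
  stopifnot(length(labels) == n_species)
  with_seed(as.integer(seed) + 202L, {
    tr <- ape::rphylo(n_species, birth = 1, death = 0)
    tr$tip.label <- labels[seq_len(n_species)]
    tr
  })
}

#' Generate a synthetic income landscape
#'
#' Lays out `n_fuas` functional urban areas, each a row of unit-square atlas
#' grid cells, and overlays every cell with 1-4 neighbourhood income polygons
#' (vertical strips, so overlap areas are exact). Neighbourhood incomes are
#' lognormal around a cell-level median (meanlog `log(28000)`, roughly an
#' Iberian annual household income, with between-cell sdlog 0.3 and
#' within-cell sdlog 0.15). FUAs are split ~80/20 between two countries and
#' the per-cell area-weighted income is standardized within country.
#'
#' @param cfg a [sim_config()].
#' @return A `landscape` list: `cells`, `fuas`, `neighbourhoods` (rectangle
#'   data frames) and `income` (per-cell weighted income with country z-score).
#' @export
generate_landscape <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(cfg$seed + 303L, {
    nf <- cfg$n_fuas; k <- cfg$cells_per_fua
    n_b <- if (nf >= 2) max(1L, as.integer(round(0.2 * nf))) else 0L
    fua_ids <- sprintf("fua%02d", seq_len(nf))
    fua_country <- c(rep("A", nf - n_b), rep("B", n_b))
    cells <- do.call(rbind, lapply(seq_len(nf), function(f) {
      off <- (f - 1) * (k + 2)
      data.frame(
        cell = sprintf("%s_c%02d", fua_ids[f], seq_len(k)),
        fua = fua_ids[f], country = fua_country[f],
        xmin = off + seq_len(k) - 1, xmax = off + seq_len(k),
        ymin = 0, ymax = 1, stringsAsFactors = FALSE
      )
    }))
    fuas <- do.call(rbind, lapply(seq_len(nf), function(f) {
      r <- cells[cells$fua == fua_ids[f], ]
      data.frame(
        fua = fua_ids[f], country = fua_country[f],
        xmin = min(r$xmin), xmax = max(r$xmax), ymin = 0, ymax = 1,
        stringsAsFactors = FALSE
      )
    }))
    nbs <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
      kk <- sample(1:4, 1)
      brk <- sort(stats::runif(kk - 1))
      edges <- cells$xmin[i] + c(0, brk, 1)
      mu <- stats::rnorm(1, log(28000), 0.3)
      data.frame(
        nb = sprintf("%s_n%d", cells$cell[i], seq_len(kk)),
        income = stats::rlnorm(kk, mu, 0.15),
        xmin = edges[-length(edges)], xmax = edges[-1],
        ymin = 0, ymax = 1, stringsAsFactors = FALSE
      )
    }))
    inc <- cell_income(cells, nbs)
    inc <- standardize_income(inc)
    structure(
      list(cells = cells, fuas = fuas, neighbourhoods = nbs, income = inc),
      class = "landscape"
    )
  })
}

#' Generate presence/absence communities along the income gradient
#'
#' Expected richness of cell *c* is
#' `baseline_richness * exp(richness_income_slope * z_c + u_f)` with a
#' Gaussian FUA random intercept `u_f` (sd `fua_sd`); realised richness is
#' Poisson. Native species are drawn without replacement with weights
#' `exp(service_income_slope * z_c * originality_i)`, where originality is a
#' species' mean group-weighted Gower distance to the rest of the pool
#' (standardized); with a negative slope, higher-income cells therefore
#' assemble functionally ordinary, mutually similar species. Each non-native
#' species occurs independently with probability
#' `plogis(invasion_intercept + invasion_income_slope * z_c)`.
#'
#' @param cfg a [sim_config()].
#' @param pool a raw [trait_table()] from [generate_species_pool()].
#' @param income per-cell income data frame with columns `cell`, `fua`,
#'   `country`, `z_income` (e.g. `generate_landscape(cfg)$income`).
#' @return A [community_matrix()].
#' @export
generate_communities <- function(cfg, pool, income) {
  stopifnot(inherits(cfg, "sim_config"), inherits(pool, "trait_table"))
  if (!all(c("cell", "fua", "country", "z_income") %in% names(income))) {
    stopf("income must have cell, fua, country, z_income (standardized per country)")
  }
  prep <- prepare_traits(pool)
  dcul <- gower_distance(prep, "cultural")
  dreg <- gower_distance(prep, "regulating")
  originality <- rowMeans((dcul + dreg) / 2)
  originality <- as.numeric(scale(originality))
  names(originality) <- pool$species
  natives <- pool$species[!pool$nonnative]
  aliens <- pool$species[pool$nonnative]
  with_seed(cfg$seed + 404L, {
    u <- stats::rnorm(length(unique(income$fua)), 0, cfg$fua_sd)
    names(u) <- unique(income$fua)
    lambda <- cfg$baseline_richness *
      exp(cfg$richness_income_slope * income$z_income + u[income$fua])
    if (any(lambda < 3)) {
      warnf("%d cells have expected richness < 3; they are likely to be dropped by the minimum-richness filter", sum(lambda < 3))
    }
    pa <- matrix(0L, nrow(income), length(pool$species),
                 dimnames = list(income$cell, pool$species))
    for (i in seq_len(nrow(income))) {
      z <- income$z_income[i]
      r <- min(stats::rpois(1, lambda[i]), length(natives))
      if (r > 0) {
        w <- exp(cfg$service_income_slope * z * originality[natives])
        picked <- sample(natives, r, prob = w)
        pa[i, picked] <- 1L
      }
      if (length(aliens)) {
        p <- stats::plogis(cfg$invasion_intercept + cfg$invasion_income_slope * z)
        hit <- stats::runif(length(aliens)) < p
        pa[i, aliens[hit]] <- 1L
      }
    }
    community_matrix(
      pa,
      cells = data.frame(cell = income$cell, fua = income$fua,
                         country = income$country, stringsAsFactors = FALSE),
      species = data.frame(species = pool$species, nonnative = pool$nonnative,
                           stringsAsFactors = FALSE)
    )
  })
}

#' Simulate a complete synthetic study
#'
#' Runs the whole generator: species pool, phylogeny, landscape, communities.
#' The returned object carries the generating slopes in `$truth` so recovery
#' of the effect structure can be tested end to end.
#'
#' @param cfg a [sim_config()].
#' @return A `synthetic_study` list: `traits`, `phylogeny`, `landscape`,
#'   `income`, `communities`, `truth`.
#' @export
simulate_study <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  pool <- generate_species_pool(cfg)
  phy <- generate_phylogeny(cfg$n_species, cfg$seed, labels = pool$species)
  land <- generate_landscape(cfg)
  comm <- generate_communities(cfg, pool, land$income)
  stopifnot(
    all(colnames(comm$pa) %in% pool$species),
    all(colnames(comm$pa) %in% phy$tip.label),
    !anyNA(comm$cells$fua), !anyNA(comm$cells$country)
  )
  structure(
    list(
      traits = pool, phylogeny = phy, landscape = land,
      income = land$income, communities = comm,
      truth = list(
        richness_income_slope = cfg$richness_income_slope,
        invasion_income_slope = cfg$invasion_income_slope,
        service_income_slope = cfg$service_income_slope,
        config = cfg
      )
    ),
    class = "synthetic_study"
  )
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat(sprintf(
    "synthetic_study: %d species (%d non-native), %d cells in %d FUAs\n",
    ncol(x$communities$pa), sum(x$traits$nonnative),
    nrow(x$communities$pa), length(unique(x$communities$cells$fua))
  ))
  cat(sprintf(
    "  generating slopes: richness %+0.2f, invasion %+0.2f, service %+0.2f\n",
    x$truth$richness_income_slope, x$truth$invasion_income_slope,
    x$truth$service_income_slope
  ))
  invisible(x)
}
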