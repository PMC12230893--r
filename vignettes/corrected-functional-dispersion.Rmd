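---
title: "Corrected functional dispersion along urban socio-economic gradients"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Corrected functional dispersion along urban socio-economic gradients}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(urbancfd)
```

## The problem

Wealthier city neighbourhoods often hold more biodiversity than poorer ones
(the *luxury effect*), and urban areas are simultaneously hotspots of
non-native species. Bird communities supply two broad classes of ecosystem
services — cultural (aesthetic: colour, ornaments, smallness) and regulating
(pest control, seed dispersal: diet, foraging, nesting, sociality, size) —
and each can be proxied by a dedicated set of functional traits. This package
implements a complete, testable pipeline for asking how species richness and
trait-based service provision of presence/absence bird communities respond to
a median-household-income gradient, and how non-native species moderate that
response.

The spatial units are atlas grid cells inside functional urban areas (FUAs:
a city core plus its commuting zone). Each grid cell is one community.
Communities holding at least one non-native species are *invaded*, the rest
*non-invaded*, and removing the non-natives from an invaded community gives
its *invaded no alien* variant, paired to the original by cell id.

## From traits to corrected functional dispersion

**Trait preparation.** Traits come in nine functional groups: five cultural
(relative tail length, colour diversity, colour elaboration, crest length,
inverse body mass) and four binary regulating groups (social degree, nesting
strategy, diet, foraging technique: 3, 5, 6 and 8 categories, none mutually
exclusive) plus body mass. Relative tail length is the residual of log tail
length regressed on log body mass; inverse body mass replaces raw mass in the
cultural set to avoid collinearity with it. Continuous traits are min-max
scaled to [0, 1] (mass log-transformed first); binary categories stay 0/1.
Within each service set, any trait pair with |Pearson r| strictly above 0.70
triggers removal of the member with the larger mean absolute correlation —
|r| = 0.70 itself is acceptable. Screening is per service set because each
set feeds its own dissimilarity matrix; the screen report records every drop.

**Group-weighted Gower distance.** Pairwise dissimilarity is the mean over
trait groups of the within-group score: a continuous trait contributes
|x_i − x_j| (ranges are 1 after scaling), a binary group the mean mismatch
over its categories. Grouping keeps, say, the eight foraging categories from
out-voting body mass. Distances lie in [0, 1]. An equal-column-weight variant
is available (`group_weighting = FALSE`).

**Functional trees and dispersion.** Each service's Gower matrix becomes an
unrooted tree by classical Saitou–Nei neighbour joining (`nj_tree()`, built
on ape's implementation). Labels are sorted before joining so the tree never
depends on input order; negative branch lengths, possible on non-additive
input, are clamped to zero with the deficit moved to the adjacent edge,
approximately preserving tip-to-tip path lengths. On additive input the
tree's patristic distances reproduce the input exactly (a tested round-trip
property). Functional dispersion (FD) of a community is the mean patristic
distance over all unordered pairs of its members — the expected trait
distance between two randomly chosen species. Phylogenetic dispersion (PD)
is the same statistic on a phylogenetic tree. Communities with fewer than
three species are excluded throughout: their dispersion estimates are
unstable and a pairwise mean needs at least three members to be informative.

**Phylogenetic correction and the null model.** FD partly reflects shared
evolutionary history, so FD is regressed on PD across communities (OLS with
intercept, pooled across countries) and the residuals are kept: they are
exactly orthogonal to PD (r = 0 to machine precision; a tested invariant).
To remove the mechanical dependence of dispersion on richness, a tip-label
randomization null is built: in each of `n_iter` iterations (999 by default)
every species is assigned a random position on the functional and
phylogenetic trees, FD and PD are recomputed for all communities, the FD~PD
regression is refit *within that iteration*, and its residuals are the
iteration's 'expected' values. The corrected functional dispersion (CFD) of
a community is the standardized effect size

> SES = (observed residual − mean of null residuals) / sd of null residuals

with the sample (n−1) standard deviation. CFD = 0 means dispersion as
expected given richness; positive values mark overdispersed communities
(service provision above expectation), negative underdispersed ones.
Degenerate nulls (sd = 0, e.g. equal-branch star trees where every
permutation is equivalent) yield a flagged `NA`, never ±infinity.

One permutation is shared between the two trees per iteration, keeping a
species' functional and phylogenetic positions co-shuffled — equivalent to
randomizing community membership against the species pool. Independent
permutations per tree are available (`shared_permutation = FALSE`) for
sensitivity analysis.

**Comparing community variants.** Invaded-no-alien communities are scored in
the *same* pooled run as the main communities: one FD~PD regression and one
null stream cover all variants. This matters. Scoring each set in its own
run recenters each set's residuals through its own regression intercept,
which absorbs precisely the systematic FD difference the paired comparison
is meant to detect; the pooled run keeps SES values on one common scale so
the per-cell difference isolates the non-natives' contribution.

## Community assembly and the income covariate

The assembly pipeline runs in a fixed, logged order: FUA-overlap filter
(keep cells with at least 50% of their area inside the FUA union; exactly
50% is kept; straddling cells go to the largest-overlap FUA), optional
rare-species occurrence filter, invasion classification, minimum-richness
filter (k = 3), income join. Counts are logged at each stage.

The occurrence filter is a sensitivity variant, off by default: per country,
species observed in fewer than round(1% × cells) cells are removed, with
round-half-away-from-zero so that 709 cells give a threshold of 7 and 111
cells a threshold of 1 ("at least" — boundary species are retained).

Cell income is the overlap-area-weighted mean of neighbourhood median
incomes: `income = Σ area_k · income_k / Σ area_k`, so a neighbourhood
contributes to a cell only through the area they share and is never
over-represented when it spans several cells. Cells intersecting no income
polygon are missing (not zero) and are dropped listwise from models. Incomes
are standardized within country (sample sd) to make gradients comparable
across countries with different costs of living; the z-score is invariant to
currency changes. All geometry is axis-aligned rectangles in one projected
plane, so every overlap area is exact — the package deliberately trades
geographic generality for arithmetic that a test can pin down.

## Inference

Three mixed models relate the responses to the gradient, each with fixed
effects `z_income × community type + country` and a random intercept per
FUA (cells within a FUA are not independent):

* **richness** — negative binomial with log link (variance μ + μ²/θ, θ
  estimated jointly, Laplace-approximated ML via glmmTMB). The Poisson
  alternative is checked by `overdispersion_test()`: the sum of squared
  Pearson residuals against a χ² with residual df; a ratio well above 1
  recommends the negative binomial.
* **CFD (cultural, regulating)** — Gaussian, fitted by REML.

Per-term tests are marginal (Type-III-style): Wald χ² for the negative
binomial model, approximate F for the Gaussian models. For the F tests the
package uses Satterthwaite denominator degrees of freedom (lmerTest) rather
than the coarser containment heuristic — Satterthwaite is standard, finer,
and changes nothing about which statistic type is reported. Terms with a
single observed level (e.g. country in a one-country simulation) are dropped
automatically; singular random-effect variances are reported as 0 with a
warning, and non-convergence raises a flag rather than failing silently.

The invaded vs invaded-no-alien contrast uses an intercept-only model on the
per-cell difference with the FUA random intercept retained (the random
structure is unstated in the source analysis; keeping it is the conservative
choice, and with fewer than two FUAs the test falls back to a one-sample t).

Residual spatial independence is checked with a distance-binned correlogram:
standardized residual pair products averaged within distance bins (a binned
Moran-type estimate), lightly smoothed across adjacent bins, with 95%
percentile confidence intervals from bootstrap resampling of cells (1000 by
default) up to two-thirds of the maximum pairwise distance. The decision
rule is the one that matters downstream: no autocorrelation when every bin's
interval includes zero. A full cubic-spline covariance smoother would add
machinery without changing that verdict, so the binned estimator is the
package's design choice.

## What the synthetic generator emulates

`simulate_study()` produces every input the pipeline needs, with the effect
structure the analysis assumes, so the whole method is testable end to end:

* **Species pool** (`generate_species_pool()`): lognormal body mass (meanlog
  log 30 g, sdlog 1 — a songbird-dominated pool), allometric tail length
  (mass^⅓ with lognormal noise), beta-distributed colour scores, ordinal
  crest, and independent Bernoulli draws for the 22 binary categories with
  at least one category forced present per group. Non-natives (the last
  `n_nonnative` species) have their colour scores pushed towards the
  attractive extreme by `nonnative_colour_boost` (default 2), mirroring the
  colourful-escapee profile of urban invaders.
* **Phylogeny** (`generate_phylogeny()`): a pure-birth (Yule) tree. Traits
  are *not* evolved on it by default: independent traits give the
  phylogenetic correction a signal-free ground truth, the cleanest null for
  SES calibration.
* **Landscape** (`generate_landscape()`): FUAs as rows of unit-square cells,
  each cell partitioned into 1–4 neighbourhood strips with lognormal incomes
  (meanlog log 28000 — an Iberian-scale annual household income — between-cell
  sdlog 0.3, within-cell 0.15), exercising the area-weighted overlay
  exactly. FUAs split ~80/20 between two countries.
* **Communities** (`generate_communities()`): expected richness
  `baseline_richness · exp(richness_income_slope · z + u_FUA)` with Poisson
  realisation and Gaussian FUA intercepts (sd `fua_sd`, default 0.2).
  Natives are sampled without replacement with weights
  `exp(service_income_slope · z · originality)`, where originality is the
  species' mean Gower distance to the pool over both trait sets; a negative
  slope therefore assembles functionally ordinary, mutually similar species
  in high-income cells — the trait-filtering (homogenisation) reading of a
  declining service gradient, and the reason both service CFDs respond. It
  acts on overall originality rather than cultural traits alone because the
  regulating gradient would otherwise carry no signal. Non-natives occur
  independently with probability
  `plogis(invasion_intercept + invasion_income_slope · z)`.

What the generator does **not** emulate: real avian biogeography or atlas
species lists, spatially autocorrelated income surfaces, phylogenetic signal
in traits (available as an explicit option only through supplying your own
trees), detection error, and abundance (the whole pipeline is
presence/absence by design). Passing tests therefore show the *method*
behaves as specified under its own assumptions, not that any particular
field dataset satisfies those assumptions.

## Numerical choices and problem sizes

Tie-breaks and degenerate inputs are pinned down so results are
reproducible: sorted-label canonicalization before neighbour joining;
constant trait columns scale to 0 (they carry no dissimilarity either way);
collinearity ties fall back to column order; null-model permutations come
from one master seed; `ses()` uses the sample sd and flags sd = 0. The
closed-form simple-regression residual path used inside the null loop equals
`residuals(lm(fd ~ pd))` to machine precision, including the constant-PD
degenerate case.

The validation suite runs the SES calibration on 200 communities × 999
iterations × 3 seeds (observed null mean ~0, |SES| > 1.96 rate ~5%), the
neighbour-joining round trip on 50 random 8-tip trees, an exhaustive
5!-relabeling oracle against the sampled null, and 25 end-to-end replicates
of 500 cells × 60 species with 199 null iterations for sign recovery —
sizes chosen to make the stochastic checks stable while keeping a full run
in the low minutes on one core.

## Known limitations

* Rectangles only; real cadastral polygons need pre-processing into a
  projected rectangular approximation or a precomputed overlap table.
* The FD~PD correction is a single pooled OLS across all communities;
  a per-country correction is obtained by running `cfd()` on per-country
  subsets, and nonlinear FD–PD relationships are not modelled.
* The null model randomizes tip labels only; richness-constrained swap
  algorithms and abundance-weighted variants are out of scope.
* The paired contrast assumes the no-alien variant passes the same
  minimum-richness filter; cells failing it drop out of the pairing, which
  slightly conditions that test on richness.
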