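# urbancfd

Quantifying how urban socio-economic status and non-native species shape
bird species richness and trait-based ecosystem-service provision.

Areas of higher socio-economic status within cities often hold more
biodiversity than poorer ones (the *luxury effect*), and cities are hotspots
for non-native birds. `urbancfd` implements a complete analysis pipeline for
presence/absence bird communities on atlas grid cells within functional
urban areas (FUAs): from species × trait tables and community matrices,
through trait-tree functional diversity, to mixed-effects inference along a
median-household-income gradient — plus a synthetic-data generator that
reproduces the assumed effect structure so every stage is testable without
restricted-access atlas data.

## The statistic at the core

For a community *i* with at least three species, functional dispersion is
the mean patristic distance between all species pairs on a neighbour-joining
tree built from group-weighted Gower trait dissimilarities (separately for
**cultural** traits — relative tail length, colour diversity and
elaboration, crest, inverse body mass — and **regulating** traits — social
degree, nesting, diet, foraging, body mass). Phylogenetic dispersion
FD<sub>phy</sub> is the same statistic on a phylogeny. The **corrected
functional dispersion (CFD)** is the standardized effect size of the
phylogenetically corrected dispersion against a tip-label randomization
null:

    resid_i = FD_i − (a + b · PD_i)             (OLS across communities)
    CFD_i   = (resid_i − mean(resid*_i)) / sd(resid*_i)

where resid\*<sub>i</sub> are residuals of the same regression refit in each
of 999 random tip relabelings of both trees. CFD = 0 means dispersion as
expected given richness; CFD > 0 overdispersion (service provision above
expectation); CFD < 0 underdispersion. Inference then uses mixed models with
a FUA random intercept: negative-binomial (log link) for richness, Gaussian
for CFD, each with fixed effects `scaled income × community type + country`,
and an intercept-only paired model for the invaded vs invaded-no-alien
contrast.

## Worked example

```r
library(urbancfd)

cfg   <- sim_config(n_species = 50, n_nonnative = 5,
                    n_fuas = 12, cells_per_fua = 10, seed = 7)
study <- simulate_study(cfg)
study
#> synthetic_study: 50 species (5 non-native), 120 cells in 12 FUAs
#>   generating slopes: richness +0.15, invasion +0.80, service -0.50

fit <- run_analysis(study, n_iter = 199, seed = 7)
fit
#> Luxury-effect CFD analysis
#>   filter log:  start=120, after_overlap_filter=120, after_occurrence_filter=120, after_min_richness=120, after_income_join=120, invaded=86, non_invaded=34
#>   CFD cultural: mean -0.181 (sd 1.268)
#>   CFD regulating: mean -0.134 (sd 1.569)
#>   richness ~ income: +0.2399 (p = 0.000132)
#>   cfd_cultural ~ income: -1.2817 (p = 1.07e-05)
#>   cfd_regulating ~ income: -1.0806 (p = 0.00285)
#>   paired invaded - no-alien (cultural): +0.870 (p = 5.19e-15)
#>   paired invaded - no-alien (regulating): +0.564 (p = 2.95e-16)
#>   paired invaded - no-alien (richness): +1.547 (p = 1.76e-31)
```

Reading the output: richness rises with scaled income (the generating slope
was +0.15 on the log scale; the model estimates +0.24 on these 120 cells),
both service CFDs fall along the gradient (the generator filters high-income
communities towards functionally ordinary species), and removing the
colour-distinctive non-native species from invaded communities lowers their
cultural CFD by 0.87 SES units — the non-natives' contribution to aesthetic
service provision. Individual stages are available as plain functions
(`prepare_traits()`, `gower_distance()`, `nj_tree()`, `dispersion()`,
`cfd()`, `fit_mixed()`, `overdispersion_test()`, `spatial_correlogram()`,
...), and `cfd()` objects support `print()`, `summary()`, `plot()`,
`residuals()` and `as.data.frame()`.

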