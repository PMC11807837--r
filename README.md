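# traitshift

Trait-based causal analysis of tree communities in human-modified tropical
landscapes.

Forest loss, fragmentation, edge density and local degradation do not just
remove species — they filter them by their functional traits, replacing
dense woods, large animal-carried seeds and tall statures with light-wooded,
small-seeded, endozoochorous "winners". `traitshift` is an R package for
ecologists who want to quantify that replacement from standard plot
inventories: a plot table, a plot × species stem-count table, a species
trait table (wood density, seed mass, LMA, maximum height, dispersal
syndrome) and a landscape table of disturbance metrics per buffer scale.

## What it computes

* **Community profiles** — community-weighted means and lower/upper 5%
  abundance-weighted percentiles per plot × trait,
  `CWM = Σ wᵢtᵢ / Σ wᵢ`, with percentiles defined on the stem-expanded
  distribution; trait-coverage filters (≥ 50% species-level and ≥ 80% total
  coverage of stems) decide which plots enter which trait's analyses.
* **Backdoor-adjusted causal effects** — for each exposure × trait ×
  statistic × region × buffer scale, the standardized total effect β from
  OLS with the exposure's DAG parents as controls (loss → ∅;
  patches → {loss}; edge → {loss, patches}; degradation → all three),
  95% t-intervals, and Moran's-eigenvector-map filtering of residual
  spatial autocorrelation over four candidate spatial weighting matrices
  (Gabriel / MST × binary / linear decay).
* **Winner–loser classification** — species forest-loss niche centroids
  (abundance-weighted mean forest loss over occupied plots) against a
  10,000-iteration within-region permutation null; standardized effect
  sizes, strict 95% exceedance classification, abundance-weighted trait–SES
  regressions and winner/loser ANOVA contrasts.
* **dc-CA** — double-constrained correspondence analysis with plot-total
  division, region as covariate, eigenvalues equal to squared fourth-corner
  correlations, the community/species **max permutation test**, and a
  Bonferroni-corrected screen of predictors across buffer scales.
* **A synthetic-data generator** with closed-form ground truth
  (`scenario_config()`, `simulate_scenario()`, `scenario_truth()`), so the
  entire pipeline is testable without any downloads.

## Worked example

Simulate a two-region study whose ground truth places a standardized direct
forest-loss effect of −0.5 on community wood density (and −0.25 via local
degradation), then run the three analysis levels:

```r
library(traitshift)
library(dplyr)

cfg  <- scenario_config(n_regions = 2, plots_per_region = 40,
                        n_species_pool = 400, seed = 42)
sim  <- simulate_scenario(cfg)
data <- as_community_data(sim)

profiles <- community_profiles(data$abundance, data$traits)
head(profiles, 4)
#> # A tibble: 4 × 6
#>   plot_id trait           cwm p_lower p_upper coverage
#>   <chr>   <chr>         <dbl>   <dbl>   <dbl>    <dbl>
#> 1 p0001   wood_density  0.529   0.304   0.777        1
#> 2 p0001   seed_mass     5.19    2.17    8.41         1
#> 3 p0001   lma          84.3    43.1   139.           1
#> 4 p0001   h_max        21.5    11.7    40.1          1
```

The CWM of wood density in plot `p0001` is 0.529 g cm⁻³ and its community's
extreme percentiles span 0.30–0.78; seed mass is profiled on the log scale.
The causal grid then estimates the total effect of forest loss per region:

```r
run_effect_grid(data, traits = c("wood_density", "seed_mass"),
                statistics = "cwm", scales = 2000,
                exposures = "forest_loss", profiles = profiles, seed = 42) |>
  select(exposure, trait, region, beta, ci_low, ci_high, significant, r2_adj)
#> # A tibble: 4 × 8
#>   exposure    trait        region   beta ci_low ci_high significant r2_adj
#> 1 forest_loss wood_density R1     -0.658 -0.905  -0.411 TRUE         0.418
#> 2 forest_loss wood_density R2     -0.709 -0.940  -0.477 TRUE         0.489
#> 3 forest_loss seed_mass    R1     -0.620 -0.878  -0.363 TRUE         0.369
#> 4 forest_loss seed_mass    R2     -0.467 -0.757  -0.176 TRUE         0.197
```

One standard deviation of (log) forest loss lowers CWM wood density by
about 0.66–0.71 standard deviations — the generator's total effect is
−0.68 (−0.5 direct plus the degradation-mediated path), so the backdoor
estimates recover the truth inside their intervals. At the species level:

```r
niche <- niche_classification(data, n_iter = 1000, seed = 42)
table(niche$status)
#>   loser neutral  winner
#>      60     196      40

dcca_term_screen(data, scales = 2000, n_perm = 199, seed = 42) |>
  select(term, eigenvalue, p_max, p_adj, significant)
#> # A tibble: 4 × 5
#>   term         eigenvalue p_max p_adj significant
#> 1 forest_loss    0.275    0.005  0.02 TRUE
#> 2 degradation    0.0421   0.015  0.06 FALSE
#> 3 edge_density   0.0155   0.175  0.7  FALSE
#> 4 n_patches      0.000430 0.99   1    FALSE
```

Most species are neutral; the identified winners and losers sit at opposite
ends of the wood-density spectrum (`winner_loser_contrast()`), and the
multivariate screen ranks forest loss far above the configuration terms,
whose conditional contributions are non-significant — the same picture the
univariate causal grid gives. `plot_effect_grid()`, `plot_niche()` and
`autoplot()` on a dc-CA fit draw the standard displays, and
`run_pipeline(config)` chains every stage from one (YAML) configuration
with a single seed.

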