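---
title: "Trait-based causal analysis of disturbed tree communities: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Trait-based causal analysis of disturbed tree communities: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(traitshift)
library(dplyr)
```

# The scientific problem

Tropical forest plots embedded in human-modified landscapes experience four
interrelated disturbance pressures: landscape-scale **forest loss** (percent
of non-forest cover in a buffer around the plot), **fragmentation** (number
of forest patches), **edge density** (share of forest close to patch
boundaries) and **local degradation** (proxied by the inverse of community
basal area per sampled area). These pressures are expected to reshape the
functional composition of the remaining tree communities: light woods, small
seeds and animal-ingested (endozoochorous) dispersal should gain dominance,
while dense woods, large seeds and synzoochorous dispersal decline.

`traitshift` implements the full analysis chain for that question at three
biological levels:

1. **Community level.** Per plot and trait, the community-weighted mean
   (CWM) and the lower/upper 5% abundance-weighted percentiles summarise
   trait dominance and extremes. Standardized total causal effects of each
   disturbance variable on these summaries are estimated by ordinary least
   squares under backdoor adjustment, with Moran's-eigenvector-map (MEM)
   filtering of residual spatial autocorrelation.
2. **Species level.** Each species' forest-loss niche centroid (SNC, its
   abundance-weighted mean forest loss) is compared with a permutation null
   that redistributes its abundance across the region's plots; species above
   (below) 95% of the null are winners (losers), and standardized effect
   sizes (SES) are regressed on traits.
3. **Multivariate level.** A double-constrained correspondence analysis
   (dc-CA) pairs a composite trait with a composite disturbance gradient,
   tested by the community/species max permutation test with the region
   factor as covariate and Bonferroni correction across screened terms.

# Causal model and backdoor adjustment

The assumed within-region DAG places directed edges
loss → patches, loss → edge, patches → edge, and {loss, patches, edge} →
degradation, with every disturbance node pointing at the community outcome.
For total effects the minimal backdoor adjustment set of an exposure is its
parent set:

| exposure | controls |
|---|---|
| forest loss | — |
| n patches | forest loss |
| edge density | forest loss, n patches |
| degradation | forest loss, n patches, edge density |

Forest loss and patch counts are `log1p`-transformed (zeros occur in fully
forested landscapes; seed mass, being strictly positive, is `log`ed), then
predictors are z-scored within region × scale and outcomes within region, so
that a coefficient is the response in outcome standard deviations to one
standard deviation of the predictor. Significance is read from the t-based
95% confidence interval excluding zero; no multiplicity correction is
applied across the effect grid (each model reports its own interval), while
corrected inference lives in the dc-CA term screen.

A companion predictive (non-causal) model selects among the four exposures
by small-sample AIC, a desk-scale approximation to out-of-sample predictive
accuracy; it reports explanatory power, not effects.

# Spatial filtering

Residual spatial autocorrelation is handled with MEM bases built from four
candidate spatial weighting matrices: {Gabriel graph, minimum spanning tree}
× {binary, linear distance-decay} weights. Eigenvectors of the doubly
centred weight matrix with positive eigenvalues are ordered by Moran's *I*.
The unfiltered model's residuals are tested by a one-sided permutation
Moran test under each candidate, Šidák-corrected across the four (the
correction procedure is not prescribed beyond "corrected"; Šidák is exact
for independent candidates and mildly conservative otherwise). If any
candidate is significant, eigenvectors are added greedily (largest absolute
correlation with the current residuals) until the residual Moran test is
non-significant; the candidate needing fewest eigenvectors wins. The
adjusted R² of the model without spatial terms is reported separately from
the full model's, since it is ambiguous which one a reader wants.

# Weighted percentile convention

The field-level definition of a trait percentile does not fix an
interpolation rule. We use the step-function inverse of the cumulative
weight with averaging at exact jumps, which is identical to the empirical
percentile (type-2) of the stem-expanded trait vector — every stem one
entry. That equivalence makes an exact brute-force oracle possible, and the
test suite asserts equality at 1e-12 (in practice exact) on random plots.
Species missing a trait are dropped from that trait's weights, and the
retained-weight share is reported as coverage. An unweighted variant
(`weighted = FALSE`) treats every present species equally, since it is not
fully settled whether percentiles should weight by abundance; the
abundance-weighted reading is the default, consistent with the
"abundance-weighted trait distribution" framing.

# Niche null model

For each qualifying species × region (at least five occupied plots within
the region by default), the null redistributes the species' abundance
vector over the region's plots by uniform permutation — per species, not as
a joint matrix shuffle, because the procedure recalculates each species'
centroid after randomizing that species' abundance. SES uses the null's
standard deviation; a robust-spread variant was considered and rejected to
keep the SES interpretable as a z-score. The winner/loser rule is a strict
exceedance against the empirical null (ties count as non-exceedance,
conservative), and a degenerate null (zero spread) classifies as neutral
with an undefined SES rather than erroring. Each species draws from an RNG
stream derived from the global seed and its own identifier, so results are
stable under adding or removing other species. Trait–SES regressions are
reported both abundance-weighted and unweighted: a markedly better weighted
fit indicates that community change is carried by a few dominant species.
The regression response defaults to SES (the raw-centroid response is a
flag), matching the species-level analysis as described.

# dc-CA and the max test

Counts are divided by plot totals before analysis, which equalizes the CA
row weights (the CWM regression inside dc-CA becomes unweighted) and damps
plot-size effects. With row weights $r$, column weights $c$ and
$Q = D_r^{-1/2}(P - rc^\top)D_c^{-1/2}$, the species side is constrained to
the span of the trait matrix and the site side to the span of the
predictors; the first axis maximizes the weighted fourth-corner correlation
of the two composites and its eigenvalue is that squared correlation. We
use the direct two-projection formulation (project $Q$ on both spans, then a
small SVD) rather than iterative alternation: it is numerically transparent
and lets a brute-force grid search over unit-variance composite pairs serve
as an oracle on tiny instances. With an unconstrained species side the
site-side solution coincides with canonical correspondence analysis, which
the tests verify against `vegan::cca()`.

The max test takes the maximum of two permutation p values computed with
the same statistic (first eigenvalue by default; the trace is a flag): the
community-level test permutes plots — within region strata when region is a
covariate, since free permutation would break the within-region framing —
and the species-level test permutes rows of the trait table. The maximum
guards against the type-1 inflation of plain CWM regression; under a
complete null it is close to uniform because the two component p values are
strongly correlated. The term screen follows the same conditioning sequence
as the causal models (loss marginally; patches given loss; edge given both;
degradation given all three), per buffer scale, Bonferroni-adjusted across
all screened terms, and ranks terms by their marginal explained
fourth-corner variance. Whether community permutations should be free or
within-region is not settled; within-region is the default because region
is a covariate, and free permutation is available by passing
`strata = NULL` to `max_test()`.

# The synthetic generator

No generative magnitudes are available from the study system itself, so the
scenario defaults are the package's own choice of a realistic study: six
regions × 45 plots (≈ 270 plots), a pool of 1,000 species, ≈ 110 adult
stems per 0.25-ha plot, lognormal baseline abundances with σ = 1.5 (the top
decile of species then holds well over half the stems, matching
hyperdominant tropical assemblages), buffer scales 500/1000/2000 m, and
trait distributions typical of Neotropical floras (wood density truncated
normal on 0.1–1.2 g cm⁻³, seed mass and maximum height lognormal, LMA
truncated normal, and a dispersal syndrome drawn from a multinomial logit
on log seed mass so synzoochory concentrates among large seeds).

Structural equations are written **between standardized latent variables**:
each of patches, edge and degradation is a linear function of its parents
plus Gaussian noise, renormalized to unit variance, and the observables are
monotone maps of these latents — `expm1` for forest loss and patch counts
(which the analysis inverts with `log1p`), linear maps for edge density and
the degradation index, and basal area as the inverse of degradation with
small lognormal observation noise. Patch counts are rounded to positive
integers; this rounding is the one place where the analysis-side transform
is not an exact inverse, and it costs a percent-level attenuation that the
parameter-recovery tolerances absorb. The per-trait sorting gradient is a
linear combination of the (reference-scale) latent exposures with the
configured direct effects, topped up by an idiosyncratic plot-level term so
its variance is exactly one — hence a configured slope *is* the
standardized total effect the pipeline estimates, and `scenario_truth()`
returns those estimands in closed form (equivalently as path-coefficient
sums, which the tests check against each other at 1e-12). A trait with no
configured effect receives no sorting gradient at all: the top-up term only
completes an existing gradient, so a fully null scenario has independent
species, which is what a binomial check of winner/loser rates presumes.
Expected counts are the softmax of baseline plus gradient × standardized
trait, scaled to the target stem count, sampled as Poisson (negative
binomial by flag). Buffer scales share one latent forest-loss field with
scale-specific admixture (correlations 0.8/0.9/1.0 by default), mimicking
nested buffers. Optional spatial structure enters as an exponential-kernel
Gaussian process on the shared field.

Default sorting places direct forest-loss effects of −0.5 on wood density
and −0.4 on (log) seed mass, and degradation effects of −0.25/−0.2, i.e. a
loss-to-degradation importance ratio of about two — the qualitative regime
the multivariate analysis should recover. What the generator does **not**
emulate: taxonomic or phylogenetic trait correlation, demographic dynamics,
raster-based landscape geometry, non-monotone trait responses and
trait-dependent detection. Passing tests therefore show the estimators
recover the assumed generative structure, not that real forests obey it.

# Numerical choices and degenerate inputs

* One RNG stream per generator stage and per species, derived from the
  global seed by exact modular hashing; identical configurations are
  byte-identical, and sub-analyses do not perturb each other.
* Zero-variance variables are dropped from standardization with a warning;
  collinear model matrices raise errors naming the offending terms (with a
  condition number in dc-CA).
* A predictor entirely absorbed by its covariates yields a zero dc-CA
  statistic (and p value 1) rather than noise-normalized garbage.
* Duplicate plot coordinates are a hard error in spatial weighting (no
  silent jitter); fewer than four plots skips the spatial step.
* Trait coverage thresholds are inclusive ("at least"); the 50%/80% rules
  are evaluated per trait, the stricter joint reading being noted but not
  adopted. Genus-level rescue for the 80% rule requires a `genus` column;
  without one the rule falls back to species-level coverage, with a logged
  notice. Missing traits are never imputed — species are dropped pairwise
  per trait and coverage is reported instead.

# Problem sizes used in tests

The shipped test suite and acceptance script run the generator at desk
scale, chosen as the package's own trade-off between Monte-Carlo precision
and turnaround: 200-plot single-region datasets (100 seeds) for parameter
recovery, 800 plots for backdoor bias, 50-plot/500-species nulls with 1,000
null-model iterations for calibration, 200 null communities with 199
permutations for max-test uniformity, and three seeds of the full 6 × 45
full-study scenario with 1,000 iterations and 199 permutations.
`run_pipeline(..., full_scale = TRUE)` restores the full 10,000-iteration
/ 999-permutation settings.

# Known limitations

* The DAG is assumed, not learned; estimates are causal only conditional on
  it, and no sensitivity analysis for unobserved confounding is provided.
* OLS with spatial eigenvector filtering addresses autocorrelation in the
  mean structure only; errors are otherwise assumed i.i.d.
* The dc-CA implementation targets the analysis chain used here (covariate
  partialling, max test, term screen); it is not a general replacement for
  a full ordination toolbox (no detrending, no biplot scaling options).
* CWMs from small plots are noisy ratio estimates; no small-sample
  correction is applied beyond what standardization absorbs.
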