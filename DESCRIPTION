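Package: traitshift
Title: Trait-Based Causal Analysis of Tree Communities in Human-Modified
    Tropical Forests
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Estimates how landscape-scale forest loss, fragmentation, edge
    density and local degradation reshape the functional composition of
    tropical tree communities.  Provides community-weighted trait means and
    extreme (5%/95%) abundance-weighted percentiles, backdoor-adjusted
    standardized causal effect models with Moran's eigenvector map spatial
    filtering, a permutation null model that classifies winner and loser
    species from abundance-weighted forest-loss niche centroids, and a
    double-constrained correspondence analysis with the community/species
    max permutation test.  A synthetic-community generator with closed-form
    ground truth exercises the full pipeline without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
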