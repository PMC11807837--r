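# Synthetic generator: determinism, noise-free limits, distributional
# behaviour and the closed-form ground truth.

test_that("identical configs give byte-identical output", {
  a <- simulate_scenario(small_config(seed = 11))
  b <- simulate_scenario(small_config(seed = 11))
  expect_identical(a$plots, b$plots)
  expect_identical(a$landscape, b$landscape)
  expect_identical(a$traits, b$traits)
  expect_identical(a$abundance, b$abundance)
  c <- simulate_scenario(small_config(seed = 12))
  expect_false(identical(a$abundance, c$abundance))
})

test_that("stage streams are stable when run standalone", {
  cfg <- small_config(seed = 3)
  land <- simulate_landscape(cfg)
  sim <- simulate_scenario(cfg)
  expect_identical(land$landscape, sim$landscape)
  expect_identical(simulate_trait_pool(cfg), sim$traits)
})

test_that("noise-free limit makes patches a deterministic function of loss", {
  cfg <- scenario_config(n_regions = 1, plots_per_region = 300,
                         n_species_pool = 50, scales = 2000,
                         dag_coefficients = list(a1 = 1),
                         noise_sd = c(patches = 0, edge = 0, degradation = 0),
                         region_sd = 0, seed = 5)
  land <- simulate_landscape(cfg)$landscape
  # Same forest loss always maps to the same patch count, and the log-log
  # relationship is essentially perfect (integer rounding only).
  agg <- land |> dplyr::distinct(forest_loss, n_patches)
  expect_equal(nrow(agg), nrow(dplyr::distinct(agg, forest_loss)))
  # Monotone deterministic map (integer rounding of patch counts is the only
  # departure from exact log-log linearity).
  expect_true(all(diff(land$n_patches[order(land$forest_loss)]) >= 0))
  fit <- lm(log1p(n_patches) ~ log1p(forest_loss), data = land)
  expect_gt(summary(fit)$r.squared, 0.9)
  expect_gt(coef(fit)[2], 0)
})

test_that("removing the degradation arrows empties the loss-degradation link", {
  cfg <- scenario_config(n_regions = 1, plots_per_region = 500,
                         n_species_pool = 50, scales = 2000,
                         dag_coefficients = list(c1 = 0, c2 = 0, c3 = 0),
                         region_sd = 0, seed = 8)
  land <- simulate_landscape(cfg)
  fl <- land$landscape$forest_loss
  dg <- land$degradation$degradation
  # alpha = 0.01 bound on a null correlation at n = 500
  expect_lt(abs(cor(log1p(fl), dg)), qnorm(0.995) / sqrt(500))
})

test_that("trait pool has the study dimensions and link structure", {
  cfg <- scenario_config(n_regions = 1, plots_per_region = 2,
                         n_species_pool = 1207, seed = 2)
  tp <- simulate_trait_pool(cfg)
  expect_equal(nrow(tp), 1207)
  expect_true(all(c("wood_density", "seed_mass", "lma", "h_max") %in% names(tp)))
  expect_true(all(tp$dispersal_syndrome %in%
                    c("abiotic", "endozoochory", "synzoochory")))
  expect_true(all(tp$wood_density > 0.1 & tp$wood_density < 1.2))
  expect_true(all(tp$seed_mass > 0 & tp$lma > 0 & tp$h_max > 0))

  # Sorting configuration must not touch the pool marginals.
  cfg2 <- scenario_config(n_regions = 1, plots_per_region = 2,
                          n_species_pool = 1207,
                          trait_effect = c(wood_density = 0), seed = 2)
  expect_identical(tp, simulate_trait_pool(cfg2))
})

test_that("syndrome frequencies match the configured seed-mass link", {
  cfg <- scenario_config(n_regions = 1, plots_per_region = 2,
                         n_species_pool = 5000, seed = 4)
  tp <- simulate_trait_pool(cfg)
  s <- as.numeric(scale(log(tp$seed_mass)))
  expected <- colMeans(traitshift:::syndrome_probabilities(s))
  observed <- prop.table(table(factor(tp$dispersal_syndrome, names(expected))))
  for (k in names(expected)) {
    se <- sqrt(expected[k] * (1 - expected[k]) / 5000)
    expect_lt(abs(observed[[k]] - expected[[k]]), 4 * se)
  }
  # Synzoochory is enriched at large seeds.
  expect_gt(median(tp$seed_mass[tp$dispersal_syndrome == "synzoochory"]),
            median(tp$seed_mass[tp$dispersal_syndrome == "abiotic"]))
})

test_that("lognormal baseline produces hyperdominance", {
  cfg <- one_region_config(seed = 6, n_plots = 60, pool = 400,
                           abundance_lognormal_sd = 1.5)
  sim <- simulate_scenario(cfg)
  totals <- sort(tapply(sim$abundance$count, sim$abundance$species_id, sum),
                 decreasing = TRUE)
  top_decile <- sum(head(totals, ceiling(0.1 * cfg$n_species_pool)))
  expect_gt(top_decile / sum(totals), 0.5)
})

test_that("no sorting means no trait-forest-loss association", {
  cfg <- one_region_config(seed = 9, trait_effect = c(wood_density = 0))
  d <- suppressMessages(as_community_data(simulate_scenario(cfg)))
  tab <- standardized_table(d)
  est <- fit_causal_model(tab, "outcome", "forest_loss")
  expect_true(est$ci_low < 0 && est$ci_high > 0)
})

test_that("closed-form truth equals the path-sum, two independent derivations", {
  for (seed in 1:3) {
    cfg <- small_config(seed = seed,
                        dag_coefficients = list(a1 = 0.5 + 0.1 * seed, b1 = 0.4,
                                                b2 = 0.6, c1 = 0.3, c2 = 0.2,
                                                c3 = 0.4))
    tr <- scenario_truth(cfg)
    ref <- tr[tr$scale == max(tr$scale), ]
    expect_equal(ref$effect, ref$path_sum, tolerance = 1e-12)

    # Independent enumeration of the loss -> degradation total effect.
    B <- traitshift:::scenario_path_matrix(cfg)
    a1 <- B["n_patches", "forest_loss"]
    b1 <- B["edge_density", "forest_loss"]; b2 <- B["edge_density", "n_patches"]
    c1 <- B["degradation", "forest_loss"]; c2 <- B["degradation", "n_patches"]
    c3 <- B["degradation", "edge_density"]
    t_dl <- c1 + a1 * c2 + (b1 + a1 * b2) * c3
    Tz <- solve(diag(4) - B)
    expect_equal(unname(Tz["degradation", "forest_loss"]), t_dl, tolerance = 1e-12)
  }
})

test_that("generated arrows are detectable and absent arrows are not", {
  hits_present <- hits_absent <- logical(100)
  for (s in 1:100) {
    cfg <- scenario_config(n_regions = 1, plots_per_region = 300,
                           n_species_pool = 50, scales = 2000,
                           dag_coefficients = list(c2 = 0), region_sd = 0,
                           seed = s)
    land <- simulate_landscape(cfg)
    df <- land$landscape |>
      dplyr::mutate(l = log1p(forest_loss), p = log1p(n_patches),
                    e = edge_density, d = land$degradation$degradation)
    # Present arrow: loss -> patches.
    p_lp <- summary(lm(p ~ l, df))$coefficients["l", 4]
    # Absent arrow: patches -> degradation given loss and edge.
    p_pd <- summary(lm(d ~ p + l + e, df))$coefficients["p", 4]
    hits_present[s] <- p_lp < 0.01
    hits_absent[s] <- p_pd >= 0.01
  }
  expect_gte(mean(hits_present), 0.95)
  expect_gte(mean(hits_absent), 0.95)
})

test_that("spatial range induces autocorrelation in forest loss", {
  cfg <- scenario_config(n_regions = 1, plots_per_region = 60,
                         n_species_pool = 50, scales = 2000,
                         spatial_range = 2500, seed = 10)
  land <- simulate_landscape(cfg)
  W <- spatial_weights(land$plots[c("x", "y")], "gabriel", "binary")
  tst <- moran_test(log1p(land$landscape$forest_loss), W, n_perm = 199, seed = 1)
  expect_lt(tst$p_value, 0.05)

  cfg0 <- scenario_config(n_regions = 1, plots_per_region = 60,
                          n_species_pool = 50, scales = 2000,
                          spatial_range = 0, seed = 10)
  land0 <- simulate_landscape(cfg0)
  tst0 <- moran_test(log1p(land0$landscape$forest_loss), W, n_perm = 199, seed = 1)
  expect_gt(tst0$p_value, 0.01)
})

test_that("config validation rejects impossible scenarios", {
  expect_error(scenario_config(n_regions = 0), "counts")
  expect_error(scenario_config(noise_sd = c(patches = -1)), "noise_sd")
  expect_error(scenario_config(trait_effect = c(bark_thickness = 1)), "unknown")
  expect_error(scenario_config(trait_effect = c(wood_density = -0.9),
                               degradation_effect = c(wood_density = -0.9)),
               "variance")
})
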