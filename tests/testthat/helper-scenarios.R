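# Shared fixtures: small scenarios built in code, cached per test run.

small_config <- function(seed = 1, ...) {
  args <- modifyList(list(
    n_regions = 2, plots_per_region = 25, n_species_pool = 120,
    scales = c(500, 2000), stems_per_plot = 80, seed = seed), list(...))
  do.call(scenario_config, args)
}

one_region_config <- function(seed = 1, n_plots = 200, pool = 300, ...) {
  args <- modifyList(list(
    n_regions = 1, plots_per_region = n_plots, n_species_pool = pool,
    scales = 2000, trait_effect = c(wood_density = -0.5),
    degradation_effect = c(wood_density = 0), seed = seed), list(...))
  do.call(scenario_config, args)
}

.cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .cache)) assign(key, force(expr), envir = .cache)
  get(key, envir = .cache)
}

small_sim <- function() cached("small_sim", simulate_scenario(small_config()))

small_data <- function() cached("small_data", {
  suppressMessages(as_community_data(small_sim()))
})

# Standardized single-region model table for one trait/statistic/scale.
standardized_table <- function(data, trait = "wood_density", statistic = "cwm",
                               scale = max(data$landscape$scale), region = NULL) {
  profiles <- community_profiles(data$abundance, data$traits)
  tab <- traitshift:::model_table(profiles, data$landscape, data$plots,
                                  trait, statistic, scale)
  if (!is.null(region)) tab <- tab[tab$region_id == region, ]
  suppressWarnings(transform_and_standardize(
    tab, c("outcome", "forest_loss", "n_patches", "edge_density", "degradation"),
    group = character(0)))
}

# Tiny deterministic community for hand-checked IO/filter cases.
toy_tables <- function() {
  plots <- tibble::tibble(
    plot_id = c("p1", "p2"), region_id = "R1",
    x = c(0, 1000), y = c(0, 0), plot_area = 0.25, basal_area = c(7.5, 5))
  traits <- tibble::tibble(
    species_id = c("spA", "spB", "spC", "spD"),
    genus = c("gen1", "gen2", "gen2", "gen3"),
    wood_density = c(0.6, NA, 0.7, NA),
    seed_mass = c(100, 50, NA, NA),
    lma = c(80, 90, 100, NA),
    h_max = c(20, 25, 30, NA),
    dispersal_syndrome = c("abiotic", "endozoochory", "synzoochory", "abiotic"))
  abundance <- tibble::tibble(
    plot_id = c("p1", "p1", "p1", "p2", "p2"),
    species_id = c("spA", "spB", "spD", "spA", "spC"),
    count = c(60L, 15L, 25L, 10L, 10L))
  landscape <- tidyr::expand_grid(plot_id = c("p1", "p2"), scale = c(500, 2000)) |>
    dplyr::mutate(forest_loss = c(10, 12, 40, 45),
                  n_patches = c(3L, 5L, 8L, 12L),
                  edge_density = c(0.2, 0.25, 0.5, 0.55))
  list(plots = plots, traits = traits, abundance = abundance, landscape = landscape)
}

toy_data <- function() {
  tt <- toy_tables()
  suppressMessages(load_community_data(
    plots = tt$plots, abundance = tt$abundance,
    traits = tt$traits, landscape = tt$landscape))
}
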