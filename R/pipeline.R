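#' Run the full analysis pipeline from one configuration
#'
#' Orchestrates simulate (or load) -> validate/filter -> community profiles
#' -> causal effect grid -> niche null model -> dc-CA term screen, with one
#' seed governing every stage.  Desk-scale defaults (1,000 null iterations,
#' 199 permutations) keep a full run fast; `full_scale = TRUE` restores the
#' full 10,000 / 999 settings.
#'
#' @param config A list, or path to a YAML file, with optional blocks
#'   `simulate` (arguments to [scenario_config()]), `input_dir` (directory of
#'   CSVs for [load_community_data()]; used when no `simulate` block),
#'   `filters` (`min_species_level`, `min_total`, `min_plots`), `causal`
#'   (`traits`, `statistics`, `exposures`, `scales`, `spatial_filter`),
#'   `niche` (`scale`, `n_iter`, `threshold`), `dcca` (`n_perm`,
#'   `statistic`), plus top-level `alpha`, `seed`, `out_dir`.
#' @param full_scale Use full-fidelity iteration counts.
#' @return A `ts_report` list with the stage outputs and summaries; written
#'   to `out_dir` (CSV + JSON) when configured.
#' @export
run_pipeline <- function(config = list(), full_scale = FALSE) {
  if (is.character(config)) {
    if (!file.exists(config)) abort_bad("config file not found: %s", config)
    config <- yaml::read_yaml(config)
  }
  seed <- config$seed %||% 1L
  alpha <- config$alpha %||% 0.05
  n_iter <- config$niche$n_iter %||% if (full_scale) 10000 else 1000
  n_perm <- config$dcca$n_perm %||% if (full_scale) 999 else 199

  if (!is.null(config$simulate) || is.null(config$input_dir)) {
    sim_args <- config$simulate %||% list()
    sim_args$seed <- sim_args$seed %||% seed
    cfg <- do.call(scenario_config, sim_args)
    sim <- simulate_scenario(cfg)
    data <- as_community_data(sim)
    truth <- sim$truth
  } else {
    data <- load_community_data(config$input_dir)
    truth <- NULL
  }

  f <- config$filters %||% list()
  coverage <- filter_plots_by_trait_coverage(
    data, min_species_level = f$min_species_level %||% 0.5,
    min_total = f$min_total %||% 0.8)
  occupancy <- filter_species_min_occupancy(data, min_plots = f$min_plots %||% 5)

  profiles <- community_profiles(data$abundance, data$traits)

  ca <- config$causal %||% list()
  effects <- run_effect_grid(
    data,
    traits = ca$traits %||% profile_trait_names(),
    statistics = ca$statistics %||% c("cwm", "p05", "p95"),
    scales = ca$scales,
    exposures = ca$exposures %||% dag_exposures(),
    spatial_filter = isTRUE(ca$spatial_filter),
    profiles = profiles,
    alpha = alpha, seed = sub_seed(seed, "grid"))

  ni <- config$niche %||% list()
  niche <- niche_classification(
    data, scale = ni$scale, min_plots = f$min_plots %||% 5,
    n_iter = n_iter, threshold = ni$threshold %||% 0.95,
    seed = sub_seed(seed, "niche"))

  dc <- config$dcca %||% list()
  dcca_terms <- dcca_term_screen(
    data, scales = dc$scales, alpha = alpha, n_perm = n_perm,
    statistic = dc$statistic %||% "first", seed = sub_seed(seed, "dcca"))

  summaries <- list(
    dims = data$report[c("n_plots", "n_regions", "n_species", "n_stems")],
    plots_excluded_by_coverage = sum(!coverage$retained),
    species_region_retained = sum(occupancy$retained),
    significant_effects = effects |>
      filter(is.na(.data$error), .data$significant) |>
      count(.data$exposure, name = "n_significant"),
    winner_loser_fractions = niche |>
      group_by(.data$region_id) |>
      summarise(winner = mean(.data$status == "winner"),
                loser = mean(.data$status == "loser"), .groups = "drop"),
    dcca_significant_terms = dcca_terms |>
      filter(.data$significant) |> select("term", "scale", "p_adj")
  )
  report <- structure(list(
    config = config, seed = seed, truth = truth,
    data = data, coverage = coverage, occupancy = occupancy,
    profiles = profiles, effects = effects, niche = niche,
    dcca_terms = dcca_terms, summaries = summaries
  ), class = "ts_report")

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    readr::write_csv(profiles, file.path(config$out_dir, "profiles.csv"))
    readr::write_csv(effects, file.path(config$out_dir, "effects.csv"))
    readr::write_csv(niche, file.path(config$out_dir, "niche.csv"))
    readr::write_csv(dcca_terms, file.path(config$out_dir, "dcca_terms.csv"))
    jsonlite::write_json(
      list(seed = seed, dims = summaries$dims,
           plots_excluded_by_coverage = summaries$plots_excluded_by_coverage,
           species_region_retained = summaries$species_region_retained,
           significant_effects = summaries$significant_effects,
           winner_loser_fractions = summaries$winner_loser_fractions,
           dcca_significant_terms = summaries$dcca_significant_terms),
      file.path(config$out_dir, "report.json"), digits = NA, auto_unbox = TRUE)
  }
  report
}

#' @export
print.ts_report <- function(x, ...) {
  cat("<ts_report>\n")
  cat(sprintf("  %d plots / %d regions / %d species\n",
              x$summaries$dims$n_plots, x$summaries$dims$n_regions,
              x$summaries$dims$n_species))
  wf <- x$summaries$winner_loser_fractions
  cat(sprintf("  winners %.1f%% / losers %.1f%% (mean over regions)\n",
              100 * mean(wf$winner), 100 * mean(wf$loser)))
  cat(sprintf("  %d significant dc-CA term(s)\n",
              nrow(x$summaries$dcca_significant_terms)))
  invisible(x)
}
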