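#' Write pipeline input tables to a directory
#'
#' Serializes a simulation (or an equivalent list of tables) to the canonical
#' CSV schemas consumed by [load_community_data()]: `plots.csv`,
#' `abundance.csv` (long), `traits.csv`, `landscape.csv`, and `truth.json`
#' when ground truth is present.
#'
#' @param sim A `ts_simulation` or a list with `plots`, `abundance`,
#'   `traits`, `landscape` tibbles (and optionally `truth`).
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_community_data <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(sim$plots, file.path(dir, "plots.csv"))
  readr::write_csv(sim$abundance, file.path(dir, "abundance.csv"))
  readr::write_csv(sim$traits, file.path(dir, "traits.csv"))
  readr::write_csv(sim$landscape, file.path(dir, "landscape.csv"))
  if (!is.null(sim$truth)) {
    jsonlite::write_json(
      list(total_effects = sim$truth$total_effects,
           species_optimum = sim$truth$species_optimum,
           path_matrix = as.data.frame(sim$truth$path_matrix)),
      file.path(dir, "truth.json"), digits = NA)
  }
  invisible(dir)
}

read_checked_csv <- function(path, what) {
  if (!file.exists(path)) abort_bad("%s file not found: %s", what, path)
  df <- readr::read_csv(path, show_col_types = FALSE,
                        na = c("", "NA"), progress = FALSE)
  probs <- readr::problems(df)
  if (nrow(probs)) {
    abort_bad("%s: %d parsing problem(s); first at row %d (%s)",
              what, nrow(probs), probs$row[1], probs$expected[1])
  }
  df
}

# Accept the wide abundance dialect (plot_id + one column per species).
normalize_abundance <- function(abundance) {
  if (all(c("plot_id", "species_id", "count") %in% names(abundance))) {
    out <- abundance
  } else if ("plot_id" %in% names(abundance)) {
    out <- abundance |>
      pivot_longer(-"plot_id", names_to = "species_id", values_to = "count") |>
      filter(.data$count != 0)
  } else {
    abort_bad("abundance table must be long (plot_id, species_id, count) or wide (plot_id + species columns)")
  }
  if (!is.numeric(out$count) || anyNA(out$count)) {
    bad <- which(!is.finite(suppressWarnings(as.numeric(out$count))) | is.na(out$count))
    abort_bad("abundance counts must be numeric; first offending row: %d", bad[1])
  }
  if (any(out$count < 0)) abort_bad("negative stem counts at row %d", which(out$count < 0)[1])
  if (any(out$count != round(out$count))) {
    abort_bad("non-integer stem counts at row %d", which(out$count != round(out$count))[1])
  }
  dup <- duplicated(out[c("plot_id", "species_id")])
  if (any(dup)) abort_bad("duplicate plot/species keys, e.g. %s / %s",
                          out$plot_id[dup][1], out$species_id[dup][1])
  out |>
    mutate(count = as.integer(.data$count)) |>
    arrange(.data$plot_id, .data$species_id)
}

#' Load and validate the four pipeline input tables
#'
#' Reads plot metadata, abundance (long or wide), traits and landscape
#' tables, checks referential integrity and value ranges, and returns typed
#' tibbles plus a validation report.  Species present in the abundance table
#' but absent from the trait table are retained with a full missing-trait
#' mask (they count against trait coverage); unknown plot keys are hard
#' errors.
#'
#' @param dir Directory holding `plots.csv`, `abundance.csv`, `traits.csv`,
#'   `landscape.csv`; alternatively pass the tables via `...` overrides.
#' @param plots,abundance,traits,landscape Optional in-memory tibbles that
#'   take precedence over the files.
#' @return A `ts_data` list: the four tibbles plus `report` (dimensions,
#'   missingness, species without trait rows).
#' @export
load_community_data <- function(dir = NULL, plots = NULL, abundance = NULL,
                                traits = NULL, landscape = NULL) {
  get_tab <- function(obj, file, what) {
    if (!is.null(obj)) return(obj)
    if (is.null(dir)) abort_bad("%s table missing and no directory given", what)
    read_checked_csv(file.path(dir, file), what)
  }
  plots <- get_tab(plots, "plots.csv", "plot metadata")
  abundance <- normalize_abundance(get_tab(abundance, "abundance.csv", "abundance"))
  traits <- get_tab(traits, "traits.csv", "trait table")
  landscape <- get_tab(landscape, "landscape.csv", "landscape table")

  assert_cols(plots, c("plot_id", "region_id", "x", "y", "plot_area", "basal_area"),
              "plot metadata")
  assert_cols(traits, c("species_id", continuous_traits(), "dispersal_syndrome"),
              "trait table")
  assert_cols(landscape, c("plot_id", "scale", "forest_loss", "n_patches",
                           "edge_density"), "landscape table")
  if (anyDuplicated(plots$plot_id)) abort_bad("duplicate plot_id in plot metadata")
  if (anyDuplicated(traits$species_id)) abort_bad("duplicate species_id in trait table")
  if (anyDuplicated(landscape[c("plot_id", "scale")])) {
    abort_bad("duplicate plot/scale keys in landscape table")
  }
  if (any(!is.finite(plots$x) | !is.finite(plots$y))) abort_bad("non-finite plot coordinates")
  if (any(plots$basal_area <= 0)) abort_bad("basal_area must be positive")
  if (any(plots$plot_area <= 0)) abort_bad("plot_area must be positive")
  if (any(landscape$forest_loss < 0 | landscape$forest_loss > 100)) {
    abort_bad("forest_loss must lie in [0, 100] percent")
  }
  if (any(landscape$n_patches < 1)) abort_bad("n_patches must be >= 1")
  if (any(landscape$edge_density < 0 | landscape$edge_density > 1)) {
    abort_bad("edge_density must lie in [0, 1]")
  }
  bad_plots <- setdiff(unique(abundance$plot_id), plots$plot_id)
  if (length(bad_plots)) {
    abort_bad("abundance references unknown plot(s): %s",
              paste(head(bad_plots, 3), collapse = ", "))
  }
  bad_plots <- setdiff(unique(landscape$plot_id), plots$plot_id)
  if (length(bad_plots)) {
    abort_bad("landscape references unknown plot(s): %s",
              paste(head(bad_plots, 3), collapse = ", "))
  }
  tr_cont <- traits[continuous_traits()]
  if (any(vapply(tr_cont, function(x) any(x <= 0, na.rm = TRUE), logical(1)))) {
    abort_bad("continuous traits must be positive where present")
  }
  orphan_species <- setdiff(unique(abundance$species_id), traits$species_id)

  # Degradation proxy derived from basal area relative to the sample area.
  plots$degradation <- degradation_index(plots$basal_area, plots$plot_area)

  report <- list(
    n_plots = nrow(plots),
    n_regions = length(unique(plots$region_id)),
    n_species = length(unique(abundance$species_id)),
    n_stems = sum(abundance$count),
    scales = sort(unique(landscape$scale)),
    species_without_traits = orphan_species,
    trait_missingness = vapply(tr_cont, function(x) mean(is.na(x)), numeric(1))
  )
  inform(sprintf("loaded %d plots / %d regions / %d species / %d stems",
                 report$n_plots, report$n_regions, report$n_species, report$n_stems))
  structure(list(plots = plots, abundance = abundance, traits = traits,
                 landscape = landscape, report = report),
            class = "ts_data")
}

#' Convert a simulation into validated pipeline data
#'
#' @param sim A `ts_simulation`.
#' @return A `ts_data` list, as from [load_community_data()].
#' @export
as_community_data <- function(sim) {
  suppressMessages(load_community_data(
    plots = sim$plots, abundance = sim$abundance,
    traits = sim$traits, landscape = sim$landscape))
}

#' Plot inclusion by trait coverage
#'
#' Applies the two inclusion rules used for community-level analyses: a plot
#' enters a trait's analyses only if at least `min_species_level` of its
#' stems belong to species with species-level data for that trait, and at
#' least `min_total` of its stems are covered when genus-level information is
#' allowed to fill in (a species without the trait counts as covered at the
#' total level when any congeneric in the trait table has it).  Both rules
#' are inclusive at the threshold.  Without a `genus` column the total rule
#' falls back on species-level coverage only (logged).
#'
#' @param data A `ts_data` list (or any list with `abundance`, `traits`).
#' @param min_species_level,min_total Coverage thresholds in `[0, 1]`.
#' @return Tibble `plot_id`, `trait`, `coverage_species`, `coverage_total`,
#'   `retained`.
#' @export
filter_plots_by_trait_coverage <- function(data, min_species_level = 0.5,
                                           min_total = 0.8) {
  if (min_species_level < 0 || min_species_level > 1 ||
      min_total < 0 || min_total > 1) {
    abort_bad("coverage thresholds must lie in [0, 1]")
  }
  traits <- data$traits
  has_genus <- "genus" %in% names(traits)
  if (!has_genus) {
    inform("trait table has no genus column; total coverage uses species-level data only")
  }
  long <- data$abundance |>
    left_join(traits, by = "species_id") |>
    pivot_longer(all_of(continuous_traits()), names_to = "trait", values_to = "value")
  if (has_genus) {
    genus_known <- long |>
      filter(!is.na(.data$value)) |>
      distinct(.data$genus, .data$trait) |>
      mutate(genus_has_trait = TRUE)
    long <- long |> left_join(genus_known, by = c("genus", "trait")) |>
      mutate(genus_has_trait = !is.na(.data$genus) & !is.na(.data$genus_has_trait))
  } else {
    long$genus_has_trait <- FALSE
  }
  long |>
    group_by(.data$plot_id, .data$trait) |>
    summarise(
      coverage_species = sum(.data$count[!is.na(.data$value)]) / sum(.data$count),
      coverage_total = sum(.data$count[!is.na(.data$value) | .data$genus_has_trait]) /
        sum(.data$count),
      .groups = "drop"
    ) |>
    mutate(retained = .data$coverage_species >= min_species_level &
             .data$coverage_total >= min_total)
}

#' Species inclusion by within-region occupancy
#'
#' Species-level analyses require a reliable niche estimate, so a species is
#' analysed within a region only when it occurs in at least `min_plots` plots
#' of that region; the same species may qualify in one region and not in
#' another.
#'
#' @param data A `ts_data` list (or any list with `abundance`, `plots`).
#' @param min_plots Minimum number of occupied plots within the region.
#' @return Tibble `species_id`, `region_id`, `n_plots_occupied`,
#'   `total_abundance`, `retained`.
#' @export
filter_species_min_occupancy <- function(data, min_plots = 5) {
  if (min_plots < 1) abort_bad("min_plots must be >= 1")
  data$abundance |>
    inner_join(data$plots[c("plot_id", "region_id")], by = "plot_id") |>
    filter(.data$count > 0) |>
    group_by(.data$species_id, .data$region_id) |>
    summarise(n_plots_occupied = n_distinct(.data$plot_id),
              total_abundance = sum(.data$count), .groups = "drop") |>
    mutate(retained = .data$n_plots_occupied >= min_plots)
}
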