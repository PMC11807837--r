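#' Community-weighted mean of a trait
#'
#' Abundance-weighted mean over the species that carry a value for the trait;
#' species with missing trait values are dropped and the remaining weights
#' renormalized.  With a one-hot dispersal-syndrome column this yields the
#' abundance-weighted proportion of the syndrome.
#'
#' @param abundances Non-negative per-species weights (e.g. stem counts).
#' @param trait Per-species trait values, possibly with `NA`.
#' @return The weighted mean, or `NA_real_` when no weighted species has a
#'   trait value (never silently zero).
#' @export
#' @examples
#' cwm(c(2, 1), c(0.4, 0.7)) # 0.5
cwm <- function(abundances, trait) {
  stopifnot(length(abundances) == length(trait))
  if (any(abundances < 0, na.rm = TRUE)) abort_bad("abundances must be non-negative")
  ok <- !is.na(trait) & !is.na(abundances) & abundances > 0
  if (!any(ok)) return(NA_real_)
  sum(abundances[ok] * trait[ok]) / sum(abundances[ok])
}

#' Abundance-weighted trait percentile
#'
#' Percentile of the abundance-weighted trait distribution, using the
#' step-function inverse of the cumulative weight with averaging at exact
#' jumps.  With integer weights this equals `quantile(rep(trait, w), p,
#' type = 2)` on the stem-expanded vector, exactly.
#'
#' @inheritParams cwm
#' @param p Probability in (0, 1); the community-profile defaults are 0.05
#'   and 0.95 (lower and upper 5% percentiles).
#' @return Trait value at the requested weighted percentile (`NA_real_` when
#'   no species carries the trait).
#' @export
weighted_percentile <- function(abundances, trait, p) {
  stopifnot(length(abundances) == length(trait), length(p) == 1L)
  if (is.na(p) || p <= 0 || p >= 1) abort_bad("p must lie strictly inside (0, 1)")
  if (any(abundances < 0, na.rm = TRUE)) abort_bad("abundances must be non-negative")
  ok <- !is.na(trait) & !is.na(abundances) & abundances > 0
  if (!any(ok)) return(NA_real_)
  o <- order(trait[ok])
  xs <- trait[ok][o]
  cw <- cumsum(abundances[ok][o])
  W <- cw[length(cw)]
  # Mirrors the empirical-quantile convention with averaging at jumps
  # (type-2): position g = p * W, average the two adjacent stem values when
  # g falls exactly on a cumulative-weight boundary.
  g <- p * W
  j <- floor(g)
  h <- ((g > j) + 1) / 2
  at <- function(k) xs[which(cw >= k)[1]]
  lo <- at(max(j, min(1, W)))
  hi <- at(min(j + 1, W))
  (1 - h) * lo + h * hi
}

#' Local degradation index from basal area
#'
#' The inverse of community basal area relative to the sampled area: plots
#' with little standing basal area per hectare score as highly degraded.
#'
#' @param basal_area Total plot basal area (m^2).
#' @param plot_area Sampled area (ha).
#' @return `1 / (basal_area / plot_area)` (ha m^-2).
#' @export
degradation_index <- function(basal_area, plot_area) {
  if (any(basal_area <= 0, na.rm = TRUE) || any(plot_area <= 0, na.rm = TRUE)) {
    abort_bad("basal_area and plot_area must be positive")
  }
  1 / (basal_area / plot_area)
}

profile_trait_names <- function() c(continuous_traits(), syndrome_levels())

# Per-species trait columns used by community profiles: continuous traits
# (seed mass optionally logged) plus one-hot dispersal syndromes.
trait_value_table <- function(traits, seed_mass_log = TRUE) {
  assert_cols(traits, c("species_id", continuous_traits(), "dispersal_syndrome"),
              "trait table")
  out <- traits |>
    transmute(species_id = .data$species_id,
              wood_density = .data$wood_density,
              seed_mass = if (seed_mass_log) log(.data$seed_mass) else .data$seed_mass,
              lma = .data$lma,
              h_max = .data$h_max)
  for (lev in syndrome_levels()) {
    out[[lev]] <- ifelse(is.na(traits$dispersal_syndrome), NA_real_,
                         as.numeric(traits$dispersal_syndrome == lev))
  }
  out
}

#' Community functional profiles
#'
#' Per plot and trait: the community-weighted mean, the lower and upper
#' abundance-weighted percentiles (5% and 95% by default) and the
#' effective trait coverage (share of stems whose species carries the
#' trait).  Dispersal syndromes enter as one-hot columns, whose CWMs are
#' abundance-weighted proportions.  Seed mass is profiled on the log scale
#' (`seed_mass_log = FALSE` for raw mg).
#'
#' @param abundance Long tibble `plot_id`, `species_id`, `count`.
#' @param traits Species trait table (see [simulate_trait_pool()] schema).
#' @param percentiles Lower and upper percentile probabilities.
#' @param weighted Use stem counts as weights; `FALSE` gives the unweighted
#'   species-level variant (every present species counts once).
#' @param seed_mass_log Profile seed mass on the log scale.
#' @return Tibble `plot_id`, `trait`, `cwm`, `p_lower`, `p_upper`,
#'   `coverage`.
#' @export
community_profiles <- function(abundance, traits, percentiles = c(0.05, 0.95),
                               weighted = TRUE, seed_mass_log = TRUE) {
  assert_cols(abundance, c("plot_id", "species_id", "count"), "abundance table")
  stopifnot(length(percentiles) == 2L, percentiles[1] < percentiles[2])
  tv <- trait_value_table(traits, seed_mass_log)
  unknown <- setdiff(unique(abundance$species_id), tv$species_id)
  if (length(unknown)) {
    # Retained with a full missing mask: they count against coverage only.
    pad <- tibble(species_id = unknown)
    for (nm in setdiff(names(tv), "species_id")) pad[[nm]] <- NA_real_
    tv <- bind_rows(tv, pad)
  }
  long <- abundance |>
    mutate(w = if (weighted) as.numeric(.data$count) else 1) |>
    inner_join(tv, by = "species_id") |>
    pivot_longer(all_of(profile_trait_names()), names_to = "trait",
                 values_to = "value")
  long |>
    group_by(.data$plot_id, .data$trait) |>
    summarise(
      cwm = cwm(.data$w, .data$value),
      p_lower = weighted_percentile(.data$w, .data$value, percentiles[1]),
      p_upper = weighted_percentile(.data$w, .data$value, percentiles[2]),
      coverage = sum(.data$w[!is.na(.data$value)]) / sum(.data$w),
      .groups = "drop"
    ) |>
    mutate(trait = factor(.data$trait, levels = profile_trait_names())) |>
    arrange(.data$plot_id, .data$trait) |>
    mutate(trait = as.character(.data$trait))
}
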