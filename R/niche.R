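# Species-level analysis: forest-loss niche centroids, permutation null
# model, winner/loser classification and trait contrasts.

#' Species niche centroid along forest loss
#'
#' Abundance-weighted mean forest loss over the plots where the species
#' occurs.
#'
#' @param abundances Per-plot abundances of the species.
#' @param forest_loss Per-plot forest loss (%).
#' @return Centroid in % forest loss.
#' @export
species_niche_centroid <- function(abundances, forest_loss) {
  stopifnot(length(abundances) == length(forest_loss))
  if (sum(abundances) <= 0) abort_bad("species has zero total abundance")
  sum(abundances * forest_loss) / sum(abundances)
}

#' Null distribution of a species niche centroid
#'
#' Randomly redistributes the species' abundance vector across the region's
#' plots (a uniform permutation) and recomputes the niche centroid,
#' `n_iter` times.
#'
#' @inheritParams species_niche_centroid
#' @param n_iter Number of null iterations.
#' @param seed Integer seed (one stream per species is derived from the
#'   global seed upstream).
#' @return Numeric vector of `n_iter` null centroids.
#' @export
null_snc_distribution <- function(abundances, forest_loss, n_iter = 10000,
                                  seed = 1L) {
  n <- length(forest_loss)
  if (n < 2) abort_bad("the region must contain at least 2 plots")
  w <- abundances / sum(abundances)
  with_seed(seed, {
    vapply(seq_len(n_iter), function(i) sum(w * forest_loss[sample.int(n)]),
           numeric(1))
  })
}

#' Classify a species from its observed and null niche centroids
#'
#' The standardized effect size is `(obs - mean(null)) / sd(null)`; the
#' species is a *winner* when its observed centroid exceeds 95% of the null
#' values, a *loser* when it falls below 95% of them, and *neutral*
#' otherwise.  Ties count as non-exceedance (conservative); a degenerate
#' null (`sd = 0`) classifies as neutral with an undefined SES.
#'
#' @param snc_obs Observed niche centroid.
#' @param null_sample Vector of null centroids.
#' @param threshold One-sided exceedance probability (default 0.95).
#' @return One-row tibble: `snc_obs`, `null_mean`, `null_sd`, `ses`,
#'   `quantile_position`, `status`.
#' @export
classify_species <- function(snc_obs, null_sample, threshold = 0.95) {
  if (!length(null_sample)) abort_bad("empty null sample")
  mu <- mean(null_sample)
  s <- sd(null_sample)
  q <- mean(null_sample < snc_obs)
  q_above <- mean(null_sample > snc_obs)
  status <- if (s == 0) "neutral"
            else if (q > threshold) "winner"
            else if (q_above > threshold) "loser"
            else "neutral"
  tibble(snc_obs = snc_obs, null_mean = mu, null_sd = s,
         ses = if (s > 0) (snc_obs - mu) / s else NA_real_,
         quantile_position = q, status = status)
}

#' Run the niche null model over all qualifying species
#'
#' For every species x region combination with at least `min_plots` occupied
#' plots, computes the observed forest-loss niche centroid at the requested
#' scale, its permutation null within the region, the standardized effect
#' size and the winner/loser/neutral status.  Each species draws from its
#' own RNG stream derived from `seed`, so adding species leaves earlier
#' results unchanged.
#'
#' @param data A `ts_data` list.
#' @param scale Buffer scale (m); defaults to the largest available.
#' @param min_plots Within-region occupancy threshold.
#' @param n_iter Null iterations per species.
#' @param threshold Classification exceedance probability.
#' @param seed Global seed.
#' @return Tibble with one row per species x region (`NicheResult` schema).
#' @export
niche_classification <- function(data, scale = NULL, min_plots = 5,
                                 n_iter = 10000, threshold = 0.95, seed = 1L) {
  scale <- scale %||% max(data$landscape$scale)
  fl <- data$landscape |>
    filter(.data$scale == !!scale) |>
    select("plot_id", "forest_loss") |>
    inner_join(data$plots[c("plot_id", "region_id")], by = "plot_id")
  occ <- filter_species_min_occupancy(data, min_plots = min_plots) |>
    filter(.data$retained)
  ab <- data$abundance |>
    inner_join(fl, by = "plot_id") |>
    inner_join(occ[c("species_id", "region_id", "n_plots_occupied",
                     "total_abundance")],
               by = c("species_id", "region_id"))
  region_fl <- fl |> group_by(.data$region_id) |>
    summarise(plot_id = list(.data$plot_id), fl = list(.data$forest_loss),
              .groups = "drop")
  by_sp <- ab |> group_by(.data$species_id, .data$region_id) |>
    summarise(n_plots_occupied = .data$n_plots_occupied[1],
              total_abundance = .data$total_abundance[1],
              plot_id = list(.data$plot_id), w = list(.data$count),
              .groups = "drop") |>
    inner_join(region_fl, by = "region_id", suffix = c("", "_region"))
  rows <- pmap(by_sp, function(species_id, region_id, n_plots_occupied,
                               total_abundance, plot_id, w, plot_id_region, fl) {
    wfull <- set_names(numeric(length(plot_id_region)), plot_id_region)
    wfull[plot_id] <- w
    obs <- species_niche_centroid(wfull, fl)
    null <- null_snc_distribution(wfull, fl, n_iter = n_iter,
                                  seed = sub_seed(seed, paste0("sp_", species_id,
                                                               "_", region_id)))
    bind_cols(tibble(species_id = species_id, region_id = region_id,
                     scale = scale, n_plots_occupied = n_plots_occupied,
                     total_abundance = total_abundance),
              classify_species(obs, null, threshold = threshold))
  })
  bind_rows(rows)
}

#' Trait effects on species niche positions
#'
#' Linear model of the standardized-effect-size niche centroid (or the raw
#' centroid) on a standardized species trait, optionally weighted by species
#' total abundance across plots.  Both the weighted and unweighted fits are
#' returned for comparison; a better weighted fit indicates that
#' community-level change is carried by a few dominant species.
#'
#' @param niche Output of [niche_classification()].
#' @param traits Species trait table.
#' @param trait Trait column to test (`seed_mass` is log-transformed).
#' @param weight_by_abundance Use total abundance as weights in the headline
#'   fit.
#' @param response `"ses"` (default) or `"snc"`.
#' @return Tibble with one row per fit (weighted and unweighted): slope,
#'   confidence interval, adjusted R-squared, n.
#' @export
trait_snc_regression <- function(niche, traits, trait = "wood_density",
                                 weight_by_abundance = TRUE,
                                 response = c("ses", "snc")) {
  response <- match.arg(response)
  tv <- trait_value_table(traits)
  dat <- niche |>
    inner_join(tv[c("species_id", trait)], by = "species_id") |>
    mutate(y = if (response == "ses") .data$ses else .data$snc_obs) |>
    filter(!is.na(.data$y), !is.na(.data[[trait]]))
  if (nrow(dat) < 3) abort_bad("need at least 3 species with trait data")
  if (sd(dat[[trait]]) == 0) abort_bad("trait '%s' has no variance among species", trait)
  dat$tz <- as.numeric(scale(dat[[trait]]))
  one_fit <- function(weighted) {
    fit <- if (weighted) lm(y ~ tz, data = dat, weights = dat$total_abundance)
           else lm(y ~ tz, data = dat)
    ci <- confint(fit, "tz")
    tibble(trait = trait, response = response, weighted = weighted,
           slope = unname(coef(fit)["tz"]), ci_low = ci[1], ci_high = ci[2],
           significant = ci[1] > 0 | ci[2] < 0,
           r2_adj = summary(fit)$adj.r.squared, n_species = nrow(dat))
  }
  out <- bind_rows(one_fit(TRUE), one_fit(FALSE))
  if (!weight_by_abundance) out <- out |> arrange(.data$weighted)
  out
}

#' Winner-loser trait contrast
#'
#' One-way (optionally abundance-weighted) analysis of variance of a species
#' trait across the winner / neutral / loser groups, with per-group
#' summaries.  Empty groups are dropped with a notice (some regions have no
#' winners).
#'
#' @inheritParams trait_snc_regression
#' @return List with `groups` (per-status weighted mean, median, n) and
#'   `anova` (F statistic, degrees of freedom, p value, weighted flag).
#' @export
winner_loser_contrast <- function(niche, traits, trait = "wood_density",
                                  weight_by_abundance = TRUE) {
  tv <- trait_value_table(traits)
  dat <- niche |>
    inner_join(tv[c("species_id", trait)], by = "species_id") |>
    filter(!is.na(.data[[trait]])) |>
    mutate(status = factor(.data$status, levels = c("loser", "neutral", "winner")))
  present <- levels(droplevels(dat$status))
  if (length(present) < 2) abort_bad("need at least two non-empty status groups")
  if (length(present) < 3) {
    inform(sprintf("status group(s) empty; contrasting %s only",
                   paste(present, collapse = " vs ")))
  }
  dat$status <- droplevels(dat$status)
  w <- if (weight_by_abundance) dat$total_abundance else rep(1, nrow(dat))
  fit <- lm(dat[[trait]] ~ dat$status, weights = w)
  a <- anova(fit)
  groups <- dat |>
    mutate(.w = w) |>
    group_by(.data$status) |>
    summarise(n = n(),
              mean = weighted.mean(.data[[trait]], .data$.w),
              median = median(.data[[trait]]), .groups = "drop") |>
    mutate(trait = trait, .before = 1)
  list(groups = groups,
       anova = tibble(trait = trait, weighted = weight_by_abundance,
                      f = a$`F value`[1], df1 = a$Df[1], df2 = a$Df[2],
                      p_value = a$`Pr(>F)`[1]))
}
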