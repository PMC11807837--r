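# ggplot2 displays for the main result types.

#' Forest plot of standardized causal effects
#'
#' Mirrors the standard presentation of backdoor-adjusted trait responses:
#' one point per region x scale with its 95% confidence interval, filled
#' when the interval excludes zero, facetted by trait and exposure.
#'
#' @param grid Output of [run_effect_grid()].
#' @return A ggplot object.
#' @export
plot_effect_grid <- function(grid) {
  dat <- grid |> filter(is.na(.data$error))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$beta, y = .data$region,
                                    colour = .data$region)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$ci_low, xmax = .data$ci_high),
                            height = 0) +
    ggplot2::geom_point(ggplot2::aes(size = factor(.data$scale),
                                     alpha = .data$significant)) +
    ggplot2::scale_alpha_manual(values = c(`TRUE` = 1, `FALSE` = 0.35)) +
    ggplot2::facet_grid(statistic ~ trait + exposure) +
    ggplot2::labs(x = "standardized causal effect", y = NULL,
                  size = "buffer scale (m)", alpha = "CI excludes 0") +
    ggplot2::theme_minimal()
}

#' Niche-centroid deviation versus a species trait
#'
#' Scatter of the standardized effect size of the forest-loss niche centroid
#' against a trait, point size proportional to species total abundance,
#' coloured by winner/loser status.
#'
#' @param niche Output of [niche_classification()].
#' @param traits Species trait table.
#' @param trait Trait column to display.
#' @return A ggplot object.
#' @export
plot_niche <- function(niche, traits, trait = "wood_density") {
  dat <- niche |>
    inner_join(trait_value_table(traits)[c("species_id", trait)], by = "species_id") |>
    filter(!is.na(.data$ses), !is.na(.data[[trait]]))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data[[trait]], y = .data$ses)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_point(ggplot2::aes(size = .data$total_abundance,
                                     colour = .data$status), alpha = 0.7) +
    ggplot2::scale_colour_manual(values = c(winner = "#2c7fb8", loser = "#d95f0e",
                                            neutral = "grey70")) +
    ggplot2::facet_wrap(~region_id) +
    ggplot2::labs(y = "SES of forest-loss niche centroid", size = "abundance") +
    ggplot2::theme_minimal()
}

#' @describeIn fit_dcca Biplot-style display of the first dc-CA axis pair.
#' @param object A `ts_dcca`.
#' @export
autoplot.ts_dcca <- function(object, ...) {
  ld <- bind_rows(
    tibble(term = rownames(object$env_cor), r = object$env_cor[, 1],
           side = "predictor"),
    tibble(term = rownames(object$trait_cor), r = object$trait_cor[, 1],
           side = "trait"))
  ggplot2::ggplot(ld, ggplot2::aes(x = .data$r, y = stats::reorder(.data$term, .data$r))) +
    ggplot2::geom_col(ggplot2::aes(fill = .data$side)) +
    ggplot2::facet_wrap(~side, scales = "free_y") +
    ggplot2::labs(x = "correlation with axis-1 composite", y = NULL,
                  title = sprintf("dc-CA axis 1 (eigenvalue %.3f)",
                                  object$eigenvalues[1])) +
    ggplot2::theme_minimal()
}
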