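#' Configure a synthetic study scenario
#'
#' Defines the generative conditions for a multi-region study of tree
#' communities along a landscape-disturbance gradient.  The generator follows
#' the causal structure assumed for human-modified tropical forest landscapes:
#' forest loss increases the number of forest patches (fragmentation), both
#' increase edge density, and all three drive local degradation (proxied by
#' the inverse of community basal area).  Trait-mediated species sorting along
#' the forest-loss and degradation gradients produces recoverable community
#' responses.
#'
#' Structural equations are written between standardized (unit-variance)
#' latent variables so that every configured slope is directly a
#' *standardized* effect, the quantity the analysis pipeline estimates.  The
#' latents are mapped to observables through the same monotone transforms the
#' pipeline inverts (`expm1`/`log1p` for forest loss and patch counts, linear
#' maps for edge density and degradation), which keeps the closed-form total
#' effects in [scenario_truth()] exact estimands.
#'
#' @param n_regions Number of study regions.
#' @param plots_per_region Plots sampled per region.
#' @param n_species_pool Size of the regional species pool.
#' @param scales Buffer radii (m) at which landscape variables are measured.
#' @param dag_coefficients Named list/vector of raw path coefficients on the
#'   latent scale: `a1` (loss to patches), `b1` (loss to edge), `b2`
#'   (patches to edge), `c1`, `c2`, `c3` (loss/patches/edge to degradation).
#' @param trait_effect Named vector: per continuous trait, the total
#'   standardized direct effect of forest loss (at the reference, i.e.
#'   largest, scale) on that trait's community sorting gradient.  Seed mass
#'   sorts on the log scale.
#' @param degradation_effect Named vector, same convention, for the direct
#'   effect of local degradation on the sorting gradient.
#' @param noise_sd Named vector of structural noise standard deviations for
#'   `patches`, `edge` and `degradation` (raw latent scale, standardized away
#'   internally).
#' @param spatial_range Range (m) of an exponential-kernel Gaussian process
#'   added to the shared forest-loss field; `0` disables spatial structure.
#' @param abundance_lognormal_sd Standard deviation of the lognormal species
#'   baseline abundances (hyperdominance strength).
#' @param stems_per_plot Expected number of adult stems per plot.
#' @param scale_cor Named vector: correlation of each scale's forest-loss
#'   field with the reference (largest) scale field; mimics nested buffers.
#' @param region_sd Standard deviation of region-level shifts of the latent
#'   forest-loss field (regional deforestation histories).
#' @param plot_area Plot area in hectares.
#' @param basal_obs_sd Lognormal observation noise on plot basal area.
#' @param trait_missing Fraction of species x continuous-trait cells set to
#'   missing (MCAR), for exercising coverage filters.
#' @param overdispersion If not `NULL`, negative-binomial size parameter used
#'   instead of Poisson sampling of stem counts.
#' @param seed Integer seed fixing every draw of the scenario.
#'
#' @return An object of class `ts_scenario` (a validated list).
#' @export
#' @examples
#' cfg <- scenario_config(n_regions = 1, plots_per_region = 40,
#'                        n_species_pool = 100, seed = 1)
#' sim <- simulate_scenario(cfg)
#' names(sim)
scenario_config <- function(n_regions = 6,
                            plots_per_region = 45,
                            n_species_pool = 1000,
                            scales = c(500, 1000, 2000),
                            dag_coefficients = list(a1 = 0.8, b1 = 0.5, b2 = 0.5,
                                                    c1 = 0.4, c2 = 0.25, c3 = 0.35),
                            trait_effect = c(wood_density = -0.5, seed_mass = -0.4),
                            degradation_effect = c(wood_density = -0.25, seed_mass = -0.2),
                            noise_sd = c(patches = 0.8, edge = 0.7, degradation = 0.7),
                            spatial_range = 0,
                            abundance_lognormal_sd = 1.5,
                            stems_per_plot = 110,
                            scale_cor = NULL,
                            region_sd = 0.35,
                            plot_area = 0.25,
                            basal_obs_sd = 0.02,
                            trait_missing = 0,
                            overdispersion = NULL,
                            seed = 1L) {
  counts <- c(n_regions = n_regions, plots_per_region = plots_per_region,
              n_species_pool = n_species_pool)
  if (any(counts < 1)) abort_bad("all counts must be >= 1")
  if (any(noise_sd < 0)) abort_bad("noise_sd components must be >= 0")
  if (spatial_range < 0) abort_bad("spatial_range must be >= 0")
  if (trait_missing < 0 || trait_missing >= 1) abort_bad("trait_missing must be in [0, 1)")
  scales <- sort(unique(scales))
  noise_sd <- modifyList(list(patches = 0.8, edge = 0.7, degradation = 0.7),
                         as.list(noise_sd))
  dag_coefficients <- modifyList(list(a1 = 0.8, b1 = 0.5, b2 = 0.5,
                                      c1 = 0.4, c2 = 0.25, c3 = 0.35),
                                 as.list(dag_coefficients))
  if (is.null(scale_cor)) {
    # Nested buffers: smaller windows share less of the reference field.
    scale_cor <- if (length(scales) == 1) 1 else seq(0.8, 1, length.out = length(scales))
    scale_cor <- set_names(scale_cor, as.character(scales))
  } else {
    scale_cor <- set_names(as.numeric(scale_cor[as.character(scales)]), as.character(scales))
    if (anyNA(scale_cor)) abort_bad("scale_cor must name every scale")
  }
  bad <- setdiff(names(trait_effect), continuous_traits())
  if (length(bad)) abort_bad("trait_effect names unknown: %s", paste(bad, collapse = ", "))
  bad <- setdiff(names(degradation_effect), continuous_traits())
  if (length(bad)) abort_bad("degradation_effect names unknown: %s", paste(bad, collapse = ", "))
  cfg <- structure(list(
    n_regions = as.integer(n_regions),
    plots_per_region = as.integer(plots_per_region),
    n_species_pool = as.integer(n_species_pool),
    scales = scales,
    dag_coefficients = dag_coefficients,
    trait_effect = trait_effect,
    degradation_effect = degradation_effect,
    noise_sd = noise_sd,
    spatial_range = spatial_range,
    abundance_lognormal_sd = abundance_lognormal_sd,
    stems_per_plot = stems_per_plot,
    scale_cor = scale_cor,
    region_sd = region_sd,
    plot_area = plot_area,
    basal_obs_sd = basal_obs_sd,
    trait_missing = trait_missing,
    overdispersion = overdispersion,
    seed = as.integer(seed),
    # Fixed observation maps from latent z scores to field units.
    maps = list(loss = c(mu = 2.2, sd = 0.6),
                patches = c(mu = 2.5, sd = 0.8),
                patches_scale_shift = set_names(
                  seq(-1.2, 0, length.out = length(scales)), as.character(scales)),
                edge = c(mu = 0.45, sd = 0.12),
                degradation = c(mu = 0.04, sd = 0.008))
  ), class = "ts_scenario")
  # Every trait's sorting gradient must have variance <= 1 before the
  # idiosyncratic plot-level term tops it up to exactly 1.
  tr <- scenario_truth(cfg)
  cfg
}

continuous_traits <- function() c("wood_density", "seed_mass", "lma", "h_max")

#' @export
print.ts_scenario <- function(x, ...) {
  cat("<ts_scenario>\n")
  cat(sprintf("  %d region(s) x %d plots, %d species pool, seed %d\n",
              x$n_regions, x$plots_per_region, x$n_species_pool, x$seed))
  cat(sprintf("  scales: %s m; spatial range: %g m\n",
              paste(x$scales, collapse = "/"), x$spatial_range))
  cat(sprintf("  forest-loss sorting: %s\n",
              paste(sprintf("%s=%g", names(x$trait_effect), x$trait_effect), collapse = ", ")))
  invisible(x)
}

# ---------------------------------------------------------------------------
# Latent structure: every latent variable is a unit-norm loading vector over
# orthonormal shocks, so covariances are plain dot products.

scenario_latents <- function(config) {
  sc <- as.character(config$scales)
  ref <- sc[length(sc)]
  d <- config$dag_coefficients
  ns <- config$noise_sd
  shocks <- c("u0", paste0("eL_", sc), paste0("eP_", sc), paste0("eE_", sc), "eD")
  zero <- set_names(numeric(length(shocks)), shocks)
  per_scale <- list()
  for (s in sc) {
    rho <- config$scale_cor[[s]]
    zL <- zero; zL["u0"] <- rho; zL[paste0("eL_", s)] <- sqrt(max(0, 1 - rho^2))
    zPr <- d$a1 * zL; zPr[paste0("eP_", s)] <- zPr[paste0("eP_", s)] + ns$patches
    sP <- sqrt(sum(zPr^2)); zP <- zPr / sP
    zEr <- d$b1 * zL + d$b2 * zP; zEr[paste0("eE_", s)] <- zEr[paste0("eE_", s)] + ns$edge
    sE <- sqrt(sum(zEr^2)); zE <- zEr / sE
    per_scale[[s]] <- list(zL = zL, zP = zP, zE = zE, sP = sP, sE = sE)
  }
  zDr <- d$c1 * per_scale[[ref]]$zL + d$c2 * per_scale[[ref]]$zP +
    d$c3 * per_scale[[ref]]$zE
  zDr["eD"] <- zDr["eD"] + ns$degradation
  sD <- sqrt(sum(zDr^2)); zD <- zDr / sD
  list(per_scale = per_scale, zD = zD, sD = sD, shocks = shocks, ref = ref)
}

# Standardized path coefficient matrix among (loss, patches, edge,
# degradation) at the reference scale; entry [to, from].
scenario_path_matrix <- function(config) {
  lat <- scenario_latents(config)
  d <- config$dag_coefficients
  ref <- lat$per_scale[[lat$ref]]
  B <- matrix(0, 4, 4, dimnames = list(
    c("forest_loss", "n_patches", "edge_density", "degradation"),
    c("forest_loss", "n_patches", "edge_density", "degradation")))
  B["n_patches", "forest_loss"] <- d$a1 / ref$sP
  B["edge_density", "forest_loss"] <- d$b1 / ref$sE
  B["edge_density", "n_patches"] <- d$b2 / ref$sE
  B["degradation", "forest_loss"] <- d$c1 / lat$sD
  B["degradation", "n_patches"] <- d$c2 / lat$sD
  B["degradation", "edge_density"] <- d$c3 / lat$sD
  B
}

# Direct standardized effects of the four exposures on trait t's sorting
# gradient, in DAG order.
scenario_direct_effects <- function(config, trait) {
  c(forest_loss = unname(config$trait_effect[trait]) %|NA|% 0,
    n_patches = 0,
    edge_density = 0,
    degradation = unname(config$degradation_effect[trait]) %|NA|% 0)
}

`%|NA|%` <- function(x, y) if (length(x) == 0 || is.na(x)) y else x

# Loading vector of trait t's sorting gradient (reference-scale exposures
# plus an idiosyncratic plot-level term topping variance up to 1).
scenario_gradient_loading <- function(config, trait, latents = scenario_latents(config)) {
  g <- scenario_direct_effects(config, trait)
  ref <- latents$per_scale[[latents$ref]]
  L <- g[["forest_loss"]] * ref$zL + g[["n_patches"]] * ref$zP +
    g[["edge_density"]] * ref$zE + g[["degradation"]] * latents$zD
  v <- sum(L^2)
  if (v > 1 + 1e-12) {
    abort_bad("sorting gradient for %s has latent variance %.3f > 1; reduce effects", trait, v)
  }
  # A trait with no configured effect has no sorting gradient at all: the
  # idiosyncratic plot-level term only tops up the variance of an existing
  # gradient to one (so configured slopes are exact standardized effects);
  # it is not a free-standing latent gradient.
  list(loading = L, sort_sd = if (v == 0) 0 else sqrt(max(0, 1 - v)))
}

#' Closed-form ground truth for a scenario
#'
#' Returns, for every continuous trait with a configured sorting effect and
#' every exposure x scale, the true total standardized effect that the
#' backdoor-adjusted pipeline estimates, together with (at the reference
#' scale) the same quantity obtained as the path-coefficient sum over the
#' standardized DAG.  The two derivations agree to numerical precision, which
#' the test suite asserts.
#'
#' @param config A [scenario_config()] object.
#' @return A tibble with columns `trait`, `exposure`, `scale`, `effect`
#'   (regression estimand given the exposure's backdoor control set) and
#'   `path_sum` (path-enumeration total effect; reference scale only).
#' @export
scenario_truth <- function(config) {
  lat <- scenario_latents(config)
  exposures <- c("forest_loss", "n_patches", "edge_density", "degradation")
  B <- scenario_path_matrix(config)
  Tz <- solve(diag(4) - B)  # total effects among exposures (incl. identity)
  dimnames(Tz) <- dimnames(B)
  traits <- union(names(config$trait_effect), names(config$degradation_effect))
  if (!length(traits)) traits <- "wood_density"
  rows <- list()
  for (trait in traits) {
    g <- scenario_direct_effects(config, trait)
    grad <- scenario_gradient_loading(config, trait, lat)
    for (s in names(lat$per_scale)) {
      ps <- lat$per_scale[[s]]
      V <- rbind(forest_loss = ps$zL, n_patches = ps$zP,
                 edge_density = ps$zE, degradation = lat$zD)
      Sg <- V %*% grad$loading            # cov(exposure_s, gradient)
      SS <- V %*% t(V)                    # cov among exposures at scale s
      for (e in exposures) {
        ctrl <- backdoor_controls(e)
        vars <- c(e, ctrl)
        # Degenerate (noise-free) scenarios make exposures collinear; the
        # regression estimand is then undefined and reported as NA.
        beta <- tryCatch(
          solve(SS[vars, vars, drop = FALSE], Sg[vars, , drop = FALSE])[1],
          error = function(e) NA_real_)
        path_sum <- if (s == lat$ref) sum(g * Tz[, e]) else NA_real_
        rows[[length(rows) + 1L]] <- tibble(
          trait = trait, exposure = e, scale = as.numeric(s),
          effect = beta, path_sum = path_sum)
      }
    }
  }
  list_rbind(rows)
}
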