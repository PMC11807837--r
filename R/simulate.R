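#' Simulate landscape disturbance tables with a known causal structure
#'
#' Draws plot coordinates and, for every plot x buffer scale, the three
#' landscape disturbance variables (percent forest loss, number of forest
#' patches, edge density) plus a latent local degradation index, following
#' the assumed causal chain loss -> patches -> edge -> degradation.  A
#' region-level shift of the shared forest-loss field emulates contrasting
#' regional deforestation histories; an optional Gaussian-process component
#' adds spatial autocorrelation.
#'
#' @param config A [scenario_config()].
#' @return A list with tibbles `plots` (plot_id, region_id, x, y, plot_area),
#'   `landscape` (plot_id, scale, forest_loss, n_patches, edge_density) and
#'   `degradation` (plot_id, degradation).  The latent shock matrix used to
#'   build the fields is attached as attribute `"shocks"` so that
#'   [simulate_communities()] can sort species along the same gradients.
#' @export
simulate_landscape <- function(config) {
  stopifnot(inherits(config, "ts_scenario"))
  lat <- scenario_latents(config)
  n_r <- config$n_regions
  n_p <- config$plots_per_region
  n <- n_r * n_p
  region_id <- rep(sprintf("R%d", seq_len(n_r)), each = n_p)

  plots <- with_seed(sub_seed(config$seed, "coords"), {
    tibble(
      plot_id = sprintf("p%04d", seq_len(n)),
      region_id = region_id,
      x = rep((seq_len(n_r) - 1) * 50000, each = n_p) + runif(n, 0, 6000),
      y = runif(n, 0, 6000),
      plot_area = config$plot_area
    )
  })

  S <- with_seed(sub_seed(config$seed, "shocks"), {
    m <- matrix(rnorm(n * length(lat$shocks)), n, length(lat$shocks),
                dimnames = list(plots$plot_id, lat$shocks))
    if (config$spatial_range > 0) {
      # Exponential-kernel GP on the shared forest-loss field, per region.
      for (r in unique(region_id)) {
        idx <- which(region_id == r)
        D <- as.matrix(dist(cbind(plots$x[idx], plots$y[idx])))
        K <- exp(-D / config$spatial_range) + diag(1e-8, length(idx))
        m[idx, "u0"] <- drop(t(chol(K)) %*% rnorm(length(idx)))
      }
    }
    m
  })
  delta <- with_seed(sub_seed(config$seed, "regions"),
                     rnorm(n_r, 0, config$region_sd))
  S[, "u0"] <- S[, "u0"] + delta[as.integer(factor(region_id, levels = unique(region_id)))]

  maps <- config$maps
  landscape <- list_rbind(map(names(lat$per_scale), function(s) {
    ps <- lat$per_scale[[s]]
    zL <- unname(drop(S %*% ps$zL)); zP <- unname(drop(S %*% ps$zP))
    zE <- unname(drop(S %*% ps$zE))
    tibble(
      plot_id = plots$plot_id,
      scale = as.numeric(s),
      forest_loss = clamp(expm1(maps$loss[["mu"]] + maps$loss[["sd"]] * zL), 0, 100),
      n_patches = pmax(1, round(expm1(maps$patches[["mu"]] +
        maps$patches_scale_shift[[s]] + maps$patches[["sd"]] * zP))),
      edge_density = clamp(maps$edge[["mu"]] + maps$edge[["sd"]] * zE, 0, 1)
    )
  }))
  degradation <- tibble(
    plot_id = plots$plot_id,
    degradation = maps$degradation[["mu"]] +
      maps$degradation[["sd"]] * unname(drop(S %*% lat$zD))
  )
  out <- list(plots = plots, landscape = landscape, degradation = degradation)
  attr(out, "shocks") <- S
  out
}

#' Simulate a species trait pool
#'
#' Continuous traits follow distributions typical of Neotropical tree floras:
#' wood density from a normal truncated to (0.1, 1.2) g cm^-3, seed mass and
#' maximum height lognormal, LMA normal truncated positive.  The dispersal
#' syndrome is drawn from a multinomial logit on standardized log seed mass,
#' so synzoochory is enriched among large-seeded species and abiotic
#' dispersal among small-seeded ones.
#'
#' @param config A [scenario_config()].
#' @return Tibble with `species_id`, `genus`, the four continuous traits and
#'   `dispersal_syndrome` (abiotic / endozoochory / synzoochory).
#' @export
simulate_trait_pool <- function(config) {
  stopifnot(inherits(config, "ts_scenario"))
  if (config$n_species_pool < 2) abort_bad("n_species_pool must be >= 2")
  n <- config$n_species_pool
  with_seed(sub_seed(config$seed, "traits"), {
    rtruncnorm <- function(n, mean, sd, lo, hi = Inf) {
      u <- runif(n, pnorm((lo - mean) / sd), pnorm((hi - mean) / sd))
      mean + sd * qnorm(u)
    }
    seed_mass <- rlnorm(n, log(150), 1.5)
    s <- as.numeric(scale(log(seed_mass)))
    probs <- syndrome_probabilities(s)
    syndrome <- syndrome_levels()[max.col(log(probs) - log(-log(matrix(
      runif(n * 3), n, 3))))]  # Gumbel-max categorical draw
    n_gen <- max(1L, round(n / 3))
    tibble(
      species_id = sprintf("sp%04d", seq_len(n)),
      genus = sprintf("g%04d", sample.int(n_gen, n, replace = TRUE)),
      wood_density = rtruncnorm(n, 0.6, 0.15, 0.1, 1.2),
      seed_mass = seed_mass,
      lma = rtruncnorm(n, 90, 25, 10),
      h_max = rlnorm(n, log(20), 0.4),
      dispersal_syndrome = syndrome
    ) |>
      inject_trait_missingness(config)
  })
}

syndrome_levels <- function() c("abiotic", "endozoochory", "synzoochory")

# Multinomial logit link of dispersal syndrome on standardized log seed mass.
syndrome_probabilities <- function(s) {
  eta <- cbind(abiotic = 0 - 0.8 * s,
               endozoochory = 0.5 - 0.1 * s,
               synzoochory = -1.2 + 1.1 * s)
  p <- exp(eta)
  p / rowSums(p)
}

inject_trait_missingness <- function(traits, config) {
  if (config$trait_missing <= 0) return(traits)
  with_seed(sub_seed(config$seed, "missing"), {
    for (tr in continuous_traits()) {
      drop <- runif(nrow(traits)) < config$trait_missing
      traits[[tr]][drop] <- NA_real_
    }
    traits
  })
}

#' Simulate communities sorted along disturbance gradients
#'
#' Expected stem counts combine a lognormal species baseline (hyperdominance)
#' with trait-mediated sorting: the log intensity of species *j* in plot *i*
#' gains `G[i, t] * z(trait_j)` for every sorting trait *t*, where `G` is the
#' plot-level disturbance gradient built from the configured forest-loss and
#' degradation effects (plus an idiosyncratic plot term that tops its
#' variance up to one, so configured slopes are exactly the standardized
#' total effects the pipeline estimates).  Counts are Poisson (or negative
#' binomial when `overdispersion` is set); plot basal area decreases with the
#' latent degradation index so that its inverse recovers that index up to
#' observation noise.
#'
#' @param config A [scenario_config()].
#' @param landscape Output of [simulate_landscape()] for the same config.
#' @param traits Output of [simulate_trait_pool()] for the same config.
#' @return List with `abundance` (long tibble plot_id/species_id/count),
#'   `plots` (plot metadata including realized `basal_area`, m^2 per plot)
#'   and `truth` (closed-form total effects, species niche optima and the
#'   standardized path matrix).
#' @export
simulate_communities <- function(config, landscape, traits) {
  stopifnot(inherits(config, "ts_scenario"))
  S <- attr(landscape, "shocks")
  if (is.null(S)) {
    abort_bad(paste("landscape lacks the latent shock attribute;",
                    "pass the object returned by simulate_landscape()"))
  }
  if (nrow(traits) != config$n_species_pool) {
    abort_bad("traits table has %d rows but config expects %d",
              nrow(traits), config$n_species_pool)
  }
  plots <- landscape$plots
  n <- nrow(plots)
  lat <- scenario_latents(config)
  sorting_traits <- union(names(config$trait_effect), names(config$degradation_effect))

  # Standardized sorting trait values (seed mass sorts on the log scale).
  tstar <- vapply(sorting_traits, function(tr) {
    x <- traits[[tr]]
    if (tr == "seed_mass") x <- log(x)
    x[is.na(x)] <- mean(x, na.rm = TRUE)
    as.numeric(scale(x))
  }, numeric(nrow(traits)))

  with_seed(sub_seed(config$seed, "communities"), {
    log_u <- rnorm(nrow(traits), 0, config$abundance_lognormal_sd)
    G <- vapply(sorting_traits, function(tr) {
      gl <- scenario_gradient_loading(config, tr, lat)
      drop(S %*% gl$loading) + gl$sort_sd * rnorm(n)
    }, numeric(n))
    eta <- G %*% t(tstar)                       # n_plots x n_species sorting term
    lam <- exp(sweep(eta, 2, log_u, "+"))
    mu <- config$stems_per_plot * lam / rowSums(lam)
    counts <- if (is.null(config$overdispersion)) {
      rpois(length(mu), mu)
    } else {
      rnbinom(length(mu), mu = mu, size = config$overdispersion)
    }
    counts <- matrix(counts, n, nrow(traits),
                     dimnames = list(plots$plot_id, traits$species_id))
    abundance <- as_tibble(as.table(counts), .name_repair = "minimal") |>
      set_names(c("plot_id", "species_id", "count")) |>
      filter(.data$count > 0) |>
      mutate(count = as.integer(.data$count)) |>
      arrange(.data$plot_id, .data$species_id)

    ba_per_area <- 1 / landscape$degradation$degradation     # m^2 per ha
    plots$basal_area <- ba_per_area * plots$plot_area *
      exp(rnorm(n, 0, config$basal_obs_sd))

    total <- scenario_truth(config)
    loss_ref <- total |>
      filter(.data$exposure == "forest_loss", .data$scale == max(.data$scale))
    optimum <- drop(tstar %*% set_names(loss_ref$effect, loss_ref$trait)[sorting_traits])
    truth <- list(
      total_effects = total,
      species_optimum = tibble(species_id = traits$species_id,
                               niche_optimum = as.numeric(optimum)),
      path_matrix = scenario_path_matrix(config)
    )
    list(abundance = abundance, plots = plots, truth = truth)
  })
}

#' Run the full synthetic generator
#'
#' @param config A [scenario_config()].
#' @return A `ts_simulation` list: `plots`, `landscape`, `degradation`,
#'   `traits`, `abundance`, `truth`, `config`.
#' @export
simulate_scenario <- function(config) {
  land <- simulate_landscape(config)
  traits <- simulate_trait_pool(config)
  comm <- simulate_communities(config, land, traits)
  structure(list(
    plots = comm$plots,
    landscape = land$landscape,
    degradation = land$degradation,
    traits = traits,
    abundance = comm$abundance,
    truth = comm$truth,
    config = config
  ), class = "ts_simulation")
}

#' @export
print.ts_simulation <- function(x, ...) {
  cat("<ts_simulation>\n")
  cat(sprintf("  %d plots, %d species pool, %s stems\n",
              nrow(x$plots), nrow(x$traits), format(sum(x$abundance$count))))
  cat(sprintf("  scales: %s m\n", paste(unique(x$landscape$scale), collapse = "/")))
  invisible(x)
}
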