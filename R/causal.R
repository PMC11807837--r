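# Backdoor-adjusted standardized effect models for community outcomes.

dag_exposures <- function() c("forest_loss", "n_patches", "edge_density", "degradation")

#' The assumed disturbance DAG
#'
#' Directed edges among the four disturbance variables: forest loss increases
#' the number of forest patches, both increase edge density, and all three
#' drive local degradation; every disturbance variable points at the
#' community outcome.
#'
#' @return A `ts_dag` list with `nodes` and an `edges` tibble.
#' @export
causal_dag <- function() {
  edges <- tribble(
    ~from, ~to,
    "forest_loss", "n_patches",
    "forest_loss", "edge_density",
    "n_patches", "edge_density",
    "forest_loss", "degradation",
    "n_patches", "degradation",
    "edge_density", "degradation",
    "forest_loss", "outcome",
    "n_patches", "outcome",
    "edge_density", "outcome",
    "degradation", "outcome"
  )
  structure(list(nodes = c(dag_exposures(), "outcome"), edges = edges),
            class = "ts_dag")
}

#' Minimal backdoor control set for a total effect
#'
#' For the assumed DAG the minimal adjustment sets are the exposure's
#' parents: none for forest loss, forest loss for fragmentation ("per se"
#' effects), forest loss plus fragmentation for edge density, and all three
#' landscape variables for local degradation.
#'
#' @param exposure One of `forest_loss`, `n_patches`, `edge_density`,
#'   `degradation`.
#' @param dag A `ts_dag`; defaults to [causal_dag()].
#' @return Character vector of control variables (possibly empty).
#' @export
backdoor_controls <- function(exposure, dag = causal_dag()) {
  if (!exposure %in% setdiff(dag$nodes, "outcome")) {
    abort_bad("unknown exposure '%s'", exposure)
  }
  # Total effect: adjust for the exposure's parents (no descendants allowed;
  # parents close every backdoor path in this DAG).
  sort_by_dag <- function(x) intersect(dag_exposures(), x)
  sort_by_dag(dag$edges$from[dag$edges$to == exposure])
}

#' Log-transform and standardize model variables
#'
#' Applies `log1p` to forest loss and patch counts (zeros occur in fully
#' forested landscapes), then z-scores every requested variable within the
#' given grouping.  Zero-variance variables are dropped with a warning.
#'
#' @param df A tibble.
#' @param variables Columns to transform/standardize.
#' @param group Grouping columns for the z-scoring (e.g. region, or region
#'   and scale).
#' @return `df` with the variables replaced by standardized versions; dropped
#'   columns recorded in attribute `"dropped"`.
#' @export
transform_and_standardize <- function(df, variables,
                                      group = intersect("region_id", names(df))) {
  assert_cols(df, variables, "model table")
  for (v in intersect(variables, c("forest_loss", "n_patches"))) {
    df[[v]] <- log1p(df[[v]])
  }
  dropped <- character(0)
  df <- df |> group_by(across(all_of(group)))
  for (v in variables) {
    s <- df |> summarise(sd = sd(.data[[v]], na.rm = TRUE), .groups = "drop")
    if (any(!is.finite(s$sd) | s$sd == 0)) {
      dropped <- c(dropped, v)
      next
    }
    df <- df |> mutate(!!v := as.numeric(scale(.data[[v]])))
  }
  df <- df |> ungroup()
  if (length(dropped)) {
    warn(sprintf("dropping zero-variance variable(s): %s", paste(dropped, collapse = ", ")))
    df <- df |> select(-all_of(dropped))
  }
  attr(df, "dropped") <- dropped
  df
}

#' Fit one backdoor-adjusted effect model
#'
#' Ordinary least squares of a standardized outcome on a standardized
#' exposure, its backdoor control set, and (optionally) selected spatial
#' eigenvectors.  The reported effect is the exposure coefficient with a
#' t-based 95% confidence interval; significance means the interval
#' excludes zero.  The adjusted R-squared of the non-spatial model is
#' reported alongside the full model's.
#'
#' @param df Tibble of standardized variables (complete cases are used).
#' @param outcome,exposure Column names.
#' @param controls Character vector of control columns.
#' @param mem Optional matrix of spatial eigenvectors (rows matching `df`).
#' @param conf_level Confidence level for the interval.
#' @return A `ts_effect` object; see [tidy.ts_effect()].
#' @export
fit_causal_model <- function(df, outcome, exposure, controls = character(0),
                             mem = NULL, conf_level = 0.95) {
  assert_cols(df, c(outcome, exposure, controls), "model table")
  vars <- c(outcome, exposure, controls)
  keep <- complete.cases(df[vars])
  dat <- df[keep, vars]
  names(dat) <- c(".y", ".x", if (length(controls)) paste0(".c", seq_along(controls)))
  rhs <- setdiff(names(dat), ".y")
  if (!is.null(mem) && ncol(mem) > 0) {
    mem <- mem[keep, , drop = FALSE]
    for (k in seq_len(ncol(mem))) dat[[paste0(".mem", k)]] <- mem[, k]
    rhs <- c(rhs, paste0(".mem", seq_len(ncol(mem))))
  }
  if (nrow(dat) < length(rhs) + 2) {
    abort_bad("too few complete cases (%d) for %d predictors", nrow(dat), length(rhs))
  }
  fit <- lm(as.formula(paste(".y ~", paste(rhs, collapse = " + "))), data = dat)
  if (anyNA(coef(fit))) {
    bad <- names(coef(fit))[is.na(coef(fit))]
    abort_bad("rank-deficient model; collinear terms: %s", paste(bad, collapse = ", "))
  }
  fit_plain <- if (!is.null(mem) && ncol(mem) > 0) {
    lm(as.formula(paste(".y ~", paste(setdiff(rhs, grep("^\\.mem", rhs, value = TRUE)),
                                      collapse = " + "))), data = dat)
  } else fit
  ci <- confint(fit, ".x", level = conf_level)
  structure(list(
    exposure = exposure, outcome = outcome, controls = controls,
    beta = unname(coef(fit)[".x"]),
    ci_low = ci[1], ci_high = ci[2],
    r2_adj = summary(fit_plain)$adj.r.squared,
    r2_adj_spatial = summary(fit)$adj.r.squared,
    n_plots = nrow(dat),
    mem_terms = if (is.null(mem)) 0L else ncol(mem),
    conf_level = conf_level,
    fit = fit
  ), class = "ts_effect")
}

#' @export
print.ts_effect <- function(x, ...) {
  cat(sprintf("<ts_effect> %s -> %s: beta = %.3f [%.3f, %.3f], R2adj = %.3f (n = %d)\n",
              x$exposure, x$outcome, x$beta, x$ci_low, x$ci_high, x$r2_adj, x$n_plots))
  invisible(x)
}

#' @describeIn fit_causal_model Tidy the effect estimate into one row.
#' @param x A `ts_effect`.
#' @param ... Unused.
#' @export
tidy.ts_effect <- function(x, ...) {
  tibble(exposure = x$exposure, outcome = x$outcome,
         beta = x$beta, ci_low = x$ci_low, ci_high = x$ci_high,
         significant = x$ci_low > 0 | x$ci_high < 0,
         r2_adj = x$r2_adj, r2_adj_spatial = x$r2_adj_spatial,
         n_plots = x$n_plots, mem_terms = x$mem_terms,
         control_set = paste(x$controls, collapse = "+"))
}

#' @describeIn fit_causal_model One-row model summary.
#' @export
glance.ts_effect <- function(x, ...) {
  s <- summary(x$fit)
  tibble(r2 = s$r.squared, r2_adj = s$adj.r.squared,
         sigma = s$sigma, n = x$n_plots,
         df_residual = x$fit$df.residual)
}

# Assemble the per-plot modelling table for one trait/statistic/scale.
model_table <- function(profiles, landscape, plots, trait, statistic, scale) {
  stat_col <- c(cwm = "cwm", p05 = "p_lower", p95 = "p_upper")[[statistic]]
  profiles |>
    filter(.data$trait == !!trait) |>
    transmute(plot_id = .data$plot_id, outcome = .data[[stat_col]]) |>
    inner_join(landscape |> filter(.data$scale == !!scale), by = "plot_id") |>
    inner_join(plots |> select(any_of(c("plot_id", "region_id", "x", "y",
                                        "degradation"))), by = "plot_id")
}

#' Estimate the full grid of standardized causal effects
#'
#' One backdoor-adjusted model per exposure x trait x statistic x region x
#' scale, each on standardized variables (predictors z-scored within region
#' x scale, outcomes within region).  Optionally detects and corrects
#' residual spatial autocorrelation with Moran's eigenvector maps before
#' reporting the effect.  Per-cell failures (e.g. too few plots) are
#' returned as flagged rows, never aborting the grid.
#'
#' @param data A `ts_data` list.
#' @param traits Traits to analyse (default: the four continuous traits and
#'   the three syndrome proportions).
#' @param statistics Subset of `c("cwm", "p05", "p95")`.
#' @param scales Buffer scales to analyse (default: all in the data).
#' @param exposures Subset of the four disturbance exposures.
#' @param spatial_filter Run the Moran eigenvector selection per model.
#' @param profiles Optional precomputed [community_profiles()] output.
#' @param alpha,n_perm,seed Spatial-filter settings.
#' @return Tibble of effect estimates (one row per grid cell), with an
#'   `error` column flagging failed cells.
#' @export
run_effect_grid <- function(data,
                            traits = profile_trait_names(),
                            statistics = c("cwm", "p05", "p95"),
                            scales = NULL,
                            exposures = dag_exposures(),
                            spatial_filter = FALSE,
                            profiles = NULL,
                            alpha = 0.05, n_perm = 199, seed = 1L) {
  scales <- scales %||% sort(unique(data$landscape$scale))
  statistics <- match.arg(statistics, several.ok = TRUE)
  exposures <- match.arg(exposures, dag_exposures(), several.ok = TRUE)
  profiles <- profiles %||% community_profiles(data$abundance, data$traits)
  regions <- sort(unique(data$plots$region_id))
  grid <- expand_grid(exposure = exposures, trait = traits,
                      statistic = statistics, region = regions, scale = scales)
  rows <- pmap(grid, function(exposure, trait, statistic, region, scale) {
    base <- tibble(exposure = exposure, trait = trait, statistic = statistic,
                   region = region, scale = scale)
    out <- tryCatch({
      tab <- model_table(profiles, data$landscape, data$plots, trait, statistic, scale) |>
        inner_join(data$plots[c("plot_id", "region_id")] |>
                     filter(.data$region_id == !!region) |> select("plot_id"),
                   by = "plot_id")
      tab <- suppressWarnings(transform_and_standardize(
        tab, c("outcome", dag_exposures()), group = character(0)))
      controls <- backdoor_controls(exposure)
      mem <- NULL
      n_mem <- 0L
      if (spatial_filter && nrow(tab) >= 4) {
        plain <- fit_causal_model(tab, "outcome", exposure, controls)
        cand <- build_spatial_candidates(tab[c("x", "y")])
        sel <- select_spatial_filter(resid(plain$fit), cand, alpha = alpha,
                                     n_perm = n_perm,
                                     seed = sub_seed(seed, paste(exposure, trait,
                                                                 statistic, region, scale)))
        mem <- sel$selected
        n_mem <- sel$n_vectors
      }
      est <- fit_causal_model(tab, "outcome", exposure, controls, mem = mem)
      bind_cols(base, tidy(est) |> select(-"exposure", -"outcome"))
    }, error = function(e) bind_cols(base, tibble(error = conditionMessage(e))))
    out
  })
  res <- bind_rows(rows)
  if (!"error" %in% names(res)) res$error <- NA_character_
  res
}

# Second-order small-sample Akaike criterion.
aicc <- function(fit) {
  k <- length(coef(fit)) + 1
  n <- length(resid(fit))
  AIC(fit) + 2 * k * (k + 1) / max(n - k - 1, 1)
}

#' Best-subset predictive model over the four exposures
#'
#' Complements the causal models: selects, by small-sample AIC (an
#' information criterion approximating out-of-sample predictive accuracy),
#' the subset of the four disturbance exposures that best predicts the
#' outcome, and reports its adjusted R-squared.
#'
#' @param df Standardized model table (see [transform_and_standardize()]).
#' @param outcome Outcome column.
#' @param exposures Candidate predictors.
#' @return List with `selected`, `r2_adj`, `aicc`, `fit`, and the per-subset
#'   `path` table.
#' @export
fit_predictive_model <- function(df, outcome, exposures = dag_exposures()) {
  assert_cols(df, c(outcome, exposures), "model table")
  keep <- complete.cases(df[c(outcome, exposures)])
  dat <- df[keep, c(outcome, exposures)]
  subsets <- unlist(lapply(0:length(exposures), function(k)
    combn(exposures, k, simplify = FALSE)), recursive = FALSE)
  path <- map(subsets, function(s) {
    f <- if (length(s)) paste(outcome, "~", paste(s, collapse = " + "))
         else paste(outcome, "~ 1")
    fit <- lm(as.formula(f), data = dat)
    tibble(subset = paste(s, collapse = "+"), k = length(s),
           aicc = aicc(fit), r2_adj = summary(fit)$adj.r.squared)
  }) |> list_rbind()
  best <- path |> arrange(.data$aicc, .data$k) |> slice(1)
  sel <- if (nzchar(best$subset)) strsplit(best$subset, "\\+")[[1]] else character(0)
  f <- if (length(sel)) paste(outcome, "~", paste(sel, collapse = " + "))
       else paste(outcome, "~ 1")
  fit <- lm(as.formula(f), data = dat)
  list(selected = sel, r2_adj = best$r2_adj, aicc = best$aicc,
       fit = fit, path = path)
}
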