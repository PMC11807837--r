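# Double-constrained correspondence analysis: species scores constrained by
# traits, site scores by disturbance predictors, eigenvalues equal to
# squared fourth-corner correlations of the paired composite gradients.

#' Row-normalize an abundance matrix for correspondence analysis
#'
#' Divides counts by plot totals (making the CWM regressions inside dc-CA
#' unweighted and damping plot-size effects), then derives the
#' correspondence-analysis row/column weights and the standardized
#' contingency residual matrix.
#'
#' @param Y Plots x species abundance matrix (dimnames required), or a long
#'   abundance tibble (`plot_id`, `species_id`, `count`).
#' @return List with `P` (relative abundance, total sum 1), `r`, `c` (row and
#'   column weights), and `Q`, the doubly weighted residual matrix
#'   `diag(r)^-1/2 (P - r c') diag(c)^-1/2`.
#' @export
prepare_relative_abundance <- function(Y) {
  if (is.data.frame(Y)) Y <- abundance_matrix(Y)
  if (is.null(rownames(Y)) || is.null(colnames(Y))) {
    abort_bad("abundance matrix needs plot rownames and species colnames")
  }
  rs <- rowSums(Y)
  cs <- colSums(Y)
  if (any(rs == 0)) abort_bad("empty plot(s): %s",
                              paste(head(rownames(Y)[rs == 0], 3), collapse = ", "))
  if (any(cs == 0)) abort_bad("empty species: %s",
                              paste(head(colnames(Y)[cs == 0], 3), collapse = ", "))
  Yrel <- Y / rs
  P <- Yrel / sum(Yrel)
  r <- rowSums(P)
  cw <- colSums(P)
  Q <- (P - tcrossprod(r, cw)) / sqrt(tcrossprod(r, cw))
  list(P = P, r = r, c = cw, Q = Q)
}

# Weighted centering + unit weighted-variance scaling of a model matrix.
w_standardize_matrix <- function(M, w, label = "matrix") {
  M <- as.matrix(M)
  mu <- drop(crossprod(w, M))
  Mc <- sweep(M, 2, mu)
  sds <- sqrt(drop(crossprod(w, Mc^2)))
  if (any(sds <= 0)) {
    abort_bad("%s column(s) with zero weighted variance: %s", label,
              paste(colnames(M)[sds <= 0], collapse = ", "))
  }
  sweep(Mc, 2, sds, "/")
}

# Symmetric inverse square root with a collinearity guard.
inv_sqrt <- function(M, label = "matrix") {
  e <- eigen((M + t(M)) / 2, symmetric = TRUE)
  if (min(e$values) <= max(e$values) * 1e-10) {
    abort_bad("%s is collinear (condition number %.2e)", label,
              max(e$values) / max(min(e$values), .Machine$double.xmin))
  }
  e$vectors %*% (t(e$vectors) / sqrt(e$values))
}

# Shared preparation for fitting and permutation testing.
dcca_prepare <- function(Y, traits, env, covariates = NULL) {
  ca <- prepare_relative_abundance(Y)
  E <- as.matrix(env)
  TT <- as.matrix(traits)
  if (nrow(E) != length(ca$r)) abort_bad("env rows (%d) != plots (%d)", nrow(E), length(ca$r))
  if (nrow(TT) != length(ca$c)) abort_bad("trait rows (%d) != species (%d)", nrow(TT), length(ca$c))
  Q <- ca$Q
  proj_out <- NULL
  if (!is.null(covariates)) {
    Z <- as.matrix(covariates)
    Zc <- sweep(Z, 2, drop(crossprod(ca$r, Z)))
    Xz <- Zc * sqrt(ca$r)
    qz <- qr(Xz)
    proj_out <- function(M) M - qr.fitted(qz, M)
    Q <- proj_out(Q)
  }
  X <- w_standardize_matrix(E, ca$r, "predictor") * sqrt(ca$r)
  if (!is.null(proj_out)) X <- proj_out(X)
  W <- w_standardize_matrix(TT, ca$c, "trait") * sqrt(ca$c)
  list(ca = ca, E = E, TT = TT, Q = Q, X = X, W = W, proj_out = proj_out)
}

dcca_eigen <- function(X, Q, W) {
  if (max(colSums(X^2)) < 1e-12) {
    # Predictors entirely absorbed by the covariates: no testable signal.
    k <- min(ncol(X), ncol(W))
    return(list(d = rep(0, k), u = matrix(0, ncol(X), k),
                v = matrix(0, ncol(W), k), Gx = diag(ncol(X)),
                Gw = inv_sqrt(crossprod(W), "trait matrix")))
  }
  Gx <- inv_sqrt(crossprod(X), "predictor matrix")
  Gw <- inv_sqrt(crossprod(W), "trait matrix")
  B <- Gx %*% crossprod(X, Q %*% W) %*% Gw
  sv <- svd(B)
  k <- min(nrow(B), ncol(B))
  list(d = sv$d[seq_len(k)], u = sv$u[, seq_len(k), drop = FALSE],
       v = sv$v[, seq_len(k), drop = FALSE], Gx = Gx, Gw = Gw)
}

#' Fit a double-constrained correspondence analysis
#'
#' Axis *k* pairs a composite disturbance gradient (linear in the
#' predictors, site side) with a composite trait (linear in the traits,
#' species side) so that their weighted fourth-corner correlation through
#' the abundance table is maximal, subject to orthogonality to earlier
#' axes; the eigenvalue of an axis is that squared correlation.  Covariates
#' (typically the region factor) are partialled out of the predictors and of
#' the abundance residual matrix by weighted regression, so the analysis
#' captures within-region structure.
#'
#' @param Y Plots x species abundance matrix or long abundance tibble.
#' @param traits Species x trait numeric matrix/data frame (rows aligned
#'   with the columns of `Y`).
#' @param env Plots x predictor numeric matrix/data frame (rows aligned with
#'   the rows of `Y`).
#' @param covariates Optional plots x covariate numeric matrix (e.g. region
#'   indicator columns).
#' @return A `ts_dcca` object: `eigenvalues`, `fourth_corner` (per-axis
#'   correlations), standardized `env_weights` and `trait_weights`,
#'   `env_cor` / `trait_cor` (predictor- and trait-composite correlations),
#'   `site_scores`, `species_scores`.
#' @export
fit_dcca <- function(Y, traits, env, covariates = NULL) {
  pr <- dcca_prepare(Y, traits, env, covariates)
  eg <- dcca_eigen(pr$X, pr$Q, pr$W)
  env_w <- eg$Gx %*% eg$u
  trait_w <- eg$Gw %*% eg$v
  Es <- w_standardize_matrix(pr$E, pr$ca$r, "predictor")
  Ts <- w_standardize_matrix(pr$TT, pr$ca$c, "trait")
  if (!is.null(pr$proj_out)) {
    Es <- pr$proj_out(Es * sqrt(pr$ca$r)) / sqrt(pr$ca$r)
  }
  site <- Es %*% env_w
  species <- Ts %*% trait_w
  k <- length(eg$d)
  dimnames(env_w) <- list(colnames(pr$E), paste0("axis", seq_len(k)))
  dimnames(trait_w) <- list(colnames(pr$TT), paste0("axis", seq_len(k)))
  env_cor <- apply(site, 2, function(s)
    apply(Es, 2, w_cor, y = s, w = pr$ca$r))
  trait_cor <- apply(species, 2, function(s)
    apply(Ts, 2, w_cor, y = s, w = pr$ca$c))
  structure(list(
    eigenvalues = eg$d^2, fourth_corner = eg$d,
    env_weights = env_w, trait_weights = trait_w,
    env_cor = env_cor, trait_cor = trait_cor,
    site_scores = site, species_scores = species,
    row_weights = pr$ca$r, col_weights = pr$ca$c,
    n_axes = k
  ), class = "ts_dcca")
}

#' @export
print.ts_dcca <- function(x, ...) {
  cat("<ts_dcca>\n  eigenvalues:", signif(x$eigenvalues, 4), "\n")
  cat("  fourth-corner correlations:", signif(x$fourth_corner, 4), "\n")
  invisible(x)
}

#' @describeIn fit_dcca Per-axis eigenvalues and loadings in long form.
#' @param x A `ts_dcca`.
#' @param ... Unused.
#' @export
tidy.ts_dcca <- function(x, ...) {
  k <- x$n_axes
  bind_rows(
    as_tibble(x$env_weights, rownames = "term") |>
      pivot_longer(-"term", names_to = "axis", values_to = "weight") |>
      mutate(side = "predictor"),
    as_tibble(x$trait_weights, rownames = "term") |>
      pivot_longer(-"term", names_to = "axis", values_to = "weight") |>
      mutate(side = "trait")
  ) |>
    mutate(eigenvalue = x$eigenvalues[as.integer(sub("axis", "", .data$axis))])
}

#' @describeIn fit_dcca One-row summary (first eigenvalue, total inertia
#'   explained by the constrained axes).
#' @export
glance.ts_dcca <- function(x, ...) {
  tibble(n_axes = x$n_axes,
         eigenvalue_1 = x$eigenvalues[1],
         fourth_corner_1 = x$fourth_corner[1],
         total_constrained = sum(x$eigenvalues))
}

dcca_statistic <- function(d, statistic) {
  switch(statistic, first = d[1]^2, trace = sum(d^2))
}

#' Community/species max permutation test for dc-CA
#'
#' Tests the trait-disturbance association with the max test: the
#' community-level p value permutes plots (rows of the predictor table,
#' within covariate strata when given), the species-level p value permutes
#' rows of the trait table, and the reported `p_max` is the maximum of the
#' two, guarding against the type-1 error inflation of plain CWM
#' regression.
#'
#' @inheritParams fit_dcca
#' @param strata Optional factor over plots restricting community
#'   permutations to within-stratum shuffles (e.g. region).
#' @param n_perm Number of permutations (>= 19).
#' @param statistic `"first"` (first eigenvalue, default) or `"trace"`.
#' @param seed Integer seed.
#' @return Tibble: `statistic`, `p_community`, `p_species`, `p_max`,
#'   `n_perm`.
#' @export
max_test <- function(Y, traits, env, covariates = NULL, strata = NULL,
                     n_perm = 999, statistic = c("first", "trace"), seed = 1L) {
  statistic <- match.arg(statistic)
  if (n_perm < 19) abort_bad("n_perm must be at least 19")
  pr <- dcca_prepare(Y, traits, env, covariates)
  eg <- dcca_eigen(pr$X, pr$Q, pr$W)
  obs <- dcca_statistic(eg$d, statistic)
  n <- length(pr$ca$r)
  perm_index <- function() {
    if (is.null(strata)) return(sample.int(n))
    idx <- seq_len(n)
    for (s in unique(strata)) {
      grp <- which(strata == s)
      idx[grp] <- grp[sample.int(length(grp))]
    }
    idx
  }
  QW <- pr$Q %*% pr$W
  Gw <- inv_sqrt(crossprod(pr$W), "trait matrix")
  XtQ <- crossprod(pr$X, pr$Q)
  Gx <- inv_sqrt(crossprod(pr$X), "predictor matrix")
  Es <- as.matrix(pr$E)
  stat_comm <- with_seed(sub_seed(seed, "community"), vapply(seq_len(n_perm), function(i) {
    Xp <- w_standardize_matrix(Es[perm_index(), , drop = FALSE], pr$ca$r) * sqrt(pr$ca$r)
    if (!is.null(pr$proj_out)) Xp <- pr$proj_out(Xp)
    Gxp <- inv_sqrt(crossprod(Xp), "predictor matrix")
    dcca_statistic(svd(Gxp %*% crossprod(Xp, QW) %*% Gw)$d, statistic)
  }, numeric(1)))
  m <- length(pr$ca$c)
  Ts <- as.matrix(pr$TT)
  stat_spec <- with_seed(sub_seed(seed, "species"), vapply(seq_len(n_perm), function(i) {
    Wp <- w_standardize_matrix(Ts[sample.int(m), , drop = FALSE], pr$ca$c) * sqrt(pr$ca$c)
    Gwp <- inv_sqrt(crossprod(Wp), "trait matrix")
    dcca_statistic(svd(Gx %*% (XtQ %*% Wp) %*% Gwp)$d, statistic)
  }, numeric(1)))
  p_comm <- (1 + sum(stat_comm >= obs)) / (n_perm + 1)
  p_spec <- (1 + sum(stat_spec >= obs)) / (n_perm + 1)
  tibble(statistic = obs, p_community = p_comm, p_species = p_spec,
         p_max = max(p_comm, p_spec), n_perm = n_perm)
}

# Model matrices for the screening terms: traits (syndrome one-hot with the
# abiotic level as reference to keep full rank), predictors per scale.
dcca_trait_matrix <- function(traits) {
  tv <- trait_value_table(traits)
  keep <- complete.cases(tv[c(continuous_traits(), syndrome_levels())])
  tv <- tv[keep, ]
  M <- as.matrix(tv[c(continuous_traits(), "endozoochory", "synzoochory")])
  rownames(M) <- tv$species_id
  M
}

dcca_env_table <- function(data, scale) {
  data$landscape |>
    filter(.data$scale == !!scale) |>
    transmute(plot_id = .data$plot_id,
              forest_loss = log1p(.data$forest_loss),
              n_patches = log1p(.data$n_patches),
              edge_density = .data$edge_density) |>
    inner_join(data$plots[c("plot_id", "region_id", "degradation")], by = "plot_id")
}

#' Screen disturbance terms with dc-CA under Bonferroni correction
#'
#' Tests each landscape variable at each buffer scale with the max test,
#' with the region factor as covariate throughout, following the same
#' conditioning sequence as the causal models: forest loss marginally,
#' fragmentation given forest loss, edge density given both, local
#' degradation given all three landscape variables at the same scale.
#' P values are Bonferroni-adjusted across all screened terms, and terms
#' are ranked by the explained fourth-corner variance of their marginal
#' analysis.
#'
#' @param data A `ts_data` list.
#' @param scales Buffer scales to screen (default: all).
#' @param alpha Familywise significance level.
#' @param n_perm Permutations per max test.
#' @param statistic Test statistic, see [max_test()].
#' @param seed Integer seed.
#' @return Tibble: term, scale, conditioning, eigenvalue, p_community,
#'   p_species, p_max, p_adj, significant, ordered by eigenvalue.
#' @export
dcca_term_screen <- function(data, scales = NULL, alpha = 0.05, n_perm = 999,
                             statistic = "first", seed = 1L) {
  scales <- scales %||% sort(unique(data$landscape$scale))
  TM <- dcca_trait_matrix(data$traits)
  ab <- data$abundance |> filter(.data$species_id %in% rownames(TM))
  Y <- abundance_matrix(ab)
  Y <- Y[rowSums(Y) > 0, colnames(Y)[colSums(Y) > 0], drop = FALSE]
  TM <- TM[colnames(Y), , drop = FALSE]
  plot_ids <- rownames(Y)
  region <- data$plots$region_id[match(plot_ids, data$plots$plot_id)]
  multi_region <- length(unique(region)) > 1
  Zr <- if (multi_region) model.matrix(~region)[, -1, drop = FALSE] else NULL
  strata <- if (multi_region) region else NULL
  seq_terms <- list(
    forest_loss = character(0),
    n_patches = "forest_loss",
    edge_density = c("forest_loss", "n_patches"),
    degradation = c("forest_loss", "n_patches", "edge_density")
  )
  rows <- list()
  for (s in scales) {
    envt <- dcca_env_table(data, s)
    envt <- envt[match(plot_ids, envt$plot_id), ]
    for (term in names(seq_terms)) {
      cond <- seq_terms[[term]]
      E1 <- as.matrix(envt[term])
      Z <- cbind(Zr, as.matrix(envt[cond]))
      if (is.null(Z) || ncol(Z) == 0) Z <- NULL
      mt <- max_test(
        Y, TM, E1, covariates = Z, strata = strata, n_perm = n_perm,
        statistic = statistic, seed = sub_seed(seed, paste("mt", term, s)))
      rows[[length(rows) + 1L]] <- tibble(
        term = term, scale = s,
        conditioning = paste(c(if (multi_region) "region", cond), collapse = "+"),
        eigenvalue = mt$statistic, p_community = mt$p_community,
        p_species = mt$p_species, p_max = mt$p_max)
    }
  }
  out <- bind_rows(rows)
  out |>
    mutate(p_adj = pmin(1, .data$p_max * nrow(out)),
           significant = .data$p_adj <= alpha) |>
    arrange(desc(.data$eigenvalue))
}
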