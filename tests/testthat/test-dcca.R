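# Double-constrained correspondence analysis and the max permutation test.

rand_Y <- function(n, m, seed, lambda = 3) {
  set.seed(seed)
  Y <- matrix(rpois(n * m, lambda), n, m,
              dimnames = list(paste0("p", seq_len(n)), paste0("s", seq_len(m))))
  Y[rowSums(Y) == 0, 1] <- 1L
  Y[1, colSums(Y) == 0] <- 1L
  Y
}

# Independent oracle: weighted fourth-corner correlation of one trait and
# one predictor, straight from its definition.
fourth_corner_direct <- function(Y, trait, env) {
  ca <- prepare_relative_abundance(Y)
  e <- env - sum(ca$r * env); e <- e / sqrt(sum(ca$r * e^2))
  t <- trait - sum(ca$c * trait); t <- t / sqrt(sum(ca$c * t^2))
  sum(ca$P * outer(e, t))
}

test_that("row normalization and CA weights match their definitions", {
  Y <- rand_Y(10, 8, 1)
  ca <- prepare_relative_abundance(Y)
  expect_equal(unname(rowSums(ca$P / sum(ca$P))), rep(1 / 10, 10) * 10 / 10,
               tolerance = 1e-12)
  expect_equal(unname(rowSums(Y / rowSums(Y))), rep(1, 10), tolerance = 1e-12)
  # Dividing by plot totals equalizes the row weights.
  expect_equal(unname(ca$r), rep(1 / 10, 10), tolerance = 1e-12)
  expect_equal(unname(ca$c), unname(colSums(Y / rowSums(Y)) / 10), tolerance = 1e-12)
  # Multiplying one plot's counts by 10 changes nothing.
  Y2 <- Y; Y2[3, ] <- Y2[3, ] * 10L
  expect_equal(prepare_relative_abundance(Y2)$Q, ca$Q, tolerance = 1e-12)
  # Empty rows and columns are named errors.
  Y3 <- Y; Y3[2, ] <- 0L
  expect_error(prepare_relative_abundance(Y3), "empty plot")
  Y4 <- Y; Y4[, 5] <- 0L
  expect_error(prepare_relative_abundance(Y4), "empty species")
})

test_that("single trait and predictor reduce to the direct fourth corner", {
  for (seed in 1:5) {
    Y <- rand_Y(12, 9, seed)
    set.seed(seed + 100)
    tr <- matrix(rnorm(9), 9, dimnames = list(colnames(Y), "t"))
    en <- matrix(rnorm(12), 12, dimnames = list(rownames(Y), "e"))
    fit <- fit_dcca(Y, tr, en)
    r4 <- fourth_corner_direct(Y, tr[, 1], en[, 1])
    expect_equal(fit$eigenvalues[1], r4^2, tolerance = 1e-8)
  }
})

test_that("eigenvalues are squared correlations in [0, 1], non-increasing", {
  Y <- rand_Y(20, 15, 2)
  set.seed(3)
  tr <- matrix(rnorm(15 * 3), 15, 3, dimnames = list(colnames(Y), paste0("t", 1:3)))
  en <- matrix(rnorm(20 * 2), 20, 2, dimnames = list(rownames(Y), paste0("e", 1:2)))
  fit <- fit_dcca(Y, tr, en)
  expect_true(all(fit$eigenvalues >= 0 & fit$eigenvalues <= 1))
  expect_true(all(diff(fit$eigenvalues) <= 1e-12))
  expect_equal(fit$eigenvalues, fit$fourth_corner^2, tolerance = 1e-12)
})

test_that("site composites have unit weighted variance and are orthogonal", {
  Y <- rand_Y(25, 18, 4)
  set.seed(5)
  tr <- matrix(rnorm(18 * 3), 18, 3, dimnames = list(colnames(Y), paste0("t", 1:3)))
  en <- matrix(rnorm(25 * 2), 25, 2, dimnames = list(rownames(Y), paste0("e", 1:2)))
  fit <- fit_dcca(Y, tr, en)
  G <- t(fit$site_scores) %*% (fit$row_weights * fit$site_scores)
  expect_equal(unname(G), diag(ncol(G)), tolerance = 1e-10)
  Gt <- t(fit$species_scores) %*% (fit$col_weights * fit$species_scores)
  expect_equal(unname(Gt), diag(ncol(Gt)), tolerance = 1e-10)
})

test_that("eigenvalues match a brute-force search over composite pairs", {
  Y <- rand_Y(8, 6, 6, lambda = 4)
  set.seed(7)
  tr <- matrix(rnorm(6 * 2), 6, 2, dimnames = list(colnames(Y), c("t1", "t2")))
  en <- matrix(rnorm(8 * 2), 8, 2, dimnames = list(rownames(Y), c("e1", "e2")))
  fit <- fit_dcca(Y, tr, en)
  # Grid search over unit-variance linear combinations on both sides.
  best <- 0
  for (a in seq(0, pi, length.out = 721)) {
    for (b in seq(0, pi, length.out = 181)) {
      ec <- cos(a) * en[, 1] + sin(a) * en[, 2]
      tc <- cos(b) * tr[, 1] + sin(b) * tr[, 2]
      best <- max(best, fourth_corner_direct(Y, tc, ec)^2)
    }
  }
  expect_equal(fit$eigenvalues[1], best, tolerance = 1e-3)
})

test_that("unconstrained species side matches canonical correspondence analysis", {
  skip_if_not_installed("vegan")
  Y <- rand_Y(12, 6, 8, lambda = 4)
  TI <- diag(6)[, -6]
  dimnames(TI) <- list(colnames(Y), paste0("d", 1:5))
  set.seed(9)
  en <- matrix(rnorm(12 * 2), 12, 2, dimnames = list(rownames(Y), c("e1", "e2")))
  fit <- fit_dcca(Y, TI, en)
  cc <- vegan::cca(Y / rowSums(Y) ~ e1 + e2, data = as.data.frame(en))
  expect_equal(unname(fit$eigenvalues), unname(cc$CCA$eig), tolerance = 1e-10)
})

test_that("planted one-dimensional association is recovered by the loadings", {
  set.seed(10)
  n <- 40; m <- 60
  env <- matrix(rnorm(n * 2), n, 2, dimnames = list(paste0("p", 1:n), c("e1", "e2")))
  tr <- matrix(rnorm(m * 3), m, 3, dimnames = list(paste0("s", 1:m), paste0("t", 1:3)))
  # Abundance driven by the product of trait 1 and predictor 1 only.
  lam <- exp(1 + 0.8 * outer(env[, 1], tr[, 1]))
  Y <- matrix(rpois(n * m, lam), n, m, dimnames = dimnames(lam))
  Y[rowSums(Y) == 0, 1] <- 1L
  Y <- Y[, colSums(Y) > 0]
  fit <- fit_dcca(Y, tr[colnames(Y), ], env)
  ec <- abs(fit$env_cor[, 1]); tc <- abs(fit$trait_cor[, 1])
  expect_gt(ec["e1"], 0.95)
  expect_gt(tc["t1"], 0.95)
  expect_gt(fit$eigenvalues[1], 5 * fit$eigenvalues[2])
})

test_that("collinear inputs raise a named condition-number error", {
  Y <- rand_Y(10, 8, 11)
  tr <- matrix(rnorm(8), 8, dimnames = list(colnames(Y), "t"))
  en <- matrix(rnorm(10), 10, 1, dimnames = list(rownames(Y), "e1"))
  en2 <- cbind(en, e2 = 2 * en[, 1])
  expect_error(fit_dcca(Y, tr, en2), "collinear")
})

test_that("max test saturates under strong association and bounds components", {
  set.seed(12)
  n <- 30; m <- 40
  env <- matrix(rnorm(n), n, 1, dimnames = list(paste0("p", 1:n), "e"))
  tr <- matrix(rnorm(m), m, 1, dimnames = list(paste0("s", 1:m), "t"))
  lam <- exp(1.5 + 1.2 * outer(env[, 1], tr[, 1]))
  Y <- matrix(rpois(n * m, lam), n, m, dimnames = dimnames(lam))
  Y[rowSums(Y) == 0, 1] <- 1L; Y <- Y[, colSums(Y) > 0]
  mt <- max_test(Y, tr[colnames(Y), , drop = FALSE], env, n_perm = 99, seed = 1)
  expect_equal(mt$p_max, 1 / 100)
  expect_gte(mt$p_max, mt$p_community)
  expect_gte(mt$p_max, mt$p_species)
  expect_error(max_test(Y, tr[colnames(Y), , drop = FALSE], env, n_perm = 9),
               "at least 19")
})

test_that("max test is invariant to species relabelling", {
  Y <- rand_Y(15, 12, 13)
  set.seed(14)
  tr <- matrix(rnorm(12), 12, dimnames = list(colnames(Y), "t"))
  en <- matrix(rnorm(15), 15, dimnames = list(rownames(Y), "e"))
  mt1 <- max_test(Y, tr, en, n_perm = 49, seed = 5)
  perm <- sample(ncol(Y))
  mt2 <- max_test(Y[, perm], tr[perm, , drop = FALSE], en, n_perm = 49, seed = 5)
  expect_equal(mt1$statistic, mt2$statistic, tolerance = 1e-12)
  expect_equal(mt1$p_community, mt2$p_community)
})

test_that("confounding through a stratum is absorbed by within-stratum permutation", {
  hits <- vapply(1:10, function(s) {
    set.seed(s)
    n <- 40; m <- 30
    region <- rep(c("A", "B"), each = n / 2)
    # Env and community composition both differ by region, but within regions
    # the association is null.
    env <- matrix(rnorm(n) + ifelse(region == "A", -1.5, 1.5), n, 1,
                  dimnames = list(paste0("p", 1:n), "e"))
    tr <- matrix(rnorm(m), m, 1, dimnames = list(paste0("s", 1:m), "t"))
    lam <- exp(1 + 0.8 * outer(ifelse(region == "A", -1, 1), tr[, 1]))
    Y <- matrix(rpois(n * m, lam), n, m,
                dimnames = list(rownames(env), rownames(tr)))
    Y[rowSums(Y) == 0, 1] <- 1L
    Y <- Y[, colSums(Y) > 0]
    Z <- cbind(regionB = as.numeric(region == "B"))
    mt <- max_test(Y, tr[colnames(Y), , drop = FALSE], env, covariates = Z,
                   strata = region, n_perm = 99, seed = s)
    mt$p_max > 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("term screening ranks the generative driver first and adjusts p", {
  cfg <- small_config(seed = 15, plots_per_region = 30, n_species_pool = 150)
  d <- suppressMessages(as_community_data(simulate_scenario(cfg)))
  sc <- dcca_term_screen(d, scales = 2000, n_perm = 99, seed = 15)
  expect_equal(nrow(sc), 4)
  expect_equal(sc$term[1], "forest_loss")
  expect_true(sc$significant[sc$term == "forest_loss"])
  expect_equal(sc$p_adj, pmin(1, sc$p_max * nrow(sc)))
  # Conditional fragmentation and edge terms carry no signal of their own.
  expect_false(any(sc$significant[sc$term %in% c("n_patches", "edge_density")]))
})

test_that("a duplicated conditional term contributes nothing", {
  Y <- rand_Y(20, 15, 16)
  set.seed(17)
  tr <- matrix(rnorm(15), 15, dimnames = list(colnames(Y), "t"))
  e1 <- rnorm(20)
  env <- matrix(e1, 20, dimnames = list(rownames(Y), "e"))
  # Condition on the same variable that is being tested.
  mt <- max_test(Y, tr, env, covariates = cbind(z = e1), n_perm = 49, seed = 6)
  expect_equal(mt$statistic, 0)
  expect_equal(mt$p_max, 1)
})

test_that("tidy, glance and autoplot work on dc-CA fits", {
  Y <- rand_Y(15, 10, 18)
  set.seed(19)
  tr <- matrix(rnorm(10 * 2), 10, 2, dimnames = list(colnames(Y), c("t1", "t2")))
  en <- matrix(rnorm(15 * 2), 15, 2, dimnames = list(rownames(Y), c("e1", "e2")))
  fit <- fit_dcca(Y, tr, en)
  td <- tidy(fit)
  expect_true(all(c("term", "axis", "weight", "side", "eigenvalue") %in% names(td)))
  gl <- glance(fit)
  expect_equal(gl$eigenvalue_1, fit$eigenvalues[1])
  expect_s3_class(autoplot(fit), "ggplot")
})
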