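# Moran's eigenvector maps: spatial predictors built from graph-based
# connectivity among plots, used to absorb residual spatial autocorrelation
# in the causal models.

#' Gabriel-graph adjacency
#'
#' Two plots are Gabriel neighbours when no third plot falls inside the
#' circle whose diameter is the segment joining them.
#'
#' @param coords Two-column matrix/data frame of plot coordinates (m).
#' @return Symmetric logical adjacency matrix.
#' @export
gabriel_graph <- function(coords) {
  xy <- as.matrix(coords)
  n <- nrow(xy)
  D2 <- as.matrix(dist(xy))^2
  A <- matrix(FALSE, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      # Inside the diametral circle iff d(i,k)^2 + d(j,k)^2 < d(i,j)^2.
      ok <- all(D2[i, -c(i, j)] + D2[j, -c(i, j)] >= D2[i, j] - 1e-12)
      A[i, j] <- A[j, i] <- ok
    }
  }
  A
}

#' Minimum-spanning-tree adjacency
#'
#' @inheritParams gabriel_graph
#' @return Symmetric logical adjacency matrix (via [ape::mst()]).
#' @export
mst_graph <- function(coords) {
  m <- unclass(ape::mst(dist(as.matrix(coords))))
  A <- (m + t(m)) > 0
  diag(A) <- FALSE
  A
}

#' Spatial weighting matrix
#'
#' Combines a connectivity graph (Gabriel or minimum spanning tree) with an
#' edge weighting: binary, or decreasing linearly with distance
#' (`1 - d/max(d)` over connected pairs).
#'
#' @inheritParams gabriel_graph
#' @param graph `"gabriel"` or `"mst"`.
#' @param weighting `"binary"` or `"linear"`.
#' @return Symmetric numeric weight matrix with zero diagonal.
#' @export
spatial_weights <- function(coords, graph = c("gabriel", "mst"),
                            weighting = c("binary", "linear")) {
  graph <- match.arg(graph)
  weighting <- match.arg(weighting)
  xy <- as.matrix(coords)
  if (anyDuplicated(xy)) {
    abort_bad(paste("duplicate plot coordinates; spatial weights are undefined.",
                    "Resolve or drop collocated plots before spatial filtering"))
  }
  A <- switch(graph, gabriel = gabriel_graph(xy), mst = mst_graph(xy))
  W <- A * 1
  if (weighting == "linear") {
    D <- as.matrix(dist(xy))
    dmax <- max(D[A])
    W <- ifelse(A, 1 - D / dmax, 0)
    # Keep the farthest linked pair connected with a small positive weight.
    W[A & W <= 0] <- 1e-8
  }
  W
}

#' Moran's I
#'
#' @param x Numeric vector over plots.
#' @param W Spatial weight matrix.
#' @return Scalar Moran's I.
#' @export
moran_i <- function(x, W) {
  z <- x - mean(x)
  n <- length(z)
  (n / sum(W)) * drop(z %*% W %*% z) / sum(z^2)
}

#' Permutation test for positive spatial autocorrelation
#'
#' One-sided (greater) permutation test of Moran's I.
#'
#' @inheritParams moran_i
#' @param n_perm Number of permutations.
#' @param seed Integer seed.
#' @return List with `observed`, `p_value`.
#' @export
moran_test <- function(x, W, n_perm = 199, seed = 1L) {
  obs <- moran_i(x, W)
  z <- x - mean(x)
  denom <- sum(z^2)
  cst <- length(z) / sum(W)
  perms <- with_seed(seed, vapply(seq_len(n_perm), function(i) {
    zp <- z[sample.int(length(z))]
    cst * drop(zp %*% W %*% zp) / denom
  }, numeric(1)))
  list(observed = obs, p_value = (1 + sum(perms >= obs)) / (n_perm + 1))
}

#' Moran's eigenvector map basis
#'
#' Eigenvectors of the doubly centered spatial weighting matrix with
#' positive eigenvalues (positive spatial autocorrelation), ordered by
#' decreasing Moran's I.
#'
#' @param W Spatial weight matrix.
#' @param id Label carried through candidate comparison.
#' @return A `ts_mem` list: `vectors` (plots x k), `values`, `moran`, `W`,
#'   `id`.
#' @export
mem_basis <- function(W, id = "mem") {
  n <- nrow(W)
  H <- diag(n) - matrix(1 / n, n, n)
  E <- eigen(H %*% W %*% H, symmetric = TRUE)
  keep <- E$values > max(E$values) * 1e-9
  vec <- E$vectors[, keep, drop = FALSE]
  mor <- apply(vec, 2, moran_i, W = W)
  o <- order(mor, decreasing = TRUE)
  structure(list(vectors = vec[, o, drop = FALSE], values = E$values[keep][o],
                 moran = mor[o], W = W, id = id), class = "ts_mem")
}

#' Build the four candidate spatial bases
#'
#' The candidates cross two connectivity graphs (Gabriel, minimum spanning
#' tree) with two weightings (binary, linear distance decay).
#'
#' @inheritParams gabriel_graph
#' @return Named list of four `ts_mem` objects.
#' @export
build_spatial_candidates <- function(coords) {
  xy <- as.matrix(coords)
  if (nrow(xy) < 4) abort_bad("need at least 4 plots to build spatial candidates")
  combos <- expand_grid(graph = c("gabriel", "mst"), weighting = c("binary", "linear"))
  out <- pmap(combos, function(graph, weighting) {
    mem_basis(spatial_weights(xy, graph, weighting),
              id = paste(graph, weighting, sep = "_"))
  })
  set_names(out, paste(combos$graph, combos$weighting, sep = "_"))
}

#' Select a spatial filter for model residuals
#'
#' Implements the candidate-comparison recipe: test the residuals of the
#' unfiltered model for positive spatial autocorrelation under each of the
#' four candidate weighting matrices (Sidak-corrected across candidates); if
#' none is significant no filter is used.  Otherwise, within each
#' significant candidate, eigenvectors are added greedily (largest absolute
#' correlation with the current residuals first) until residual Moran's I is
#' no longer significant, and the candidate needing the fewest eigenvectors
#' wins.
#'
#' @param residuals Residuals of the unfiltered model.
#' @param candidates List of `ts_mem` objects (see
#'   [build_spatial_candidates()]).
#' @param alpha Significance level (applied after Sidak correction).
#' @param n_perm Permutations per Moran test.
#' @param seed Integer seed.
#' @param max_vectors Cap on selected eigenvectors.
#' @return A `ts_spatial_filter` list: `selected` (matrix of chosen
#'   eigenvectors or `NULL`), `candidate`, `n_vectors`, `trail` (tibble of
#'   every test performed).
#' @export
select_spatial_filter <- function(residuals, candidates, alpha = 0.05,
                                  n_perm = 199, seed = 1L, max_vectors = NULL) {
  m <- length(candidates)
  trail <- imap(candidates, function(cand, nm) {
    tst <- moran_test(residuals, cand$W, n_perm = n_perm,
                      seed = sub_seed(seed, paste0("global_", nm)))
    tibble(candidate = nm, stage = "global", n_vectors = 0L,
           moran = tst$observed, p_raw = tst$p_value,
           p_adj = 1 - (1 - tst$p_value)^m)
  }) |> list_rbind()
  sig <- trail |> filter(.data$p_adj <= alpha)
  if (!nrow(sig)) {
    return(structure(list(selected = NULL, candidate = NA_character_,
                          n_vectors = 0L, trail = trail),
                     class = "ts_spatial_filter"))
  }
  best <- NULL
  for (nm in sig$candidate) {
    cand <- candidates[[nm]]
    k_max <- min(max_vectors %||% ncol(cand$vectors), ncol(cand$vectors))
    res <- residuals
    chosen <- integer(0)
    for (k in seq_len(k_max)) {
      avail <- setdiff(seq_len(ncol(cand$vectors)), chosen)
      sc <- abs(drop(crossprod(cand$vectors[, avail, drop = FALSE],
                               res - mean(res))))
      pick <- avail[which.max(sc)]
      chosen <- c(chosen, pick)
      V <- cand$vectors[, chosen, drop = FALSE]
      res <- resid(lm(residuals ~ V))
      tst <- moran_test(res, cand$W, n_perm = n_perm,
                        seed = sub_seed(seed, paste0("fwd_", nm, "_", k)))
      trail <- bind_rows(trail, tibble(candidate = nm, stage = "forward",
                                       n_vectors = k, moran = tst$observed,
                                       p_raw = tst$p_value, p_adj = tst$p_value))
      if (tst$p_value > alpha) break
    }
    if (is.null(best) || length(chosen) < best$n_vectors) {
      best <- list(candidate = nm, n_vectors = length(chosen),
                   selected = cand$vectors[, chosen, drop = FALSE])
    }
  }
  structure(c(best[c("selected", "candidate", "n_vectors")], list(trail = trail)),
            class = "ts_spatial_filter")
}

#' @export
print.ts_spatial_filter <- function(x, ...) {
  if (is.null(x$selected)) {
    cat("<ts_spatial_filter> no residual spatial autocorrelation detected\n")
  } else {
    cat(sprintf("<ts_spatial_filter> %s, %d eigenvector(s)\n",
                x$candidate, x$n_vectors))
  }
  invisible(x)
}
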