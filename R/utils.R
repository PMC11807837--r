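# Internal helpers shared across modules.

# Derive a reproducible child seed from a base seed and a stream label.
# Keeps results stable when stages are re-run in isolation: each stage of the
# generator and each species in the null model owns its own stream.
sub_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  M <- 2147483587
  h <- 0
  for (ch in utf8ToInt(as.character(stream))) h <- (h * 131 + ch) %% M
  # Both terms stay far below 2^53, so the modular arithmetic is exact.
  as.integer(((abs(seed) %% M) * 48271 + h * 7919) %% M) + 1L
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Weighted mean/sd/cor in a probability-weight metric (weights sum to 1).
w_mean <- function(x, w) sum(w * x)
w_center <- function(x, w) x - w_mean(x, w)
w_sd <- function(x, w) sqrt(sum(w * w_center(x, w)^2))
w_cor <- function(x, y, w) {
  xc <- w_center(x, w); yc <- w_center(y, w)
  sum(w * xc * yc) / sqrt(sum(w * xc^2) * sum(w * yc^2))
}

`%just%` <- function(x, nm) x[intersect(names(x), nm)]

abort_bad <- function(msg, ...) abort(sprintf(msg, ...), class = "traitshift_error")

assert_cols <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss)) {
    abort_bad("%s is missing required column(s): %s", what, paste(miss, collapse = ", "))
  }
  invisible(df)
}

# Long (plot_id, species_id, count) -> plots x species integer matrix.
abundance_matrix <- function(abundance, plots = NULL) {
  assert_cols(abundance, c("plot_id", "species_id", "count"), "abundance table")
  wide <- abundance |>
    pivot_wider(id_cols = "plot_id", names_from = "species_id",
                values_from = "count", values_fill = 0L, names_sort = TRUE)
  m <- as.matrix(wide[, -1, drop = FALSE])
  rownames(m) <- wide$plot_id
  if (!is.null(plots)) {
    missing_plots <- setdiff(plots$plot_id, rownames(m))
    if (length(missing_plots)) {
      pad <- matrix(0L, length(missing_plots), ncol(m),
                    dimnames = list(missing_plots, colnames(m)))
      m <- rbind(m, pad)
    }
    m <- m[as.character(plots$plot_id), , drop = FALSE]
  }
  storage.mode(m) <- "double"
  m
}
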