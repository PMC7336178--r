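## Internal helpers: argument checks, seed management, small numerics.

stop_invalid <- function(...) {
  stop(errorCondition(paste0(...), class = c("saxscan_invalid_argument", "error")))
}

check_scalar_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
    stop_invalid("`", name, "` must be a single positive finite number")
  invisible(x)
}

## Evaluate `expr` under a temporary RNG state seeded with `seed`; the
## caller's RNG state is untouched.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop_invalid("`seed` must be a single integer")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

## Deterministic fan-out of one user seed into per-task substreams.
## Keeps results below 2^31 so set.seed() accepts them.
derive_seed <- function(seed, counter) {
  as.integer((as.double(seed) %% 2147483647 * 48271 + counter) %% 2147483629) + 1L
}

## Raster (row-major) linear index of matrix cells, used for deterministic
## labeling order.
raster_order <- function(rows, cols, n_cols) {
  (rows - 1) * n_cols + cols
}
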