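# Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores the caller's RNG state so that seeded package internals
#' never perturb user-level random streams.
#' @noRd
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }, add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

# Derive a child seed from a parent seed and a stage offset, kept inside the
# 32-bit integer range R requires of set.seed().
child_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 7919 + offset) %% 2147483629)
}

stopifnot_scalar <- function(x, name = deparse(substitute(x))) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  }
  invisible(x)
}

# index of the nearest value in a sorted grid, ties toward the lower index
nearest_grid_index <- function(x, grid) {
  i <- findInterval(x, grid, all.inside = TRUE)
  lo <- grid[i]; hi <- grid[i + 1L]
  ifelse(x - lo <= hi - x, i, i + 1L)
}

fmt_pct <- function(x) sprintf("%.1f%%", 100 * x)
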