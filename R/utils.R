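# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a temporary RNG seed
#'
#' Runs `expr` with the global RNG seeded to `seed`, then restores the
#' previous RNG state, so simulations are reproducible without disturbing
#' the caller's random stream.
#'
#' @param seed single integer seed.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a per-stage seed from a global seed and a stage counter, kept
# within 32-bit integer range.
derive_seed <- function(seed, stage_index) {
  as.integer((as.numeric(seed) + 1000003 * as.numeric(stage_index)) %%
    (.Machine$integer.max - 1L)) + 1L
}

stop_if_not_scalar_number <- function(x, name, min = -Inf, strict_min = NULL) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  }
  if (!is.null(strict_min) && x <= strict_min) {
    stop(sprintf("`%s` must be > %g", name, strict_min), call. = FALSE)
  }
  if (x < min) {
    stop(sprintf("`%s` must be >= %g", name, min), call. = FALSE)
  }
  invisible(x)
}

#' Rand index between two partitions
#'
#' Fraction of object pairs on which two clusterings agree (both together or
#' both apart). Used to quantify recovery of planted cluster structure.
#'
#' @param a,b cluster label vectors of equal length.
#' @return Rand index in \[0, 1\].
#' @examples
#' rand_index(c(1, 1, 2, 2), c(2, 2, 1, 1)) # 1: identical partitions
#' @export
rand_index <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 2)
  n <- length(a)
  same_a <- outer(a, a, "==")
  same_b <- outer(b, b, "==")
  idx <- upper.tri(same_a)
  mean(same_a[idx] == same_b[idx])
}
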