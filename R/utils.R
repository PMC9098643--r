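#' Derive a reproducible sub-stream seed
#'
#' All randomness in the package flows from a single master seed. Components
#' (solver initialization, down-sampling, noise, replicates) draw their own
#' seeds through named sub-streams so that they can be re-seeded independently
#' without disturbing each other.
#'
#' @param seed Master integer seed.
#' @param stream Character label of the sub-stream (e.g. `"solver-init"`).
#' @return An integer seed in `[0, 2^31 - 1)`.
#' @export
derive_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stream))
  codes <- utf8ToInt(stream)
  h <- sum(codes * seq_along(codes))
  as.integer((abs(as.numeric(seed)) * 7919 + h * 104729 + 17) %% 2147483647)
}

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a

# Consistent symmetric pair enumeration: all unordered (i, j), i < j, 1-based.
#' @keywords internal
upper_pairs <- function(n) {
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE]
}
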