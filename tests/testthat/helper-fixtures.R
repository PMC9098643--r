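# Shared fixtures, built in code at test time.

# Complete squared-distance matrix of a benchmark curve.
complete_sqdist <- function(n = 60, kind = "loop", seed = 1L,
                            resolution = 5000L) {
  s <- generate_benchmark(n, kind = kind, seed = seed,
                          resolution = resolution)
  list(truth = s, D = sq_edm_from_structure(s),
       d = sqdist_matrix(sq_edm_from_structure(s), resolution = resolution))
}

# Small symmetric positive contact map as a data.frame-based fixture.
random_contact_map <- function(n = 20, seed = 1L, resolution = 5000L) {
  set.seed(seed)
  A <- matrix(stats::runif(n * n, 0.2, 3), n)
  A <- (A + t(A)) / 2
  diag(A) <- 0
  idx <- which(upper.tri(A), arr.ind = TRUE)
  contact_map(data.frame(i = idx[, 1] - 1L, j = idx[, 2] - 1L,
                         value = A[idx]),
              n_bins = n, resolution = resolution)
}

random_rotation <- function(seed = 1L) {
  set.seed(seed)
  qr_dec <- qr(matrix(stats::rnorm(9), 3))
  Q <- qr.Q(qr_dec)
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

expect_edm_equal <- function(a, b, tolerance = 1e-6) {
  expect_equal(sq_edm_from_structure(a), sq_edm_from_structure(b),
               tolerance = tolerance)
}
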