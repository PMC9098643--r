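test_that("the accessibility regression recovers planted coefficients exactly", {
  n <- 40
  set.seed(31)
  S <- stats::runif(n, 0.5, 3)
  G <- abs(outer(1:n, 1:n, "-")) * 5000
  D <- -0.3 * outer(S, rep(1, n)) - 0.3 * outer(rep(1, n), S) +
    0.01 * G / 5000 * 5000 * 1e-3 + 60
  D <- (D + t(D)) / 2
  diag(D) <- 0
  msk <- matrix(TRUE, n, n); diag(msk) <- FALSE
  d <- sqdist_matrix(D, msk, 5000L)
  fit <- suppressWarnings(
    fit_distance_regression(d, signal_track(S, 5000L)))
  expect_equal(fit$alpha1, -0.3, tolerance = 1e-8)
  expect_equal(fit$alpha2, fit$alpha1)
  expect_equal(fit$alpha3 * 5000, 0.01 * 5, tolerance = 1e-8)
  expect_equal(fit$intercept, 60, tolerance = 1e-6)

  # degenerate designs are rejected by name
  expect_error(fit_distance_regression(d, signal_track(rep(1, n), 5000L)),
               "S_i \\+ S_j")
})

test_that("regression estimates are unbiased under Gaussian noise", {
  n <- 30
  set.seed(32)
  S <- stats::runif(n, 0.5, 3)
  G <- abs(outer(1:n, 1:n, "-"))
  base <- -0.4 * outer(S, rep(1, n)) - 0.4 * outer(rep(1, n), S) +
    0.2 * G + 40
  msk <- matrix(TRUE, n, n); diag(msk) <- FALSE
  est <- replicate(200, {
    E <- matrix(stats::rnorm(n * n, sd = 0.5), n)
    E <- (E + t(E)) / 2
    D <- base + E; diag(D) <- 0
    fit_distance_regression(sqdist_matrix(D, msk), signal_track(S))$alpha1
  })
  se <- stats::sd(est) / sqrt(length(est))
  expect_lt(abs(mean(est) - (-0.4)), 3 * se + 1e-3)
})

test_that("imputation evaluates the linear form with a positive floor", {
  model <- structure(list(alpha1 = -0.2, alpha2 = -0.2, alpha3 = 2e-5,
                          intercept = 10,
                          fit_stats = list(r_squared = 1, n_pairs = 0)),
                     class = "distance_regression")
  S <- c(1, 2, 0.5, 3)
  e <- impute_distances(model, signal_track(S, 5000L))
  for (pair in list(c(1, 2), c(1, 4), c(2, 3))) {
    i <- pair[1]; j <- pair[2]
    expect_equal(e$values[i, j],
                 10 - 0.2 * S[i] - 0.2 * S[j] + 2e-5 * abs(i - j) * 5000,
                 tolerance = 1e-10)
  }
  # constant signal, positive slope: strictly increasing in separation
  model$alpha3 <- 1e-4
  e2 <- impute_distances(model, signal_track(rep(1, 6), 5000L))
  expect_true(all(diff(e2$values[1, 2:6]) > 0))
  # floor keeps entries positive even when the linear form goes negative
  model$intercept <- -100
  e3 <- impute_distances(model, signal_track(S, 5000L))
  expect_true(all(measured_pairs(e3)$value > 0))
})

test_that("double-centering inverts the EDM map on centered Grams", {
  set.seed(33)
  s <- structure3d(matrix(stats::rnorm(30), 10))
  D <- sq_edm_from_structure(s)
  X <- gram_from_distances(D)
  expect_equal(sq_edm_from_gram(X), D, tolerance = 1e-10)
  expect_equal(X, gram_from_coords(s), tolerance = 1e-10)
  expect_lt(max(abs(rowSums(X))), 1e-10)
  expect_equal(gram_from_distances(matrix(0, 5, 5)), matrix(0, 5, 5))
})

test_that("the integrative solver reduces to the base solver at gamma 0 and tracks E as gamma grows", {
  fx <- complete_sqdist(40, seed = 7)
  din <- downsample_measurements(fx$d, 0.4, seed = 3)
  e_perfect <- sqdist_matrix(fx$D, resolution = 5000L)

  base_cfg <- solver_config(seed = 6)
  f0 <- solve_lowrank(din, base_cfg)
  fi0 <- solve_integrative(din, e_perfect,
                           integrative_config(gamma = 0, base = base_cfg))
  expect_identical(sq_edm_from_structure(f0$structure),
                   sq_edm_from_structure(fi0$structure))

  # with a strong penalty toward a *different* EDM, the solution moves
  # toward that target on the penalized (unmeasured) pairs
  other <- generate_benchmark(40, "helix", seed = 2)
  e_other <- sqdist_matrix(sq_edm_from_structure(other) * 4,
                           resolution = 5000L)
  fg <- solve_integrative(din, e_other,
                          integrative_config(gamma = 50, base = base_cfg))
  R0 <- sq_edm_from_structure(fi0$structure)
  Rg <- sq_edm_from_structure(fg$structure)
  Eo <- e_other$values; diag(Eo) <- 0
  um <- !din$mask & upper.tri(Eo)
  rho0 <- stats::cor(R0[um], Eo[um], method = "spearman")
  rhog <- stats::cor(Rg[um], Eo[um], method = "spearman")
  expect_gt(rhog, rho0)
})

test_that("cross-cell-type imputation pulls the solution toward the target truth", {
  # source and target structures differ; the target's accessibility signal
  # carries the information that distinguishes them
  n <- 50
  src <- generate_benchmark(n, "loop", seed = 1)
  tgt <- generate_benchmark(n, "random-walk", seed = 8)
  D_src <- sq_edm_from_structure(src)
  D_tgt <- sq_edm_from_structure(tgt)
  d_src <- downsample_measurements(
    sqdist_matrix(D_src, resolution = 5000L), 0.3, seed = 5)

  # a signal predictive of the *target* distances: fit the regression on
  # the target truth, then impute from it (emulating DNase transfer)
  set.seed(41)
  S_tgt <- stats::runif(n, 0.5, 3)
  base <- -0.5 * outer(S_tgt, rep(1, n)) - 0.5 * outer(rep(1, n), S_tgt)
  D_mix <- 0.5 * D_tgt + 4 + base - min(base)
  diag(D_mix) <- 0
  msk <- matrix(TRUE, n, n); diag(msk) <- FALSE
  e_tgt <- sqdist_matrix(D_mix, msk, 5000L)

  cfgb <- solver_config(seed = 9)
  source_only <- solve_lowrank(d_src, cfgb)$structure
  integ <- solve_integrative(d_src, e_tgt,
                             integrative_config(gamma = 5,
                                                base = cfgb))$structure
  up <- upper.tri(D_tgt)
  rho_src <- stats::cor(sq_edm_from_structure(source_only)[up], D_tgt[up],
                        method = "spearman")
  rho_int <- stats::cor(sq_edm_from_structure(integ)[up], D_tgt[up],
                        method = "spearman")
  expect_gt(rho_int, rho_src)
})

test_that("fragment splitting replicates parent distances and boosts resolution", {
  # brute-force expansion oracle at factor 2, n_low = 3
  v <- matrix(c(0, 4, 9, 4, 0, 5, 9, 5, 0), 3)
  d_low <- sqdist_matrix(v, resolution = 10000L)
  ex <- expand_sqdist(d_low, 2)
  expect_equal(ex$n, 6L)
  parent <- c(1, 1, 2, 2, 3, 3)
  for (i in 1:6) for (j in 1:6) {
    if (parent[i] == parent[j]) {
      expect_false(ex$mask[i, j])
    } else {
      expect_true(ex$mask[i, j])
      expect_equal(ex$values[i, j], v[parent[i], parent[j]])
    }
  }
  expect_equal(ex$resolution, 5000L)

  # factor 1 is the identity expansion
  ex1 <- expand_sqdist(d_low, 1)
  expect_equal(ex1$values, d_low$values)

  # coarsened benchmark boosted back beats the naive replicated matrix
  n_f <- 60
  fine <- generate_benchmark(n_f, "loop", seed = 3)
  D_fine <- sq_edm_from_structure(fine)
  coarse_idx <- seq(1, n_f, by = 2)
  coarse_coords <- (fine$coords[coarse_idx, ] +
                      fine$coords[coarse_idx + 1, ]) / 2
  D_coarse <- sq_edm_from_structure(structure3d(coarse_coords))
  d_low2 <- sqdist_matrix(D_coarse, resolution = 10000L)
  # an informative high-resolution signal built from the fine structure:
  # radial position (arbitrary monotone 1D readout of the geometry)
  S_high <- sqrt(rowSums(scale(fine$coords, scale = FALSE)^2))
  s_high <- signal_track(S_high, 5000L)
  boosted <- suppressWarnings(
    boost_resolution(d_low2, 2, s_high,
                     integrative_config(gamma = 0.5,
                                        base = solver_config(seed = 2))))
  # naive replication: children inherit the parent position outright, so
  # same-parent child pairs sit at squared distance 0
  up <- upper.tri(D_fine)
  parent2 <- (seq_len(n_f) - 1L) %/% 2L + 1L
  naive_vals <- D_coarse[parent2, parent2]
  naive_vals[outer(parent2, parent2, "==")] <- 0
  rho_naive <- stats::cor(naive_vals[up], D_fine[up], method = "spearman")
  rho_boost <- stats::cor(sq_edm_from_structure(boosted)[up], D_fine[up],
                          method = "spearman")
  expect_gt(rho_boost, rho_naive)
  expect_error(boost_resolution(d_low2, 2, signal_track(rep(1, 10)),
                                integrative_config()),
               "factor")
})

test_that("bedGraph signal averaging respects bin boundaries", {
  tmp <- withr::local_tempfile()
  writeLines(c("chr1\t0\t5000\t2",
               "chr1\t5000\t7500\t4",
               "chr1\t12500\t15000\t8"), tmp)
  s <- read_bedgraph(tmp, 5000, n_bins = 3)
  expect_equal(s$values, c(2, 2, 4))   # bin2: 4 over half the bin; bin3: 8 over half
})
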