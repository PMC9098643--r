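test_that("sampling operator and its adjoint satisfy the defining identities", {
  s <- structure3d(rbind(c(0, 0, 0), c(1, 0, 0), c(3, 0, 0)))
  X <- gram_from_coords(s)
  op <- sampling_operator(rbind(c(1, 3)), 3)
  expect_equal(apply_sampling(op, X), 9)            # |0 - 3|^2

  expect_equal(apply_sampling(op, matrix(0, 3, 3)), 0)

  # single omega matrix (pair (1,2), n = 2)
  op2 <- sampling_operator(rbind(c(1, 2)), 2)
  expect_equal(apply_sampling_adjoint(op2, 1),
               matrix(c(1, -1, -1, 1), 2))
  expect_equal(apply_sampling_adjoint(op2, 0), matrix(0, 2, 2))

  # sub-diagonal pairs define the adjacency operator
  B <- subdiagonal_operator(4)
  expect_equal(B$pairs[, 2] - B$pairs[, 1], rep(1L, 3))

  # adjoint identity <A(X), y> = <X, A*(y)> on random inputs
  set.seed(11)
  for (k in 1:5) {
    n <- 8
    pairs <- chromoscaffold:::upper_pairs(n)[sample(28, 12), ]
    opk <- sampling_operator(pairs, n)
    Xr <- tcrossprod(matrix(stats::rnorm(n * 3), n))
    y <- stats::rnorm(12)
    expect_equal(sum(apply_sampling(opk, Xr) * y),
                 sum(Xr * apply_sampling_adjoint(opk, y)),
                 tolerance = 1e-12)
  }

  expect_error(sampling_operator(rbind(c(1, 1)), 3), "self-pairs")
  expect_error(sampling_operator(rbind(c(1, 5)), 3), "out of range")
  expect_error(sampling_operator(rbind(c(1, 2), c(2, 1)), 3), "duplicate")
})

test_that("augmented Lagrangian value and gradient obey plug-in identities", {
  n <- 10
  fx <- complete_sqdist(n, seed = 2)
  mp <- measured_pairs(fx$d)
  op <- sampling_operator(as.matrix(mp[, c("i", "j")]), n)
  b <- mp$value
  cfg <- solver_config(d_t = 1.5)

  # P = 0, Lambda = 0: (lambda/2)(n-1) d_t^2 + (r/2) ||b||^2
  P0 <- matrix(0, n, 3)
  expect_equal(objective_value(P0, op, b, cfg),
               cfg$lambda_pen / 2 * (n - 1) * cfg$d_t^2 +
                 cfg$r_reg / 2 * sum(b^2))
  expect_equal(lagrangian_gradient(P0, op, b, cfg), matrix(0, n, 3))

  # feasible P with adjacent squared distances = d_t: only the trace is left
  seg <- structure3d(cbind(sqrt(1.5) * (seq_len(n) - 1), 0, 0))
  Pf <- scale(seg$coords, center = TRUE, scale = FALSE)
  b_feas <- apply_sampling(op, tcrossprod(Pf))
  expect_equal(objective_value(Pf, op, b_feas, cfg), sum(Pf^2))

  # doubling P quadruples the trace term (lambda = r -> 0 limit via tiny weights)
  cfg0 <- solver_config(lambda_pen = 1e-12, r_reg = 1e-12, d_t = 1.5)
  set.seed(3)
  Pr <- matrix(stats::rnorm(n * 3), n)
  expect_equal(objective_value(2 * Pr, op, b, cfg0) /
                 objective_value(Pr, op, b, cfg0), 4, tolerance = 1e-6)
  expect_equal(lagrangian_gradient(Pr, op, b, cfg0), 2 * Pr,
               tolerance = 1e-6)

  # central-difference check of the full gradient
  cfgA <- solver_config(d_t = 1.2)
  set.seed(4)
  Lam <- stats::rnorm(length(b), sd = 0.1)
  G <- lagrangian_gradient(Pr, op, b, cfgA, Lambda = Lam)
  eps <- 1e-6
  for (k in 1:4) {
    E <- matrix(stats::rnorm(n * 3), n)
    fd <- (objective_value(Pr + eps * E, op, b, cfgA, Lambda = Lam) -
           objective_value(Pr - eps * E, op, b, cfgA, Lambda = Lam)) /
          (2 * eps)
    expect_equal(sum(G * E), fd, tolerance = 1e-4)
  }
})

test_that("noiseless complete inputs are recovered essentially exactly", {
  fx <- complete_sqdist(50, seed = 6)
  fit <- solve_lowrank(fx$d, solver_config(seed = 2))
  expect_lt(relative_error_distances(fit$structure, fx$D), 1e-3)
  expect_lt(fit$state$measured_error, 1e-3)

  # 2-point problem: squared distance 1 between the two points
  d2 <- sqdist_matrix(matrix(c(0, 1, 1, 0), 2),
                      matrix(c(FALSE, TRUE, TRUE, FALSE), 2))
  f2 <- solve_lowrank(d2, solver_config(seed = 1))
  expect_equal(sq_edm_from_structure(f2$structure)[1, 2], 1,
               tolerance = 1e-2)

  empty <- sqdist_matrix(matrix(NA_real_, 3, 3), matrix(FALSE, 3, 3))
  expect_error(suppressWarnings(solve_lowrank(empty)), "empty measurement")
})

test_that("accepted descent steps never increase the augmented Lagrangian", {
  fx <- complete_sqdist(40, seed = 9)
  din <- downsample_measurements(fx$d, 0.5, seed = 3)
  din <- add_noise(din, level = 1, seed = 3)
  fit <- solve_lowrank(din, solver_config(seed = 5))
  h <- fit$state$history
  for (o in unique(h$outer)) {
    obj <- h$objective[h$outer == o]
    if (length(obj) > 1) expect_true(all(diff(obj) <= 1e-8 * abs(obj[-1])))
  }
})

test_that("solutions agree in EDM across seeds and covary with input scale", {
  fx <- complete_sqdist(30, seed = 12)
  f1 <- solve_lowrank(fx$d, solver_config(seed = 1))
  f2 <- solve_lowrank(fx$d, solver_config(seed = 99))
  expect_equal(sq_edm_from_structure(f1$structure),
               sq_edm_from_structure(f2$structure), tolerance = 0.05)

  # scaling squared distances by s^2 scales the recovered EDM by s^2
  s2 <- 9
  d_scaled <- sqdist_matrix(fx$D * s2, resolution = 5000)
  f3 <- solve_lowrank(d_scaled, solver_config(seed = 1))
  expect_equal(sq_edm_from_structure(f3$structure),
               s2 * sq_edm_from_structure(f1$structure), tolerance = 0.05)
})

test_that("reproducibility: identical config gives identical output", {
  fx <- complete_sqdist(25, seed = 3)
  din <- downsample_measurements(fx$d, 0.6, seed = 2)
  f1 <- solve_lowrank(din, solver_config(seed = 8))
  f2 <- solve_lowrank(din, solver_config(seed = 8))
  expect_identical(f1$structure$coords, f2$structure$coords)
})

test_that("d_t grid tuning picks the bracket member nearest the truth", {
  fx <- complete_sqdist(30, seed = 5)
  mp <- measured_pairs(fx$d)
  true_dt <- stats::median(mp$value[mp$j == mp$i + 1L])
  cfg <- solver_config(seed = 2, max_iter = 40)
  sel <- tune_dt(fx$d, cfg, candidates = true_dt * c(0.25, 1, 4))
  expect_equal(as.numeric(sel), true_dt)
  expect_equal(as.numeric(tune_dt(fx$d, cfg, candidates = 2)), 2)
})
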