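test_that("benchmark curve generators produce uniform chains deterministically", {
  h <- generate_benchmark(100, "helix")
  adj <- sqrt(rowSums((h$coords[-1, ] - h$coords[-100, ])^2))
  expect_lt(diff(range(adj)), 1e-9)        # parametric uniformity
  expect_equal(mean(adj), 1)               # common scale

  expect_identical(generate_benchmark(50, "random-walk", seed = 3)$coords,
                   generate_benchmark(50, "random-walk", seed = 3)$coords)

  w <- generate_benchmark(200, "random-walk", seed = 5)
  adj_w <- sqrt(rowSums((w$coords[-1, ] - w$coords[-200, ])^2))
  expect_lt(stats::sd(adj_w) / mean(adj_w), 0.5)

  lp <- generate_benchmark(80, "loop")
  adj_l <- sqrt(rowSums((lp$coords[-1, ] - lp$coords[-80, ])^2))
  expect_lt(max(adj_l) / min(adj_l), 3)    # bounded adjacent steps
  expect_error(generate_benchmark(50, "zigzag"))
})

test_that("the noise protocol shifts by level times delta and stays positive", {
  fx <- complete_sqdist(40, seed = 2)
  din <- downsample_measurements(fx$d, 0.5, seed = 1)
  delta <- min(measured_pairs(din)$value)

  # degenerate sd = 0: exact deterministic shift by delta (level 1)
  sh <- add_noise(din, level = 1, seed = 1, sd = 0)
  expect_equal(measured_pairs(sh)$value,
               measured_pairs(din)$value + delta, tolerance = 1e-12)

  # masks preserved exactly; all outputs positive
  for (lev in 1:2) {
    nz <- add_noise(din, level = lev, seed = 4)
    expect_identical(nz$mask, din$mask)
    expect_true(all(measured_pairs(nz)$value > 0))
  }

  # level-2 mean shift is 2 delta within 3 standard errors
  big <- complete_sqdist(150, seed = 3)
  n2 <- add_noise(big$d, level = 2, seed = 9)
  shift <- measured_pairs(n2)$value - measured_pairs(big$d)$value
  delta_b <- min(measured_pairs(big$d)$value)
  se <- stats::sd(shift) / sqrt(length(shift))
  expect_lt(abs(mean(shift) - 2 * delta_b), 3 * se)
})

test_that("coordinate relative error is invariant to pose and first-order exact", {
  s <- generate_benchmark(60, "loop")
  expect_equal(relative_error_coords(s, s), 0, tolerance = 1e-12)

  R <- random_rotation(4)
  moved <- structure3d(sweep(s$coords %*% R * 3.7, 2, c(1, 2, 3), "+"))
  expect_lt(relative_error_coords(moved, s), 1e-10)

  # small perturbation: ratio tracks eps^2 ||U||^2 / ||truth||^2
  set.seed(13)
  U <- matrix(stats::rnorm(180), 60)
  eps <- 1e-4
  sn <- normalize_structure(s)
  pert <- structure3d(sn$coords + eps * U)
  expected <- eps^2 * sum(U^2) / sum(sn$coords^2)
  expect_equal(relative_error_coords(pert, sn), expected, tolerance = 0.05)
  expect_error(relative_error_coords(generate_benchmark(30, "loop"), s),
               "same number")
})

test_that("distance relative error has the scaling identity and scope handling", {
  fx <- complete_sqdist(50, seed = 5)
  expect_equal(relative_error_distances(fx$truth, fx$D), 0, tolerance = 1e-12)

  eps <- 0.03
  scaled <- structure3d(fx$truth$coords * (1 + eps))
  expect_equal(relative_error_distances(scaled, fx$D), eps^2,
               tolerance = 1e-10)

  # masked reference: error computed over measured pairs only
  din <- downsample_measurements(fx$d, 0.3, seed = 2)
  expect_equal(relative_error_distances(fx$truth, din), 0, tolerance = 1e-12)
})

test_that("Spearman evaluation is exact on perfect input and rank-invariant to eta", {
  # random-walk curve: no parametric symmetries, hence no near-ties whose
  # order a monotone transform could disturb
  fx <- complete_sqdist(45, kind = "random-walk", seed = 6)
  expect_equal(spearman_eval(fx$truth, fx$D), 1)

  # reversed ranks give -1
  rev_vals <- max(fx$D) + 1 - fx$D
  diag(rev_vals) <- 0
  msk <- matrix(TRUE, 45, 45); diag(msk) <- FALSE
  expect_equal(spearman_eval(fx$truth, sqdist_matrix(rev_vals, msk)), -1)

  # monotone distortion of the conversion exponent leaves ranks intact
  for (eta_ratio in c(0.5, 2)) {
    distorted <- fx$D^eta_ratio
    diag(distorted) <- 0
    expect_equal(spearman_eval(fx$truth, sqdist_matrix(distorted, msk)), 1)
  }

  # scopes split by the partition
  part <- partition_domains(45, 15)
  expect_equal(spearman_eval(fx$truth, fx$d, part, "intra"), 1)
  expect_equal(spearman_eval(fx$truth, fx$d, part, "inter"), 1)
  # a single-domain partition leaves no inter-domain pairs
  tiny <- sqdist_matrix(fx$D[1:3, 1:3])
  expect_error(spearman_eval(structure3d(fx$truth$coords[1:3, ]), tiny,
                             partition_domains(3, 2), "inter"),
               "fewer than 3")
})

test_that("neighborhood capture applies the all-pairs rule per anchor tuple", {
  s <- normalize_structure(generate_benchmark(50, "loop"))
  sets <- list(c(1, 2, 3), c(1, 25, 50), c(10, 11))
  expect_equal(neighborhood_capture(s, sets, Inf), 1)
  expect_equal(neighborhood_capture(s, sets, 0), 0)

  # hand-check one tuple at an intermediate threshold
  dm <- as.matrix(stats::dist(s$coords))
  thr <- max(dm[1, 2], dm[1, 3], dm[2, 3]) + 1e-9
  expect_equal(neighborhood_capture(s, list(c(1, 2, 3)), thr), 1)
  expect_equal(neighborhood_capture(s, list(c(1, 2, 3)),
                                    min(dm[1, 2], dm[1, 3], dm[2, 3])), 0)
  expect_error(neighborhood_capture(s, list(c(1, 99)), 1), "out of range")
})

test_that("genomic-distance-controlled p-values match ranks and are null-uniform", {
  s <- generate_benchmark(300, "loop")
  sep <- 7
  n_cand <- 300 - sep
  dvec <- sqrt(rowSums((s$coords[1:n_cand, ] -
                        s$coords[(1 + sep):300, ])^2))

  # extreme rank: the minimum-distance pair beats every draw except itself
  i <- which.min(dvec)
  p_min <- genomic_distance_controlled_test(s, c(i, i + sep),
                                            n_random = 200, seed = 2)
  expect_lte(p_min, (1 + 1) / 201)

  # median-distance pair lands near p = 0.5
  i_med <- order(dvec)[ceiling(n_cand / 2)]
  p_med <- genomic_distance_controlled_test(s, c(i_med, i_med + sep),
                                            n_random = 250, seed = 2)
  expect_gt(p_med, 0.35)
  expect_lt(p_med, 0.65)

  # exhaustive-enumeration oracle when every candidate is drawn
  p_all <- suppressWarnings(
    genomic_distance_controlled_test(s, c(i_med, i_med + sep),
                                     n_random = n_cand * 20, seed = 3))
  rank_frac <- mean(dvec <= dvec[i_med])
  expect_equal(p_all, rank_frac, tolerance = 0.05)

  expect_warning(
    genomic_distance_controlled_test(s, c(1, 299), n_random = 50, seed = 1),
    "replacement")

  # null uniformity on a random structure (KS test)
  rw <- generate_benchmark(300, "random-walk", seed = 9)
  set.seed(10)
  ps <- vapply(1:300, function(k) {
    a <- sample(1:(300 - 12), 1)
    genomic_distance_controlled_test(rw, c(a, a + 12), n_random = 199,
                                     seed = k)
  }, numeric(1))
  expect_gt(suppressWarnings(stats::ks.test(ps, "punif"))$p.value, 0.01)  # discrete p-values tie harmlessly
})

test_that("the simulation study emits a full-factorial tidy table", {
  tab <- run_simulation_study(n = 40, rates = c(0.6, 1), levels = c(0, 1),
                              replicates = 2, seed = 3,
                              cfg = solver_config(max_iter = 60))
  expect_equal(nrow(tab), 2 * 2 * 2)
  expect_named(tab, c("rate", "level", "replicate", "re_coord", "re_dist",
                      "spearman", "iterations"))
  noiseless <- tab[tab$level == 0 & tab$rate == 1, ]
  expect_true(all(noiseless$re_dist < 1e-3))
})
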