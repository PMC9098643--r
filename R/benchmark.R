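#' Generate a synthetic benchmark structure
#'
#' Produces a smooth 3D curve with bounded, roughly uniform adjacent
#' distances, standing in for a chromosome-like polymer chain. Kinds:
#'
#' * `"loop"` (default): a helix-of-helices -- a minor helix winding around
#'   a major circular carrier, giving chromosome-like loops at two scales;
#' * `"helix"`: a plain parametric helix (adjacent distances exactly equal);
#' * `"random-walk"`: a moving-average-smoothed Gaussian walk.
#'
#' Coordinates are scaled so the mean adjacent distance is 1. Output is
#' deterministic under `seed` (the parametric kinds do not consume
#' randomness at all).
#'
#' @param n Number of bins (>= 10).
#' @param kind One of `"loop"`, `"helix"`, `"random-walk"`.
#' @param seed Integer seed (used by `"random-walk"`).
#' @param resolution Bin width in bp attached to the output.
#' @return A [structure3d()].
#' @export
generate_benchmark <- function(n, kind = c("loop", "helix", "random-walk"),
                               seed = 1L, resolution = 5000L) {
  stopifnot(n >= 10)
  kind <- match.arg(kind)
  P <- switch(kind,
    helix = {
      t <- seq(0, by = 0.2, length.out = n)
      R <- 3; c0 <- 0.5
      cbind(R * cos(t), R * sin(t), c0 * t)
    },
    loop = {
      t <- seq(0, 1, length.out = n)
      theta <- 3 * pi * t          # major carrier arc
      phi <- 2 * pi * 12 * t       # minor winding
      R <- 10; r <- 3; c0 <- 2
      cbind((R + r * cos(phi)) * cos(theta),
            (R + r * cos(phi)) * sin(theta),
            r * sin(phi) + c0 * theta)
    },
    `random-walk` = {
      old <- if (exists(".Random.seed", globalenv()))
        get(".Random.seed", globalenv()) else NULL
      set.seed(derive_seed(seed, "benchmark-walk"))
      w <- 7L
      steps <- matrix(stats::rnorm(3 * (n + w - 1L)), ncol = 3)
      walk <- apply(steps, 2, cumsum)
      sm <- apply(walk, 2, function(v)
        stats::filter(v, rep(1 / w, w), sides = 2))
      if (!is.null(old)) assign(".Random.seed", old, globalenv())
      sm[!is.na(sm[, 1]), , drop = FALSE][seq_len(n), , drop = FALSE]
    })
  adj <- sqrt(rowSums((P[-1, , drop = FALSE] - P[-n, , drop = FALSE])^2))
  structure3d(P / mean(adj), resolution)
}

#' Add measurement noise to a squared-distance matrix
#'
#' Implements the two-level white-noise protocol: with `delta` the minimum
#' of the measured (down-sampled) squared distances, level 1 draws noise
#' from `Normal(mean = delta, sd = delta)` and level 2 from
#' `Normal(mean = 2 * delta, sd = delta)`, added to each measured entry
#' (one draw per unordered pair, applied symmetrically). `N(delta, delta)`
#' is read as mean / standard deviation; set `sd` to override (e.g. `sd = 0`
#' for a deterministic shift). Entries are re-drawn until positive (at most
#' 100 draws, then clamped at `delta / 100`), keeping the perturbed values
#' valid squared Euclidean distances.
#'
#' @param d A [sqdist_matrix()] with measured entries.
#' @param level Noise level, 1 or 2.
#' @param seed Integer seed.
#' @param sd Noise standard deviation; defaults to `delta`.
#' @return A [sqdist_matrix()] with the same mask and noisy values.
#' @export
add_noise <- function(d, level = 1L, seed = 1L, sd = NULL) {
  stopifnot(level %in% c(1L, 2L))
  mp <- measured_pairs(d)
  if (!nrow(mp)) stop("no measured entries")
  delta <- min(mp$value)
  sd <- sd %||% delta
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  set.seed(derive_seed(seed, "noise"))
  m <- nrow(mp)
  noise <- stats::rnorm(m, mean = level * delta, sd = sd)
  val <- mp$value + noise
  for (k in 1:100) {
    bad <- which(val <= 0)
    if (!length(bad)) break
    val[bad] <- mp$value[bad] +
      stats::rnorm(length(bad), mean = level * delta, sd = sd)
  }
  val[val <= 0] <- delta / 100
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
  vals <- matrix(NA_real_, d$n, d$n)
  msk <- d$mask
  vals[cbind(mp$i, mp$j)] <- val
  vals[cbind(mp$j, mp$i)] <- val
  sqdist_matrix(vals, msk, d$resolution, d$bin_mask)
}

#' Coordinate-level relative error after normalization and alignment
#'
#' Both structures are centered and scaled to unit Frobenius norm, the
#' reconstruction is orthogonally aligned (reflections allowed) to the
#' benchmark, and `||C_re - C_benchmark||_F^2 / ||C_benchmark||_F^2` is
#' returned. Invariant to rigid motion, reflection, and global scale of the
#' reconstruction.
#'
#' @param recon,truth [structure3d()] objects with equal bin counts.
#' @return Non-negative scalar.
#' @export
relative_error_coords <- function(recon, truth) {
  if (nrow(recon$coords) != nrow(truth$coords))
    stop("structures must have the same number of bins")
  A <- normalize_structure(recon)
  B <- normalize_structure(truth)
  A <- procrustes_align(A, B, allow_reflection = TRUE)
  sum((A$coords - B$coords)^2) / sum(B$coords^2)
}

#' Distance-level relative error against a squared-distance matrix
#'
#' `RE = ||R - D^(1/2)||_F^2 / ||D^(1/2)||_F^2` where `R` holds the
#' (non-squared) pairwise distances of the reconstruction and `D` the
#' reference squared distances, evaluated over the reference's measured set
#' (all pairs when complete). No alignment or rescaling is applied: the
#' reconstruction is expected in the data's distance units.
#'
#' @param recon A [structure3d()].
#' @param truth_sq A [sqdist_matrix()] or a complete symmetric matrix of
#'   squared distances.
#' @return Non-negative scalar.
#' @export
relative_error_distances <- function(recon, truth_sq) {
  R <- sqrt(sq_edm_from_structure(recon))
  if (inherits(truth_sq, "sqdist_matrix")) {
    mp <- measured_pairs(truth_sq)
    if (truth_sq$n != nrow(R)) stop("dimension mismatch")
    r <- R[cbind(mp$i, mp$j)]
    dref <- sqrt(mp$value)
  } else {
    truth_sq <- as.matrix(truth_sq)
    if (nrow(truth_sq) != nrow(R)) stop("dimension mismatch")
    up <- upper.tri(truth_sq)
    r <- R[up]
    dref <- sqrt(truth_sq[up])
  }
  sum((r - dref)^2) / sum(dref^2)
}

#' Spearman correlation between predicted and observed distances
#'
#' Rank correlation between the reconstruction's pairwise distances and the
#' square roots of the observed squared distances, over measured pairs in
#' the requested scope. Positive values indicate agreement (distances
#' correlated with distances). Scopes: `"all"` pairs, `"intra"` (both bins
#' in the same domain), `"inter"` (different domains).
#'
#' @param pred A [structure3d()].
#' @param obs A [sqdist_matrix()] (or complete symmetric squared-distance
#'   matrix).
#' @param part A [partition_domains()] result; required for `"intra"` /
#'   `"inter"`.
#' @param scope One of `"all"`, `"intra"`, `"inter"`.
#' @return Scalar correlation in `[-1, 1]`.
#' @export
spearman_eval <- function(pred, obs, part = NULL,
                          scope = c("all", "intra", "inter")) {
  scope <- match.arg(scope)
  if (!inherits(obs, "sqdist_matrix")) obs <- sqdist_matrix(as.matrix(obs))
  mp <- measured_pairs(obs)
  if (scope != "all") {
    if (is.null(part)) stop("a domain partition is required for this scope")
    dom <- domain_of(part, obs$n)
    same <- dom[mp$i] == dom[mp$j]
    mp <- mp[if (scope == "intra") same else !same, , drop = FALSE]
  }
  if (nrow(mp) < 3L) stop("fewer than 3 pairs in scope")
  R <- sqrt(sq_edm_from_structure(pred))
  stats::cor(R[cbind(mp$i, mp$j)], sqrt(mp$value), method = "spearman")
}

#' Fraction of multi-way anchor sets captured in one spatial neighborhood
#'
#' An anchor tuple is captured iff all pairwise 3D distances among its
#' anchors are below `threshold`. The structure should be F-norm normalized
#' (see [normalize_structure()]) so that thresholds are comparable across
#' structures.
#'
#' @param s A [structure3d()].
#' @param anchor_sets List of integer vectors of 1-based bin indices (each
#'   of length >= 2).
#' @param threshold Distance threshold defining the neighborhood.
#' @return Fraction in `[0, 1]` of captured tuples.
#' @export
neighborhood_capture <- function(s, anchor_sets, threshold) {
  n <- nrow(s$coords)
  captured <- vapply(anchor_sets, function(idx) {
    idx <- as.integer(idx)
    if (any(idx < 1L | idx > n)) stop("anchor index out of range")
    dm <- as.matrix(stats::dist(s$coords[idx, , drop = FALSE]))
    all(dm[upper.tri(dm)] < threshold)
  }, logical(1))
  mean(captured)
}

#' Genomic-distance-controlled permutation test for 3D proximity
#'
#' Compares the 3D distance of a focal bin pair against `n_random` random
#' pairs with the same 1D genomic separation on the same chromosome, and
#' returns the one-sided (short-distance) empirical p-value with add-one
#' smoothing: `p = (1 + #{d_random <= d_focal}) / (1 + n_random)`.
#'
#' @param s A [structure3d()].
#' @param pair Integer vector `c(i, j)` of 1-based bin indices, `i != j`.
#' @param n_random Number of random controlled pairs (default 1000).
#' @param seed Integer seed.
#' @return Empirical p-value in `(0, 1]`.
#' @export
genomic_distance_controlled_test <- function(s, pair, n_random = 1000L,
                                             seed = 1L) {
  n <- nrow(s$coords)
  i <- min(pair); j <- max(pair)
  if (i == j) stop("pair must have distinct bins")
  sep <- j - i
  starts <- seq_len(n - sep)
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  set.seed(derive_seed(seed, "gd-control"))
  if (length(starts) < n_random) {
    warning("fewer candidate pairs than n_random; sampling with replacement")
    a <- sample(starts, n_random, replace = TRUE)
  } else {
    a <- sample(starts, n_random, replace = FALSE)
  }
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
  dfun <- function(p, q) sqrt(sum((s$coords[p, ] - s$coords[q, ])^2))
  d_obs <- dfun(i, j)
  d_rand <- sqrt(rowSums((s$coords[a, , drop = FALSE] -
                          s$coords[a + sep, , drop = FALSE])^2))
  (1 + sum(d_rand <= d_obs)) / (1 + n_random)
}

#' Run the full down-sampling / noise simulation study
#'
#' Full-factorial protocol: generate a benchmark curve, form its squared
#' distance matrix, down-sample the measured pairs at each rate, corrupt
#' with each noise level, reconstruct with the low-rank solver, and score
#' against the known truth. Per-replicate seeds derive deterministically
#' from `seed`.
#'
#' @param n Bins in the benchmark structure.
#' @param rates Down-sampling rates in (0, 1].
#' @param levels Noise levels among `0` (none), `1`, `2`.
#' @param replicates Replicates per (rate, level) cell.
#' @param seed Master seed.
#' @param kind Benchmark curve kind (see [generate_benchmark()]).
#' @param cfg Base [solver_config()]; its seed is re-derived per replicate.
#' @return Data frame with one row per run: `rate`, `level`, `replicate`,
#'   `re_coord`, `re_dist`, `spearman`, `iterations`.
#' @export
run_simulation_study <- function(n = 200L, rates = seq(0.1, 0.9, by = 0.1),
                                 levels = c(1L, 2L), replicates = 10L,
                                 seed = 1L, kind = "loop",
                                 cfg = solver_config()) {
  truth <- generate_benchmark(n, kind = kind, seed = derive_seed(seed, "truth"))
  D_true <- sq_edm_from_structure(truth)
  d_full <- sqdist_matrix(D_true, resolution = truth$resolution)
  grid <- expand.grid(replicate = seq_len(replicates), level = levels,
                      rate = rates)
  rows <- lapply(seq_len(nrow(grid)), function(g) {
    rate <- grid$rate[g]; level <- grid$level[g]; rep_k <- grid$replicate[g]
    sub_seed <- derive_seed(seed, sprintf("sim-%g-%d-%d", rate, level, rep_k))
    din <- downsample_measurements(d_full, rate, seed = sub_seed)
    if (level > 0) din <- add_noise(din, level = level, seed = sub_seed)
    ck <- cfg
    ck$seed <- sub_seed
    fit <- solve_lowrank(din, ck)
    data.frame(rate = rate, level = level, replicate = rep_k,
               re_coord = relative_error_coords(fit$structure, truth),
               re_dist = relative_error_distances(fit$structure, D_true),
               spearman = spearman_eval(fit$structure, D_true),
               iterations = fit$state$iteration)
  })
  do.call(rbind, rows)
}
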