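#' Per-bin 1D accessibility signal track
#'
#' Mean chromatin-accessibility signal (e.g. DNase-seq fold-change over
#' genomic background) per genomic bin, aligned to the bins of a contact
#' map or distance matrix.
#'
#' @param values Non-negative numeric vector, one value per bin.
#' @param resolution Bin width in bp.
#' @return An object of class `signal_track`.
#' @export
signal_track <- function(values, resolution = NA_integer_) {
  values <- as.numeric(values)
  if (any(!is.finite(values)) || any(values < 0))
    stop("signal values must be finite and non-negative")
  structure(list(values = values, resolution = resolution),
            class = "signal_track")
}

#' Read a bedGraph signal into per-bin averages
#'
#' Averages interval signal over each bin of width `resolution` (bp not
#' covered by any interval contribute 0, matching fold-change-over-
#' background conventions).
#'
#' @param path bedGraph file (`chrom start end value`).
#' @param resolution Bin width in bp.
#' @param n_bins Number of bins; inferred from the last interval end when
#'   omitted.
#' @param chrom Restrict to this chromosome label (default: first seen).
#' @return A [signal_track()].
#' @export
read_bedgraph <- function(path, resolution, n_bins = NULL, chrom = NULL) {
  bg <- utils::read.table(path, header = FALSE,
                          col.names = c("chrom", "start", "end", "value"))
  chrom <- chrom %||% bg$chrom[1]
  bg <- bg[bg$chrom == chrom, , drop = FALSE]
  nb <- n_bins %||% as.integer(ceiling(max(bg$end) / resolution))
  acc <- numeric(nb)
  for (r in seq_len(nrow(bg))) {
    b0 <- bg$start[r] %/% resolution
    b1 <- (bg$end[r] - 1L) %/% resolution
    for (b in b0:b1) {
      lo <- max(bg$start[r], b * resolution)
      hi <- min(bg$end[r], (b + 1L) * resolution)
      if (b + 1L <= nb) acc[b + 1L] <- acc[b + 1L] + bg$value[r] * (hi - lo)
    }
  }
  signal_track(acc / resolution, resolution)
}

#' Fit the accessibility-distance regression
#'
#' Ordinary least squares of the observed squared distances on
#' accessibility and genomic separation over the measured pairs:
#' `D_ij ~ alpha * (S_i + S_j) + alpha3 * G_ij + intercept`, where `G_ij`
#' is the 1D genomic distance in bp. The accessibility term is symmetrized
#' (`alpha1 = alpha2 = alpha`) because `D` is symmetric in `(i, j)`; an
#' intercept is included and reported separately. Negative accessibility
#' coefficients reflect co-accessible loci sitting closer in 3D space.
#'
#' @param d A [sqdist_matrix()] with at least 10 measured pairs.
#' @param s A [signal_track()] aligned to the bins of `d`.
#' @return An object of class `distance_regression` with `alpha1`, `alpha2`,
#'   `alpha3`, `intercept` and `fit_stats` (`r_squared`, `n_pairs`).
#' @export
fit_distance_regression <- function(d, s) {
  stopifnot(length(s$values) == d$n)
  mp <- measured_pairs(d)
  if (nrow(mp) < 10L) stop("need at least 10 measured pairs")
  res <- if (is.na(d$resolution)) 1 else d$resolution
  Ssum <- s$values[mp$i] + s$values[mp$j]
  G <- (mp$j - mp$i) * res
  if (stats::sd(Ssum) < 1e-12)
    stop("degenerate design: accessibility predictor (S_i + S_j) is constant")
  if (stats::sd(G) < 1e-12)
    stop("degenerate design: genomic-distance predictor is constant")
  fit <- stats::lm(mp$value ~ Ssum + G)
  cf <- stats::coef(fit)
  structure(list(alpha1 = unname(cf["Ssum"]), alpha2 = unname(cf["Ssum"]),
                 alpha3 = unname(cf["G"]), intercept = unname(cf[1]),
                 fit_stats = list(r_squared = summary(fit)$r.squared,
                                  n_pairs = nrow(mp))),
            class = "distance_regression")
}

#' @export
print.distance_regression <- function(x, ...) {
  cat(sprintf(
    "<distance_regression> alpha1 = alpha2 = %.4g, alpha3 = %.4g, intercept = %.4g (R^2 = %.3f, n = %d)\n",
    x$alpha1, x$alpha3, x$intercept, x$fit_stats$r_squared,
    x$fit_stats$n_pairs))
  invisible(x)
}

#' Impute a complete squared-distance matrix from accessibility
#'
#' `E_ij = intercept + alpha1 S_i + alpha2 S_j + alpha3 G_ij` for all bin
#' pairs of the target signal, floored at `1e-6 * median(E)` so imputed
#' squared distances stay positive.
#'
#' @param model A [fit_distance_regression()] result.
#' @param s_target Target cell-type [signal_track()].
#' @param n Number of bins (defaults to the signal length).
#' @return A fully observed [sqdist_matrix()].
#' @export
impute_distances <- function(model, s_target, n = length(s_target$values)) {
  stopifnot(length(s_target$values) == n)
  res <- if (is.na(s_target$resolution)) 1 else s_target$resolution
  S <- s_target$values
  G <- abs(outer(seq_len(n), seq_len(n), "-")) * res
  E <- model$intercept + model$alpha1 * outer(S, rep(1, n)) +
    model$alpha2 * outer(rep(1, n), S) + model$alpha3 * G
  floor_val <- 1e-6 * abs(stats::median(E[upper.tri(E)]))
  floor_val <- max(floor_val, 1e-12)
  E[E < floor_val] <- floor_val
  diag(E) <- 0
  msk <- matrix(TRUE, n, n); diag(msk) <- FALSE
  sqdist_matrix(E, msk, s_target$resolution)
}

#' Gram matrix of a complete squared-distance matrix
#'
#' Classical double-centering `X = -1/2 J E J` with
#' `J = I - (1/n) 1 1^T`. When `E` is a true squared EDM,
#' [sq_edm_from_gram()] of the result reproduces `E` exactly; row sums of
#' the output are zero.
#'
#' @param e A fully observed [sqdist_matrix()] or complete symmetric matrix
#'   of squared distances.
#' @return Symmetric `n x n` Gram matrix.
#' @export
gram_from_distances <- function(e) {
  E <- if (inherits(e, "sqdist_matrix")) {
    if (any(!e$mask[upper.tri(e$mask)]))
      stop("matrix must be fully observed")
    v <- e$values; diag(v) <- 0; v
  } else {
    as.matrix(e)
  }
  n <- nrow(E)
  rm_ <- rowMeans(E)
  gm <- mean(E)
  -0.5 * (E - outer(rm_, rep(1, n)) - outer(rep(1, n), rm_) + gm)
}

#' Integrative solver configuration
#'
#' @param gamma Weight of the imputed-distance penalty (>= 0, default 0.5).
#' @param base A [solver_config()] for the underlying completion solver.
#' @return A list of class `integrative_config`.
#' @export
integrative_config <- function(gamma = 0.5, base = solver_config()) {
  stopifnot(gamma >= 0)
  structure(list(gamma = gamma, base = base), class = "integrative_config")
}

#' Integrative reconstruction with imputed-distance penalty
#'
#' Solves the base completion problem on the source cell-type measurements
#' with an extra penalty `gamma * ||A_E(P P^T) - A_E(E^M)||^2`, where `E^M`
#' is the double-centered Gram matrix of the imputed distance matrix `E`
#' and `A_E` samples the measured source pairs plus a uniform sample of
#' unmeasured pairs (at the base config's `k_rate`) -- the imputed,
#' target-cell-type-specific information thereby reaches pairs the source
#' Hi-C missed. With `gamma = 0` the result is identical to
#' [solve_lowrank()] under the same seed.
#'
#' @param d_source Source cell-type [sqdist_matrix()].
#' @param e Fully observed imputed [sqdist_matrix()] (see
#'   [impute_distances()]).
#' @param cfg An [integrative_config()].
#' @return As [solve_lowrank()]: list with `structure` and `state`.
#' @export
solve_integrative <- function(d_source, e, cfg = integrative_config()) {
  if (cfg$gamma == 0) return(solve_lowrank(d_source, cfg$base))
  stopifnot(e$n == d_source$n)
  EM <- gram_from_distances(e)
  mp <- measured_pairs(d_source)
  all_pairs <- upper_pairs(d_source$n)
  measured_key <- paste(mp$i, mp$j)
  unmeas <- all_pairs[!(paste(all_pairs[, 1], all_pairs[, 2]) %in%
                          measured_key), , drop = FALSE]
  k_rate <- cfg$base$k_rate
  if (k_rate < 1 && nrow(unmeas) > 0) {
    old <- if (exists(".Random.seed", globalenv()))
      get(".Random.seed", globalenv()) else NULL
    set.seed(derive_seed(cfg$base$seed, "integrative-pairs"))
    take <- sort(sample(nrow(unmeas), ceiling(k_rate * nrow(unmeas))))
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
    unmeas <- unmeas[take, , drop = FALSE]
  }
  pen_pairs <- rbind(as.matrix(mp[, c("i", "j")]),
                     unname(unmeas))
  op <- sampling_operator(pen_pairs, d_source$n)
  targets <- apply_sampling(op, EM)
  solve_lowrank(d_source, cfg$base,
                extra_penalty = list(pairs = op$pairs, values = targets,
                                     gamma = cfg$gamma))
}

#' Boost structure resolution by fragment splitting
#'
#' Splits each low-resolution fragment into `factor` consecutive children
#' that inherit the parent's pairwise squared distances (pairs of children
#' of the same parent are unmeasured), fits the accessibility-distance
#' regression on the expanded matrix against the high-resolution signal,
#' imputes a complete high-resolution matrix, and runs the integrative
#' solver on the pair.
#'
#' @param d_low Low-resolution [sqdist_matrix()].
#' @param factor Integer splitting factor (>= 1; 1 is the identity
#'   expansion).
#' @param s_high High-resolution [signal_track()] of length
#'   `factor * d_low$n`.
#' @param cfg An [integrative_config()].
#' @return The high-resolution [structure3d()].
#' @export
boost_resolution <- function(d_low, factor, s_high,
                             cfg = integrative_config()) {
  factor <- as.integer(factor)
  stopifnot(factor >= 1L)
  if (length(s_high$values) != factor * d_low$n)
    stop("signal length must be factor * n_low")
  d_high <- expand_sqdist(d_low, factor)
  model <- fit_distance_regression(d_high, s_high)
  e <- impute_distances(model, s_high)
  fit <- solve_integrative(d_high, e, cfg)
  fit$structure
}

#' Expand a squared-distance matrix by index replication
#'
#' Child bins inherit the pairwise values of their parents; pairs of
#' children sharing a parent are left unmeasured.
#'
#' @param d_low A [sqdist_matrix()].
#' @param factor Integer splitting factor.
#' @return A [sqdist_matrix()] of dimension `factor * d_low$n`.
#' @export
expand_sqdist <- function(d_low, factor) {
  factor <- as.integer(factor)
  n_high <- factor * d_low$n
  parent <- (seq_len(n_high) - 1L) %/% factor + 1L
  vals <- d_low$values[parent, parent]
  msk <- d_low$mask[parent, parent]
  same_parent <- outer(parent, parent, "==")
  msk[same_parent] <- FALSE
  vals[!msk] <- NA_real_
  res_low <- d_low$resolution
  res_high <- if (is.na(res_low)) NA_integer_
              else as.integer(res_low %/% factor)
  sqdist_matrix(vals, msk, res_high)
}
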