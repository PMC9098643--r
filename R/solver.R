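#' Linear sampling operator over unordered index pairs
#'
#' Represents the operator `A` that maps a symmetric matrix `X` to the
#' vector `f` with `f_k = X[a,a] + X[b,b] - 2 X[a,b]` for each stored pair
#' `(a, b)` -- i.e. the squared distance implied by `X` when `X` is a Gram
#' matrix. The sub-diagonal operator `B` used for the adjacent-fragment
#' penalty is the same type with pairs fixed to `(i, i + 1)`; see
#' [subdiagonal_operator()].
#'
#' @param pairs Two-column integer matrix of unordered 1-based index pairs;
#'   no duplicates, no self-pairs.
#' @param n Dimension of the matrices the operator acts on.
#' @return An object of class `sampling_operator`.
#' @export
sampling_operator <- function(pairs, n) {
  pairs <- matrix(as.integer(pairs), ncol = 2)
  a <- pmin(pairs[, 1], pairs[, 2])
  b <- pmax(pairs[, 1], pairs[, 2])
  if (any(a == b)) stop("self-pairs are not allowed")
  if (any(b > n) || any(a < 1L)) stop("pair index out of range")
  if (anyDuplicated(cbind(a, b))) stop("duplicate pairs")
  structure(list(pairs = cbind(a = a, b = b), n = as.integer(n)),
            class = "sampling_operator")
}

#' @rdname sampling_operator
#' @export
subdiagonal_operator <- function(n) {
  sampling_operator(cbind(seq_len(n - 1L), seq_len(n - 1L) + 1L), n)
}

#' Apply a sampling operator
#' @param op A [sampling_operator()].
#' @param X Symmetric `n x n` matrix.
#' @return Numeric vector of length `nrow(op$pairs)`.
#' @export
apply_sampling <- function(op, X) {
  if (nrow(X) != op$n) stop("dimension mismatch")
  a <- op$pairs[, 1]; b <- op$pairs[, 2]
  X[cbind(a, a)] + X[cbind(b, b)] - 2 * X[cbind(a, b)]
}

#' Apply the adjoint of a sampling operator
#'
#' `A*(y) = sum_k y_k omega_k`, where `omega_k` adds `y_k` at `(a,a)` and
#' `(b,b)` and subtracts it at `(a,b)` and `(b,a)`.
#'
#' @param op A [sampling_operator()].
#' @param y Numeric vector matching the operator's pair count.
#' @return Symmetric `n x n` matrix.
#' @export
apply_sampling_adjoint <- function(op, y) {
  if (length(y) != nrow(op$pairs)) stop("length mismatch")
  cpp_adjoint_dense(op$n, op$pairs[, 1] - 1L, op$pairs[, 2] - 1L,
                    as.numeric(y))
}

#' Solver configuration
#'
#' @param lambda_pen Weight of the adjacent-distance penalty (default 10).
#' @param r_reg Regularization weight on the measured-pair term (default 1).
#' @param d_t Target squared distance between adjacent fragments. `NULL`
#'   (default) sets it per problem to the median measured adjacent squared
#'   distance; see [tune_dt()] for grid tuning against the objective.
#' @param tol Convergence threshold: mean relative absolute error between
#'   reconstructed and observed distances on the measured set (default 1e-3).
#' @param max_iter Outer (multiplier-update) iteration cap.
#' @param inner_iter Barzilai-Borwein steps per outer iteration.
#' @param k_rate Down-sampling rate applied to the measured set inside the
#'   solver for speed (adjacent pairs always kept); default 1 = use all.
#' @param stall_window Outer iterations without material improvement of the
#'   measured error before stopping early; 0 disables the check. Noisy
#'   over-determined inputs plateau above `tol`, and iterating past the
#'   plateau interpolates the measurement noise, so stopping at its onset
#'   acts as regularization. The check engages only after the error has
#'   halved from its initial value (the first multiplier updates are
#'   non-monotone).
#' @param stall_rel Relative error improvement counting as material for the
#'   stall check.
#' @param n_starts Number of random multi-starts; the problem is nonconvex,
#'   and the run with the lowest final measured-set error is kept. The
#'   first start that converges below `tol` short-circuits the rest.
#' @param seed Integer seed for the random initialization (and `k_rate`
#'   sub-sampling); start `k` derives its own sub-seed.
#' @return A list of class `solver_config`.
#' @export
solver_config <- function(lambda_pen = 10, r_reg = 1, d_t = NULL, tol = 1e-3,
                          max_iter = 100L, inner_iter = 20L, k_rate = 1,
                          stall_window = 5L, stall_rel = 5e-3,
                          n_starts = 3L, seed = 1L) {
  stopifnot(lambda_pen > 0, r_reg > 0, tol > 0, k_rate > 0, k_rate <= 1,
            is.null(d_t) || d_t > 0, stall_window >= 0, n_starts >= 1)
  structure(list(lambda_pen = lambda_pen, r_reg = r_reg, d_t = d_t,
                 tol = tol, max_iter = as.integer(max_iter),
                 inner_iter = as.integer(inner_iter), k_rate = k_rate,
                 stall_window = as.integer(stall_window),
                 stall_rel = stall_rel, n_starts = as.integer(n_starts),
                 seed = as.integer(seed)),
            class = "solver_config")
}

#' Augmented Lagrangian value
#'
#' `Trace(P P^T) + lambda/2 ||B(P P^T) - d_t 1||^2 +
#'  r/2 ||A(P P^T) - b + Lambda||^2`, with `B` the sub-diagonal operator.
#'
#' @param P `N x 3` coordinate matrix.
#' @param op Measurement [sampling_operator()] (`A`).
#' @param b Measured squared distances, one per pair of `op`.
#' @param cfg A [solver_config()] with `d_t` set.
#' @param Lambda Multiplier vector (defaults to zeros).
#' @return Scalar objective value.
#' @export
objective_value <- function(P, op, b, cfg, Lambda = NULL) {
  Lambda <- Lambda %||% numeric(length(b))
  cpp_lagrangian_value(P, op$pairs[, 1] - 1L, op$pairs[, 2] - 1L,
                       as.numeric(b), as.numeric(Lambda),
                       cfg$lambda_pen, cfg$r_reg, cfg$d_t)
}

#' Gradient of the augmented Lagrangian with respect to the coordinates
#'
#' `2 P + 2 lambda B*(B(P P^T) - d_t 1) P + 2 r A*(A(P P^T) - b + Lambda) P`,
#' evaluated through sparse operator application.
#'
#' @inheritParams objective_value
#' @return `N x 3` gradient matrix.
#' @export
lagrangian_gradient <- function(P, op, b, cfg, Lambda = NULL) {
  Lambda <- Lambda %||% numeric(length(b))
  cpp_lagrangian_grad_r(P, op$pairs[, 1] - 1L, op$pairs[, 2] - 1L,
                        as.numeric(b), as.numeric(Lambda),
                        cfg$lambda_pen, cfg$r_reg, cfg$d_t)
}

#' @keywords internal
resolve_dt <- function(cfg, mp) {
  if (!is.null(cfg$d_t)) return(cfg$d_t)
  adj <- mp$value[mp$j == mp$i + 1L]
  if (!length(adj)) adj <- mp$value
  stats::median(adj)
}

#' Reconstruct a 3D structure by low-rank distance-matrix completion
#'
#' Solves the trace-minimization problem over the Gram matrix `X = P P^T`
#' subject to the measured squared distances, with an adjacent-fragment
#' distance penalty, via the alternating scheme: Barzilai-Borwein descent on
#' `P` (monotone Armijo safeguard, so accepted steps never increase the
#' augmented Lagrangian) with the multiplier fixed, then the update
#' `Lambda <- Lambda + (A(P P^T) - b)`. Iterations stop when the mean
#' relative absolute error between reconstructed and observed distances on
#' the measured set falls below `cfg$tol`, or at `cfg$max_iter`.
#'
#' @param d A [sqdist_matrix()] with at least one measured pair. Chain
#'   adjacencies should be present (a warning is emitted otherwise).
#' @param cfg A [solver_config()].
#' @param extra_penalty Optional list with elements `pairs` (two-column
#'   1-based matrix), `values` (target squared distances) and `gamma`,
#'   adding `gamma * ||A_E(P P^T) - values||^2` to the objective (used by
#'   the integrative solver).
#' @return A list with `structure` (the centered [structure3d()]) and
#'   `state` (class `solver_state`: final `P`, `Lambda`, iteration count,
#'   measured error, per-step objective history).
#' @export
solve_lowrank <- function(d, cfg = solver_config(), extra_penalty = NULL) {
  mp <- measured_pairs(d)
  if (!nrow(mp)) stop("empty measurement set")
  n <- d$n
  n_adj <- sum(mp$j == mp$i + 1L)
  if (n_adj < n - 1L)
    warning(sprintf("%d of %d chain adjacencies unmeasured", n - 1L - n_adj,
                    n - 1L))
  if (cfg$k_rate < 1) {
    dk <- downsample_measurements(d, cfg$k_rate,
                                  seed = derive_seed(cfg$seed, "solver-krate"))
    mp <- measured_pairs(dk)
  }
  d_t <- resolve_dt(cfg, mp)
  ea <- integer(0); eb <- integer(0); evals <- numeric(0); gamma <- 0
  if (!is.null(extra_penalty) && extra_penalty$gamma > 0) {
    ea <- as.integer(extra_penalty$pairs[, 1] - 1L)
    eb <- as.integer(extra_penalty$pairs[, 2] - 1L)
    evals <- as.numeric(extra_penalty$values)
    gamma <- extra_penalty$gamma
  }
  run_once <- function(init_seed) {
    old <- if (exists(".Random.seed", globalenv()))
      get(".Random.seed", globalenv()) else NULL
    set.seed(init_seed)
    P0 <- matrix(stats::rnorm(3 * n, sd = sqrt(d_t / 6)), n, 3)
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
    cpp_alm_solve(P0, mp$i - 1L, mp$j - 1L, mp$value,
                  cfg$lambda_pen, cfg$r_reg, d_t, cfg$tol,
                  cfg$max_iter, cfg$inner_iter, ea, eb, evals, gamma,
                  cfg$stall_window %||% 5L, cfg$stall_rel %||% 5e-3)
  }
  n_starts <- cfg$n_starts %||% 3L
  fit <- NULL
  for (start_k in seq_len(n_starts)) {
    fk <- run_once(derive_seed(cfg$seed, sprintf("solver-init-%d", start_k)))
    if (isTRUE(fk$diverged)) {
      fk <- run_once(derive_seed(cfg$seed,
                                 sprintf("solver-init-%d-restart", start_k)))
      if (isTRUE(fk$diverged)) next
    }
    if (is.null(fit) || fk$measured_error < fit$measured_error) fit <- fk
    if (fit$measured_error < cfg$tol) break
  }
  if (is.null(fit)) stop("solver diverged on every start; check inputs")
  res <- d$resolution
  s <- structure3d(fit$P, res)
  state <- structure(
    list(P = fit$P, Lambda = fit$Lambda, iteration = fit$iterations,
         measured_error = fit$measured_error, d_t = d_t,
         history = data.frame(outer = fit$inner_outer_index,
                              objective = fit$inner_objective),
         outer_error = fit$outer_error, config = cfg),
    class = "solver_state")
  list(structure = s, state = state)
}

#' @export
print.solver_state <- function(x, ...) {
  cat(sprintf(
    "<solver_state> %d outer iterations, measured error %.3g, d_t = %.3g\n",
    x$iteration, x$measured_error, x$d_t))
  invisible(x)
}

#' Tune the adjacent-distance parameter on a grid
#'
#' Runs [solve_lowrank()] once per candidate `d_t` (all with the same seed)
#' and returns the candidate minimizing the converged penalized objective
#' (the augmented Lagrangian at `Lambda = 0`). Ties break toward the smaller
#' candidate.
#'
#' @param d A [sqdist_matrix()].
#' @param cfg A [solver_config()]; its `d_t` is overridden per candidate.
#' @param candidates Positive scalars to try. Default: a log-spaced grid
#'   around the median measured adjacent squared distance.
#' @return The selected `d_t` (with the per-candidate objectives as
#'   attribute `"objectives"`).
#' @export
tune_dt <- function(d, cfg = solver_config(), candidates = NULL) {
  if (is.null(candidates)) {
    mp <- measured_pairs(d)
    ctr <- resolve_dt(solver_config(), mp)
    candidates <- ctr * 2^seq(-3, 3)
  }
  stopifnot(length(candidates) >= 1L, all(candidates > 0))
  candidates <- sort(candidates)
  objs <- rep(NA_real_, length(candidates))
  for (k in seq_along(candidates)) {
    ck <- cfg
    ck$d_t <- candidates[k]
    fit <- tryCatch(solve_lowrank(d, ck), error = function(e) NULL)
    if (is.null(fit)) next
    op <- sampling_operator(as.matrix(measured_pairs(d)[, c("i", "j")]), d$n)
    objs[k] <- objective_value(fit$state$P, op, measured_pairs(d)$value, ck)
  }
  if (all(is.na(objs))) stop("all candidate runs diverged")
  best <- which(objs == min(objs, na.rm = TRUE))[1]  # sorted: ties -> smaller
  structure(candidates[best], objectives = objs)
}
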