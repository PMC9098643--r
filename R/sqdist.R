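#' Partially observed squared-distance matrix
#'
#' Container for the solver input: a symmetric matrix of squared 3D
#' distances defined only on a measurement mask. The diagonal is implicitly
#' zero and never part of the mask. Unmeasured entries are `NA`.
#'
#' @param values Symmetric numeric `n x n` matrix; `NA` where unmeasured.
#' @param mask Logical symmetric `n x n` matrix, `TRUE` = measured. Defaults
#'   to `is.finite(values)` off the diagonal.
#' @param resolution Bin width in bp (optional bookkeeping).
#' @param bin_mask Per-bin retention flag carried from the source map.
#' @return An object of class `sqdist_matrix`.
#' @export
sqdist_matrix <- function(values, mask = NULL, resolution = NA_integer_,
                          bin_mask = NULL) {
  values <- as.matrix(values)
  n <- nrow(values)
  stopifnot(ncol(values) == n)
  if (is.null(mask)) {
    mask <- is.finite(values)
    diag(mask) <- FALSE
  }
  mask <- as.matrix(mask)
  diag(mask) <- FALSE
  if (!isTRUE(all.equal(mask, t(mask)))) stop("mask must be symmetric")
  v <- values[mask]
  if (length(v)) {
    if (any(!is.finite(v)) || any(v <= 0))
      stop("measured squared distances must be finite and > 0")
    sym_err <- max(abs(values[mask] - t(values)[mask]))
    if (sym_err > 1e-8 * max(abs(v), 1))
      stop("values must be symmetric on the mask")
  }
  values[!mask] <- NA_real_
  diag(values) <- 0
  structure(list(n = n, values = values, mask = mask,
                 resolution = resolution,
                 bin_mask = bin_mask %||% rep(TRUE, n)),
            class = "sqdist_matrix")
}

#' @export
print.sqdist_matrix <- function(x, ...) {
  dens <- sum(x$mask) / (x$n * (x$n - 1))
  cat(sprintf("<sqdist_matrix> %d x %d, %.1f%% of off-diagonal pairs measured\n",
              x$n, x$n, 100 * dens))
  invisible(x)
}

#' Measured unordered pairs of a squared-distance matrix
#' @param d A [sqdist_matrix()].
#' @return Data frame `i`, `j` (1-based, `i < j`), `value`.
#' @export
measured_pairs <- function(d) {
  idx <- which(d$mask & upper.tri(d$mask), arr.ind = TRUE)
  data.frame(i = idx[, 1], j = idx[, 2], value = d$values[idx])
}

#' Convert interaction frequencies to squared spatial distances
#'
#' Applies the power-law conversion `D_ij = IF_ij^(-eta)` on every measured
#' pair of the (normalized) contact map; `D_ij` is interpreted as the squared
#' 3D distance. Zero-contact pairs are treated as missing measurements, not
#' as infinite distances, so they simply stay outside the mask. Only pairs
#' with both bins retained enter the mask.
#'
#' @param cm A normalized [contact_map()].
#' @param eta Conversion exponent, > 0 (default 0.5).
#' @return A [sqdist_matrix()] over the full bin indexing of `cm`.
#' @export
contacts_to_distances <- function(cm, eta = 0.5) {
  stopifnot(eta > 0)
  n <- cm$n_bins
  vals <- matrix(NA_real_, n, n)
  msk <- matrix(FALSE, n, n)
  ent <- cm$entries
  ent <- ent[ent$value > 0 & ent$i != ent$j &
             cm$bin_mask[ent$i + 1L] & cm$bin_mask[ent$j + 1L], , drop = FALSE]
  if (nrow(ent)) {
    d <- ent$value^(-eta)
    ii <- ent$i + 1L; jj <- ent$j + 1L
    vals[cbind(ii, jj)] <- d; vals[cbind(jj, ii)] <- d
    msk[cbind(ii, jj)] <- TRUE; msk[cbind(jj, ii)] <- TRUE
  }
  sqdist_matrix(vals, msk, cm$resolution, cm$bin_mask)
}

#' Down-sample the measurement mask
#'
#' Retains a uniform sample without replacement of `ceiling(rate * m)` of the
#' `m` measured non-adjacent unordered pairs. Chain-adjacent pairs
#' `(i, i + 1)` are exempt and always retained so the adjacent-distance
#' penalty operator stays defined and the polymer chain stays connected.
#'
#' @param d A [sqdist_matrix()].
#' @param rate Fraction of non-adjacent measured pairs to keep, in (0, 1].
#' @param seed Integer seed; identical seeds give identical masks.
#' @return A [sqdist_matrix()] with the reduced mask.
#' @export
downsample_measurements <- function(d, rate, seed = 1L) {
  if (!is.numeric(rate) || rate <= 0 || rate > 1)
    stop("rate must be in (0, 1]")
  mp <- measured_pairs(d)
  adjacent <- mp$j == mp$i + 1L
  non_adj <- which(!adjacent)
  m <- length(non_adj)
  n_keep <- ceiling(rate * m)
  if (rate < 1 && m > 0) {
    withr_seed <- derive_seed(seed, "downsample")
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(withr_seed)
    keep_idx <- sort(sample(non_adj, n_keep))
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
  } else {
    keep_idx <- non_adj
  }
  sel <- mp[c(which(adjacent), keep_idx), , drop = FALSE]
  vals <- matrix(NA_real_, d$n, d$n)
  msk <- matrix(FALSE, d$n, d$n)
  vals[cbind(sel$i, sel$j)] <- sel$value; vals[cbind(sel$j, sel$i)] <- sel$value
  msk[cbind(sel$i, sel$j)] <- TRUE; msk[cbind(sel$j, sel$i)] <- TRUE
  sqdist_matrix(vals, msk, d$resolution, d$bin_mask)
}

#' Write / read a squared-distance matrix as triplet TSV
#'
#' One `pos1 pos2 squared_distance` line per measured unordered pair,
#' positions in bp (bin starts).
#'
#' @param d A [sqdist_matrix()].
#' @param path File path.
#' @return `path` invisibly for the writer; a [sqdist_matrix()] for the
#'   reader.
#' @export
write_sqdist <- function(d, path) {
  mp <- measured_pairs(d)
  res <- if (is.na(d$resolution)) 1L else d$resolution
  utils::write.table(
    data.frame(pos1 = (mp$i - 1L) * res, pos2 = (mp$j - 1L) * res,
               sqdist = mp$value),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_sqdist
#' @param resolution Bin width in bp used when writing.
#' @param n_bins Optional known dimension.
#' @export
read_sqdist <- function(path, resolution, n_bins = NULL) {
  raw <- utils::read.table(path, header = FALSE)
  i <- pmin(raw[, 1], raw[, 2]) %/% resolution + 1L
  j <- pmax(raw[, 1], raw[, 2]) %/% resolution + 1L
  n <- n_bins %||% max(j)
  vals <- matrix(NA_real_, n, n)
  msk <- matrix(FALSE, n, n)
  vals[cbind(i, j)] <- raw[, 3]; vals[cbind(j, i)] <- raw[, 3]
  msk[cbind(i, j)] <- TRUE; msk[cbind(j, i)] <- TRUE
  sqdist_matrix(vals, msk, resolution)
}
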