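#' Construct a contact map
#'
#' A `contact_map` holds sparse, symmetric, bin-level Hi-C interaction
#' frequencies for one chromosome. Entries are stored once per unordered pair
#' with 0-based bin indices `i <= j`; bin `b` spans the half-open genomic
#' interval `[b * resolution, (b + 1) * resolution)`. `bin_mask` marks bins
#' retained for analysis (centromere/telomere and zero-coverage bins are
#' dropped by [filter_bins()]).
#'
#' @param entries Data frame with integer columns `i`, `j` (0-based bin
#'   indices, `i <= j`) and numeric `value` (non-negative counts or
#'   normalized frequencies).
#' @param n_bins Number of bins on the chromosome.
#' @param resolution Bin width in bp.
#' @param chrom Chromosome label.
#' @param bin_mask Logical vector of length `n_bins`; defaults to all `TRUE`.
#' @return An object of class `contact_map`.
#' @export
contact_map <- function(entries, n_bins, resolution, chrom = "chrN",
                        bin_mask = NULL) {
  entries <- as.data.frame(entries)
  stopifnot(all(c("i", "j", "value") %in% names(entries)))
  entries$i <- as.integer(entries$i)
  entries$j <- as.integer(entries$j)
  entries$value <- as.numeric(entries$value)
  if (nrow(entries)) {
    if (any(entries$i > entries$j)) stop("entries must satisfy i <= j")
    if (any(entries$value < 0)) stop("negative interaction frequency")
    if (any(entries$j >= n_bins)) stop("bin index out of range")
    if (anyDuplicated(entries[c("i", "j")])) stop("duplicate (i, j) entry")
  }
  bin_mask <- bin_mask %||% rep(TRUE, n_bins)
  stopifnot(length(bin_mask) == n_bins)
  structure(
    list(entries = entries[order(entries$i, entries$j), , drop = FALSE],
         n_bins = as.integer(n_bins), resolution = as.integer(resolution),
         chrom = chrom, bin_mask = as.logical(bin_mask)),
    class = "contact_map")
}

#' @export
print.contact_map <- function(x, ...) {
  cat(sprintf("<contact_map> %s: %d bins @ %d bp, %d entries, %d bins retained\n",
              x$chrom, x$n_bins, x$resolution, nrow(x$entries),
              sum(x$bin_mask)))
  invisible(x)
}

#' Read a sparse triplet Hi-C contact map
#'
#' Reads whitespace/tab-delimited triplet text (`pos1 pos2 count`, the format
#' of genome-wide Hi-C "observed" dumps), converting genomic start positions
#' to bin indices. Symmetric duplicates (`(a,b)` and `(b,a)`) are collapsed
#' after checking that their counts agree. Transparent to gzip via
#' [base::gzfile()] file extension handling in [utils::read.table()].
#'
#' @param path Path to the triplet file (optionally gzipped).
#' @param resolution Bin width in bp; positions must be multiples of it.
#' @param chrom Chromosome label to attach.
#' @param n_bins Optional known number of bins; inferred from the maximum
#'   position when omitted (an empty file then raises an error).
#' @return A [contact_map()].
#' @export
read_contact_map <- function(path, resolution, chrom = "chrN", n_bins = NULL) {
  raw <- tryCatch(
    utils::read.table(path, header = FALSE, colClasses = "numeric"),
    error = function(e) {
      if (grepl("no lines available", conditionMessage(e))) {
        data.frame(V1 = numeric(0), V2 = numeric(0), V3 = numeric(0))
      } else {
        stop(sprintf("parse error in '%s': %s", path, conditionMessage(e)),
             call. = FALSE)
      }
    })
  if (ncol(raw) < 3L && nrow(raw) > 0L)
    stop(sprintf("parse error in '%s': expected 3 columns, found %d",
                 path, ncol(raw)), call. = FALSE)
  if (nrow(raw) == 0L) {
    if (is.null(n_bins)) stop("empty contact file and n_bins unknown")
    return(contact_map(data.frame(i = integer(0), j = integer(0),
                                  value = numeric(0)),
                       n_bins, resolution, chrom))
  }
  pos <- as.matrix(raw[, 1:2])
  bad <- which(pos %% resolution != 0)
  if (length(bad))
    stop(sprintf("position not a multiple of resolution %d (first at line %d)",
                 resolution, ((bad[1] - 1L) %% nrow(raw)) + 1L), call. = FALSE)
  if (any(raw[, 3] < 0)) {
    ln <- which(raw[, 3] < 0)[1]
    stop(sprintf("negative count at line %d", ln), call. = FALSE)
  }
  i <- pmin(pos[, 1], pos[, 2]) %/% resolution
  j <- pmax(pos[, 1], pos[, 2]) %/% resolution
  df <- data.frame(i = as.integer(i), j = as.integer(j),
                   value = as.numeric(raw[, 3]))
  key <- paste(df$i, df$j)
  if (anyDuplicated(key)) {
    agree <- tapply(df$value, key, function(v) max(v) - min(v) < 1e-9)
    if (!all(agree))
      stop("symmetric duplicate entries with conflicting counts",
           call. = FALSE)
    df <- df[!duplicated(key), , drop = FALSE]
  }
  nb <- n_bins %||% (max(df$j) + 1L)
  contact_map(df, nb, resolution, chrom)
}

#' Write a contact map as sparse triplet text
#'
#' Inverse of [read_contact_map()]: one `pos1 pos2 count` line per stored
#' unordered pair, positions in bp.
#'
#' @param cm A [contact_map()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_contact_map <- function(cm, path) {
  df <- data.frame(pos1 = cm$entries$i * cm$resolution,
                   pos2 = cm$entries$j * cm$resolution,
                   count = cm$entries$value)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Dense symmetric matrix of a contact map
#' @param cm A [contact_map()].
#' @param retained_only Restrict to bins in `bin_mask`?
#' @return A symmetric numeric matrix (zero where no entry is stored).
#' @export
as_dense_matrix <- function(cm, retained_only = FALSE) {
  m <- matrix(0, cm$n_bins, cm$n_bins)
  if (nrow(cm$entries)) {
    ii <- cm$entries$i + 1L
    jj <- cm$entries$j + 1L
    m[cbind(ii, jj)] <- cm$entries$value
    m[cbind(jj, ii)] <- cm$entries$value
  }
  if (retained_only) m <- m[cm$bin_mask, cm$bin_mask, drop = FALSE]
  m
}

#' Remove low-coverage bins
#'
#' Bins whose total contact count falls at or below `min_row_contacts`
#' (default 0: only bins with no contacts at all) are dropped from
#' `bin_mask` and their entries pruned. Original bin indexing is retained so
#' genomic coordinates stay recoverable. Centromere/telomere bins in real
#' data surface as zero-coverage rows and are removed this way.
#'
#' @param cm A [contact_map()].
#' @param min_row_contacts Minimum total contacts for a bin to be kept.
#' @return The filtered [contact_map()].
#' @export
filter_bins <- function(cm, min_row_contacts = 0) {
  tot <- numeric(cm$n_bins)
  if (nrow(cm$entries)) {
    tot <- tot + as.numeric(tapply(cm$entries$value, factor(cm$entries$i,
                 levels = 0:(cm$n_bins - 1L)), sum, default = 0))
    tot <- tot + as.numeric(tapply(cm$entries$value, factor(cm$entries$j,
                 levels = 0:(cm$n_bins - 1L)), sum, default = 0))
  }
  keep <- cm$bin_mask & tot > 0 & tot >= min_row_contacts
  if (!any(keep)) stop("all bins removed by coverage filter")
  ent <- cm$entries
  ent <- ent[keep[ent$i + 1L] & keep[ent$j + 1L], , drop = FALSE]
  contact_map(ent, cm$n_bins, cm$resolution, cm$chrom, keep)
}

#' Knight-Ruiz matrix balancing
#'
#' Balances the retained sub-matrix of a contact map so that every retained
#' row sums to the same constant (doubly stochastic up to global scale),
#' replacing `IF_ij` with `x_i * IF_ij * x_j` for a positive scaling vector
#' `x`. Uses the inner-outer Newton iteration for symmetric non-negative
#' matrices with a conjugate-gradient inner solve. Rows that cannot be
#' balanced (reducible support) are dropped from `bin_mask` with a warning
#' and the balancing re-run.
#'
#' @param cm A [contact_map()] (run [filter_bins()] first so zero rows are
#'   already masked).
#' @param tol Row-sum tolerance of the balanced matrix.
#' @param max_iter Cap on total inner (matrix-vector) iterations.
#' @return The balanced [contact_map()].
#' @export
kr_normalize <- function(cm, tol = 1e-6, max_iter = 3000L) {
  for (attempt in 1:3) {
    keep <- cm$bin_mask
    A <- as_dense_matrix(cm)[keep, keep, drop = FALSE]
    if (!nrow(A)) stop("no retained bins to balance")
    x <- kr_scaling(A, tol = tol, max_iter = max_iter)
    if (!anyNA(x)) {
      xf <- rep(NA_real_, cm$n_bins)
      xf[keep] <- x
      ent <- cm$entries
      ent$value <- ent$value * xf[ent$i + 1L] * xf[ent$j + 1L]
      ent <- ent[is.finite(ent$value), , drop = FALSE]
      return(contact_map(ent, cm$n_bins, cm$resolution, cm$chrom, keep))
    }
    drop_local <- which(is.na(x))
    drop_global <- which(keep)[drop_local]
    warning(sprintf("KR balancing dropped %d unbalanceable bin(s)",
                    length(drop_global)))
    keep[drop_global] <- FALSE
    if (!any(keep)) stop("KR balancing removed all bins")
    ent <- cm$entries
    ent <- ent[keep[ent$i + 1L] & keep[ent$j + 1L], , drop = FALSE]
    cm <- contact_map(ent, cm$n_bins, cm$resolution, cm$chrom, keep)
  }
  stop("KR balancing failed to converge after repeated row removal")
}

# Inner-outer Newton balancing of a symmetric non-negative matrix.
# Returns the positive scaling vector x with diag(x) A diag(x) doubly
# stochastic, or NA at positions that failed to balance.
#' @keywords internal
kr_scaling <- function(A, tol = 1e-6, max_iter = 3000L) {
  n <- nrow(A)
  if (n == 1L) return(if (A[1, 1] > 0) 1 / sqrt(A[1, 1]) else NA_real_)
  if (any(rowSums(A) == 0)) {
    x <- rep(NA_real_, n)
    return(x)
  }
  e <- rep(1, n)
  x <- e
  delta <- 0.1; Delta <- 3          # interior cone bounds
  g <- 0.9; etamax <- 0.1
  eta <- etamax
  stop_tol <- tol * 0.5
  v <- x * as.vector(A %*% x)
  rk <- 1 - v
  rho_km1 <- sum(rk * rk)
  rout <- rho_km1; rold <- rout
  mvp <- 0L
  while (rout > stop_tol * stop_tol) {
    k <- 0L
    rho_km2 <- NA_real_
    innertol <- max(eta^2 * rout, stop_tol^2)
    y <- e; Z <- NULL; p <- NULL; w <- NULL
    while (rho_km1 > innertol) {       # CG on the Newton system
      k <- k + 1L
      if (k == 1L) {
        Z <- rk / v
        p <- Z
        rho_km1 <- sum(rk * Z)
      } else {
        beta <- rho_km1 / rho_km2
        p <- Z + beta * p
      }
      w <- x * as.vector(A %*% (x * p)) + v * p
      alpha <- rho_km1 / sum(p * w)
      ap <- alpha * p
      ynew <- y + ap
      if (min(ynew) <= delta) {
        if (delta == 0) break
        ind <- ap < 0
        gamma <- min((delta - y[ind]) / ap[ind])
        y <- y + gamma * ap
        break
      }
      if (max(ynew) >= Delta) {
        ind <- ynew > Delta
        gamma <- min((Delta - y[ind]) / ap[ind])
        y <- y + gamma * ap
        break
      }
      y <- ynew
      rk <- rk - alpha * w
      rho_km2 <- rho_km1
      Z <- rk / v
      rho_km1 <- sum(rk * Z)
      mvp <- mvp + 1L
      if (mvp > max_iter) return(rep(NA_real_, n))
    }
    x <- x * y
    v <- x * as.vector(A %*% x)
    rk <- 1 - v
    rho_km1 <- sum(rk * rk)
    rout <- rho_km1
    mvp <- mvp + 1L
    if (mvp > max_iter) return(rep(NA_real_, n))
    rat <- rout / rold; rold <- rout
    res_norm <- sqrt(rout)
    eta <- g * rat
    if (g * eta^2 > 0.1) eta <- max(eta, g * eta^2)
    eta <- max(min(eta, etamax), stop_tol / res_norm)
  }
  x
}
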