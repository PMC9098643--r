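#' 3D structure of ordered genomic bins
#'
#' Ordered `N x 3` coordinates for the bins of one chromosome, rows sorted
#' by genomic position.
#'
#' @param coords Numeric `N x 3` matrix of finite coordinates.
#' @param resolution Bin width in bp.
#' @param bin_starts Genomic start (bp) per row; defaults to
#'   `0, resolution, 2 * resolution, ...`.
#' @param chrom Chromosome label.
#' @return An object of class `structure3d`.
#' @export
structure3d <- function(coords, resolution = NA_integer_, bin_starts = NULL,
                        chrom = "chrN") {
  coords <- as.matrix(coords)
  if (ncol(coords) != 3L) stop("coords must have exactly 3 columns")
  if (!all(is.finite(coords))) stop("coords must be finite")
  coords <- matrix(as.numeric(coords), nrow(coords), 3L)  # drop attributes
  res <- if (is.na(resolution)) 1L else resolution
  bin_starts <- bin_starts %||% ((seq_len(nrow(coords)) - 1L) * res)
  stopifnot(length(bin_starts) == nrow(coords))
  structure(list(coords = unname(coords), resolution = resolution,
                 bin_starts = as.numeric(bin_starts), chrom = chrom),
            class = "structure3d")
}

#' @export
print.structure3d <- function(x, ...) {
  cat(sprintf("<structure3d> %s: %d bins, resolution %s bp\n", x$chrom,
              nrow(x$coords), format(x$resolution)))
  invisible(x)
}

#' Gram matrix of a structure
#'
#' Centers the coordinates at the origin and returns `X = P P^T`. For 3D
#' coordinates the Gram matrix has rank at most 3 and satisfies `X 1 = 0`.
#'
#' @param s A [structure3d()].
#' @return Symmetric `N x N` Gram matrix.
#' @export
gram_from_coords <- function(s) {
  P <- scale(s$coords, center = TRUE, scale = FALSE)
  tcrossprod(P)
}

#' Squared Euclidean distance matrix from a Gram matrix
#'
#' `D_ij = X_ii + X_jj - 2 X_ij`. A squared EDM generated by 3D points has
#' rank at most 5: it is the sum of the rank-<=3 Gram term and two rank-1
#' terms.
#'
#' @param g Symmetric Gram matrix.
#' @return Symmetric squared-distance matrix with zero diagonal.
#' @export
sq_edm_from_gram <- function(g) {
  g <- as.matrix(g)
  dg <- diag(g)
  D <- outer(dg, dg, "+") - 2 * g
  diag(D) <- 0
  D
}

#' Squared EDM of a structure
#' @param s A [structure3d()].
#' @return Symmetric matrix of squared pairwise distances.
#' @export
sq_edm_from_structure <- function(s) {
  sq_edm_from_gram(gram_from_coords(s))
}

#' Recover coordinates from an (approximate) Gram matrix
#'
#' Eigendecomposes `g`, clips negative eigenvalues at zero (the closest-PSD
#' projection in spectral terms; solver iterates need not be exactly PSD) and
#' returns the top-3 spectral coordinates. When `g` is PSD with rank <= 3 the
#' squared EDM of the result reproduces that of `g` exactly.
#'
#' @param g Symmetric, approximately PSD matrix.
#' @param resolution,bin_starts,chrom Passed to [structure3d()].
#' @return A [structure3d()].
#' @export
coords_from_gram <- function(g, resolution = NA_integer_, bin_starts = NULL,
                             chrom = "chrN") {
  g <- (g + t(g)) / 2
  eg <- eigen(g, symmetric = TRUE)
  ev <- pmax(eg$values[1:3], 0)
  if (sum(eg$values > 1e-12 * max(abs(eg$values), 1)) < 3L)
    warning("Gram matrix has fewer than 3 positive eigenvalues; padding zeros")
  P <- eg$vectors[, 1:3, drop = FALSE] %*% diag(sqrt(ev), 3)
  structure3d(P, resolution, bin_starts, chrom)
}

#' Center and scale a structure to unit Frobenius norm
#'
#' `P_scaled = P / ||P||_F` after centering the coordinates; puts structures
#' from different sources on a common scale before comparison.
#'
#' @param s A [structure3d()].
#' @return The normalized [structure3d()].
#' @export
normalize_structure <- function(s) {
  P <- scale(s$coords, center = TRUE, scale = FALSE)
  fn <- sqrt(sum(P^2))
  if (fn == 0) stop("degenerate structure: all points identical")
  structure3d(P / fn, s$resolution, s$bin_starts, s$chrom)
}

#' Orthogonal (Procrustes) alignment of one structure onto another
#'
#' Finds the orthogonal matrix minimizing the Frobenius distance between
#' `moving` and `reference` via SVD of the cross-covariance. Reflections are
#' allowed by default because distance data cannot determine chirality; set
#' `allow_reflection = FALSE` to restrict to proper rotations (e.g. for
#' comparisons against imaging data with known handedness).
#'
#' @param moving,reference [structure3d()] objects with equal bin counts,
#'   both centered/normalized by the caller as appropriate.
#' @param allow_reflection Permit determinant -1 solutions?
#' @return `moving` transformed by the optimal orthogonal matrix.
#' @export
procrustes_align <- function(moving, reference, allow_reflection = TRUE) {
  A <- moving$coords
  B <- reference$coords
  if (!all(dim(A) == dim(B))) stop("structures must have equal dimensions")
  sv <- svd(crossprod(A, B))
  R <- sv$u %*% t(sv$v)
  if (!allow_reflection && det(R) < 0) {
    u <- sv$u
    u[, 3] <- -u[, 3]
    R <- u %*% t(sv$v)
  }
  structure3d(A %*% R, moving$resolution, moving$bin_starts, moving$chrom)
}

#' Write / read a structure as TSV
#'
#' Columns `chrom`, `start`, `end`, `x`, `y`, `z`, one row per bin.
#'
#' @param s A [structure3d()].
#' @param path File path.
#' @return `path` invisibly (writer); a [structure3d()] (reader).
#' @export
write_structure <- function(s, path) {
  res <- if (is.na(s$resolution)) 1L else s$resolution
  df <- data.frame(chrom = s$chrom, start = s$bin_starts,
                   end = s$bin_starts + res,
                   x = s$coords[, 1], y = s$coords[, 2], z = s$coords[, 3])
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE)
  invisible(path)
}

#' @rdname write_structure
#' @export
read_structure <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t")
  res <- if (nrow(df) > 1L) df$end[1] - df$start[1] else NA_integer_
  structure3d(as.matrix(df[, c("x", "y", "z")]), res, df$start, df$chrom[1])
}
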