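#' Local curvature profile of a chromatin structure
#'
#' For each interior bin, a quadratic parametric curve
#' `r(t) = (x(t), y(t), z(t))` is least-squares fitted through the bin and
#' its two upstream and two downstream neighbors (window of 5 bins,
#' `t = -2, ..., 2` in bin index units), and the curvature
#' `kappa = |r'' x r'| / |r'|^3` is evaluated at the central bin (`t = 0`).
#' High values mark sharp chromatin bends. The first and last `fit_window`
#' bins are undefined (`NA`). `normalized_kappa` divides by the
#' per-chromosome median over defined bins, for fair comparison across
#' chromosomes.
#'
#' @param s A [structure3d()] with at least 5 bins.
#' @param fit_window Half-width of the fit window in bins (default 2).
#' @return A data frame of class `curvature_profile` with columns `chrom`,
#'   `start`, `end`, `kappa`, `normalized_kappa`.
#' @export
curvature_profile <- function(s, fit_window = 2L) {
  P <- s$coords
  n <- nrow(P)
  w <- as.integer(fit_window)
  if (n < 2L * w + 1L) stop("need at least 2 * fit_window + 1 bins")
  t <- seq(-w, w)
  Tm <- cbind(1, t, t^2)
  # pseudo-inverse of the quadratic design, shared by every window and axis
  Tpinv <- solve(crossprod(Tm), t(Tm))
  kappa <- rep(NA_real_, n)
  for (b in (w + 1L):(n - w)) {
    coef <- Tpinv %*% P[(b - w):(b + w), , drop = FALSE]  # 3 x 3: a0, a1, a2 rows
    r1 <- coef[2L, ]            # r'(0)
    r2 <- 2 * coef[3L, ]        # r''(0)
    speed <- sqrt(sum(r1^2))
    if (speed == 0) next        # stationary fit: curvature undefined
    cr <- c(r1[2] * r2[3] - r1[3] * r2[2],
            r1[3] * r2[1] - r1[1] * r2[3],
            r1[1] * r2[2] - r1[2] * r2[1])
    kappa[b] <- sqrt(sum(cr^2)) / speed^3
  }
  med <- stats::median(kappa, na.rm = TRUE)
  res <- if (is.na(s$resolution)) 1L else s$resolution
  out <- data.frame(chrom = s$chrom, start = s$bin_starts,
                    end = s$bin_starts + res, kappa = kappa,
                    normalized_kappa = kappa / med)
  class(out) <- c("curvature_profile", "data.frame")
  out
}

#' Write a curvature profile as BED-like TSV
#' @param cp A [curvature_profile()].
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_curvature <- function(cp, path) {
  utils::write.table(cp, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
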