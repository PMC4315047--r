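#' Bonferroni-corrected correlation floor
#'
#' Returns the smallest Pearson correlation whose two-sided p-value (via the
#' t transform with `n_timepoints - 2` degrees of freedom) reaches
#' `alpha / n_tests`. Correlations below this floor are treated as spurious
#' and contribute nothing to weighted degree centrality.
#'
#' @param alpha Family-wise significance level (default 0.05).
#' @param n_tests Number of tests the correction divides over. For a
#'   per-voxel (per-row) framing this is `N - 1`; a whole-brain pairwise
#'   framing would use `N (N - 1) / 2`.
#' @param n_timepoints Length of the correlated time series; must exceed 3.
#' @return The correlation floor in `(0, 1]`.
#' @export
bonferroni_r_threshold <- function(alpha = 0.05, n_tests, n_timepoints) {
  if (!(alpha > 0 && alpha < 1)) stop("alpha must be in (0, 1)")
  if (n_timepoints <= 3) stop("need more than 3 time points")
  p <- alpha / n_tests
  if (p <= 0 || !is.finite(p)) {
    warning("alpha / n_tests underflows to zero; returning a floor of 1")
    return(1)
  }
  df <- n_timepoints - 2
  tcrit <- stats::qt(1 - p / 2, df = df)
  if (!is.finite(tcrit)) {
    warning("t quantile not finite at this correction level; returning 1")
    return(1)
  }
  tcrit / sqrt(df + tcrit^2)
}

#' Voxel-wise weighted degree centrality
#'
#' For every in-mask voxel i, sums the Pearson correlations r_ij with all
#' other in-mask voxels j that survive the Bonferroni-corrected
#' significance floor; negative and sub-threshold correlations contribute
#' zero, and the self-correlation is excluded. The correlation matrix is
#' processed in row blocks so memory stays bounded on large masks.
#'
#' @param series Voxel x time numeric matrix of in-mask series, or a
#'   [bold_run()] (its in-mask voxels are used, in mask order).
#' @param mask Optional 3D logical mask; required when `series` is a matrix
#'   and a spatial map output is wanted.
#' @param alpha Family-wise level for [bonferroni_r_threshold()] (default
#'   0.05).
#' @param n_tests_mode `"per_voxel"` (default; `N - 1` tests) or
#'   `"pairwise"` (`N (N - 1) / 2` tests).
#' @param block_size Rows per correlation block (default 512).
#' @return An object of class `centrality_map`: `values` (per retained
#'   voxel), `map` (3D array, `NA` outside mask, when a mask is known),
#'   `r_threshold`, `n_voxels`, and the indices of any constant voxels that
#'   were removed from the mask.
#' @export
compute_wdc_map <- function(series, mask = NULL, alpha = 0.05,
                            n_tests_mode = c("per_voxel", "pairwise"),
                            block_size = 512L) {
  n_tests_mode <- match.arg(n_tests_mode)
  if (inherits(series, "bold_run")) {
    mask <- series$mask
    series <- masked_series(series$data, series$mask)
  }
  series <- as.matrix(series)
  if (nrow(series) == 0L) stop("mask is empty: no voxel series to correlate")
  t_len <- ncol(series)
  sds <- apply(series, 1L, stats::sd)
  const <- which(sds == 0 | !is.finite(sds))
  if (length(const) > 0L) {
    warning(sprintf("removing %d constant voxel(s) from the mask", length(const)))
    series <- series[-const, , drop = FALSE]
    if (nrow(series) == 0L) stop("mask is empty after removing constant voxels")
  }
  n_vox <- nrow(series)
  if (n_vox < 2L) stop("need at least 2 non-constant voxels")
  n_tests <- if (n_tests_mode == "per_voxel") n_vox - 1 else n_vox * (n_vox - 1) / 2
  r_thr <- bonferroni_r_threshold(alpha, n_tests, t_len)

  z <- series - rowMeans(series)
  z <- z / sqrt(rowSums(z^2))
  s <- numeric(n_vox)
  starts <- seq(1L, n_vox, by = block_size)
  for (b in starts) {
    rows <- b:min(b + block_size - 1L, n_vox)
    rblk <- z[rows, , drop = FALSE] %*% t(z)           # block of correlations
    rblk[rblk < r_thr] <- 0
    # remove the self term (r_ii = 1 always survives the floor)
    rblk[cbind(seq_along(rows), rows)] <- 0
    s[rows] <- rowSums(rblk)
  }

  map <- NULL
  if (!is.null(mask)) {
    retained <- which(as.vector(mask))
    if (length(const) > 0L) retained <- retained[-const]
    full <- rep(NA_real_, prod(dim(mask)))
    full[retained] <- s
    map <- array(full, dim = dim(mask))
  }
  structure(
    list(values = s, map = map, r_threshold = r_thr, n_voxels = n_vox,
         alpha = alpha, n_tests_mode = n_tests_mode,
         dropped_constant = const),
    class = "centrality_map"
  )
}

#' @export
print.centrality_map <- function(x, ...) {
  cat(sprintf("<centrality_map> %d voxels, r floor %.4f (%s Bonferroni), WDC range [%.3f, %.3f]\n",
              x$n_voxels, x$r_threshold, x$n_tests_mode,
              min(x$values), max(x$values)))
  invisible(x)
}
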