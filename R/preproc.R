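#' Construct a BOLD run object
#'
#' A `bold_run` bundles one subject's 4D voxel time series with its brain
#' mask, repetition time and voxel geometry. All temporal operations in the
#' package consume and return this container.
#'
#' @param data 4D numeric array (x, y, z, t).
#' @param mask 3D logical array matching the spatial dimensions of `data`.
#'   Defaults to all-`TRUE`.
#' @param tr Repetition time in seconds.
#' @param voxel_size Voxel edge lengths in mm (length 1 or 3).
#' @param affine 4x4 voxel-to-mm affine (0-based voxel indices). Defaults to
#'   a diagonal affine with the origin at the grid centre.
#' @return An object of class `bold_run`.
#' @export
bold_run <- function(data, mask = NULL, tr, voxel_size = c(3, 3, 3),
                     affine = NULL) {
  d <- dim(data)
  if (length(d) != 4L) stop("`data` must be a 4D array (x, y, z, t)")
  if (d[4L] < 2L) stop("a BOLD run needs at least 2 volumes")
  if (is.null(mask)) mask <- array(TRUE, dim = d[1:3])
  if (!identical(dim(mask), d[1:3])) {
    stop("mask shape must equal the spatial shape of the data")
  }
  if (!is.numeric(tr) || tr <= 0) stop("`tr` must be a positive number")
  voxel_size <- rep(as.numeric(voxel_size), length.out = 3L)
  if (any(voxel_size <= 0)) stop("voxel sizes must be positive")
  if (is.null(affine)) affine <- default_affine(d[1:3], voxel_size)
  structure(
    list(data = data, mask = array(as.logical(mask), dim = d[1:3]),
         tr = tr, voxel_size = voxel_size, affine = affine),
    class = "bold_run"
  )
}

#' @export
print.bold_run <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<bold_run> %d x %d x %d grid, %d volumes, TR = %g s, %d mask voxels\n",
              d[1], d[2], d[3], d[4], x$tr, sum(x$mask)))
  invisible(x)
}

n_volumes <- function(run) dim(run$data)[4L]

nyquist <- function(run) 1 / (2 * run$tr)

#' Drop leading volumes from a run
#'
#' Scanner signal needs several volumes to reach steady state; the
#' conventional remedy is to discard the first few volumes before any
#' temporal processing.
#'
#' @param run A [bold_run()].
#' @param n Number of leading volumes to drop (default 5).
#' @return The truncated `bold_run`.
#' @export
drop_volumes <- function(run, n = 5L) {
  stopifnot(inherits(run, "bold_run"))
  t <- n_volumes(run)
  if (n < 0 || n >= t - 1) stop("cannot drop ", n, " of ", t, " volumes")
  if (n == 0L) return(run)
  run$data <- run$data[, , , -(seq_len(n)), drop = FALSE]
  run
}

# Ideal (rectangular) frequency-domain band-pass on a voxel x time matrix.
# Frequencies strictly outside [low, high] are zeroed, including DC when
# low > 0. Exactly idempotent.
ideal_bandpass <- function(mat, tr, low, high) {
  t <- ncol(mat)
  freqs <- seq(0, t - 1) / (t * tr)
  freqs <- pmin(freqs, 1 / tr - freqs)  # two-sided spectrum folding
  keep <- freqs >= low & freqs <= high
  ft <- stats::mvfft(t(mat))
  ft[!keep, ] <- 0
  t(Re(stats::mvfft(ft, inverse = TRUE))) / t
}

# Remove per-row linear trend (intercept + slope on scan index)
detrend_linear <- function(mat) {
  t <- ncol(mat)
  x <- cbind(1, seq_len(t))
  beta <- t(qr.coef(qr(x), t(mat)))
  mat - beta %*% t(x)
}

#' Detrend and band-pass filter a BOLD run
#'
#' Removes each in-mask voxel's linear trend, then applies an ideal
#' (rectangular) frequency-domain band-pass: Fourier coefficients outside
#' `[low, high]` Hz are zeroed. The rectangular filter is exactly idempotent
#' and matches the convention of resting-state connectivity toolboxes. An
#' optional Butterworth mode (forward-backward, order 4) is provided for
#' users who prefer a smooth transition band.
#'
#' @param run A [bold_run()].
#' @param low,high Pass-band edges in Hz; `0 <= low < high <= 1/(2 tr)`.
#' @param detrend Remove the linear trend first (default `TRUE`).
#' @param method `"ideal"` (default) or `"butterworth"`.
#' @return A `bold_run` with filtered in-mask series; voxels outside the mask
#'   are untouched.
#' @export
filter_timeseries <- function(run, low = 0.01, high = 0.1, detrend = TRUE,
                              method = c("ideal", "butterworth")) {
  stopifnot(inherits(run, "bold_run"))
  method <- match.arg(method)
  nyq <- nyquist(run)
  if (low < 0 || low >= high) stop("need 0 <= low < high")
  if (high > nyq + 1e-12) {
    stop(sprintf("high edge %g Hz exceeds the Nyquist frequency %g Hz", high, nyq))
  }
  mat <- masked_series(run$data, run$mask)
  if (detrend) mat <- detrend_linear(mat)
  if (method == "ideal") {
    mat <- ideal_bandpass(mat, run$tr, low, high)
  } else {
    bf <- signal::butter(2L, c(low, high) / nyq, type = "pass")
    mat <- t(apply(mat, 1L, function(x) signal::filtfilt(bf, x)))
  }
  d <- dim(run$data)
  out <- matrix(run$data, nrow = prod(d[1:3]), ncol = d[4L])
  out[as.vector(run$mask), ] <- mat
  run$data <- array(out, dim = d)
  run
}

# Friston-24 expansion: 6 parameters, their one-volume lag, and both squared
friston24 <- function(motion6) {
  motion6 <- as.matrix(motion6)
  if (ncol(motion6) != 6L) stop("motion table must have 6 columns")
  lag <- rbind(0, motion6[-nrow(motion6), , drop = FALSE])
  cbind(motion6, lag, motion6^2, lag^2)
}

#' Regress nuisance signals out of a BOLD run
#'
#' Removes, per voxel, the least-squares fit on an intercept, the Friston-24
#' head-motion expansion (6 rigid-body parameters, their one-volume lag, and
#' both squared) and the mean white-matter and cerebrospinal-fluid time
#' series. Collinear design columns are dropped (with a warning) via
#' pivoted QR before fitting.
#'
#' @param run A [bold_run()].
#' @param motion6 Motion table with one row per volume and 6 columns
#'   (3 translations in mm, 3 rotations in radians).
#' @param wm_mask,csf_mask Optional 3D logical arrays selecting white-matter
#'   and CSF voxels; their mean series are added as confounds.
#' @return A `bold_run` of residual series (mean removed).
#' @export
nuisance_regress <- function(run, motion6, wm_mask = NULL, csf_mask = NULL) {
  stopifnot(inherits(run, "bold_run"))
  t <- n_volumes(run)
  motion6 <- as.matrix(motion6)
  if (nrow(motion6) != t) {
    stop(sprintf("motion table has %d rows but the run has %d volumes",
                 nrow(motion6), t))
  }
  x <- cbind(intercept = 1, friston24(motion6))
  for (nm in c("wm", "csf")) {
    m <- if (nm == "wm") wm_mask else csf_mask
    if (!is.null(m)) {
      if (!identical(dim(m), dim(run$mask))) stop(nm, " mask shape mismatch")
      x <- cbind(x, colMeans(masked_series(run$data, m)))
    }
  }
  qx <- qr(x)
  if (qx$rank < ncol(x)) {
    drop <- qx$pivot[(qx$rank + 1L):ncol(x)]
    warning(sprintf("dropping %d collinear confound column(s): %s",
                    length(drop), paste(drop, collapse = ", ")))
    x <- x[, qx$pivot[seq_len(qx$rank)], drop = FALSE]
    qx <- qr(x)
  }
  mat <- masked_series(run$data, run$mask)
  resid <- t(qr.resid(qx, t(mat)))
  d <- dim(run$data)
  out <- matrix(run$data, nrow = prod(d[1:3]), ncol = d[4L])
  out[as.vector(run$mask), ] <- resid
  run$data <- array(out, dim = d)
  run
}

#' Head-motion summary scalars
#'
#' Computes the gross and micro head-motion summaries used as group-analysis
#' covariates: the maximum and root-mean-square Euclidean translation norm,
#' and the mean frame-wise displacement (FD). FD for a volume pair is the
#' sum of absolute backward differences of the six rigid-body parameters,
#' with rotations (radians) converted to arc length on a 50-mm sphere.
#'
#' @param motion6 Motion table, one row per volume: 3 translations (mm) then
#'   3 rotations (radians).
#' @param head_radius Sphere radius in mm for the rotation conversion
#'   (default 50).
#' @return A list of class `motion_summary` with `max_disp`, `rms_disp` and
#'   `mean_fd` (all mm).
#' @export
motion_summaries <- function(motion6, head_radius = 50) {
  motion6 <- as.matrix(motion6)
  if (ncol(motion6) != 6L) stop("motion table must have 6 columns")
  if (nrow(motion6) < 2L) stop("need at least 2 volumes")
  disp <- sqrt(rowSums(motion6[, 1:3, drop = FALSE]^2))
  d <- abs(diff(motion6))
  fd <- rowSums(d[, 1:3, drop = FALSE]) + head_radius * rowSums(d[, 4:6, drop = FALSE])
  structure(
    list(max_disp = max(disp), rms_disp = sqrt(mean(disp^2)), mean_fd = mean(fd)),
    class = "motion_summary"
  )
}

#' @export
print.motion_summary <- function(x, ...) {
  cat(sprintf("<motion_summary> max %.3f mm, rms %.3f mm, mean FD %.4f mm\n",
              x$max_disp, x$rms_disp, x$mean_fd))
  invisible(x)
}

#' Full temporal preprocessing of one run
#'
#' Applies the fixed in-scope temporal pipeline: drop leading volumes,
#' per-voxel linear detrend, ideal band-pass, nuisance regression
#' (Friston-24 + mean WM + mean CSF). The motion table is truncated in step
#' with the dropped volumes. Spatial steps (slice timing, realignment,
#' normalization, smoothing) are out of scope: inputs are assumed aligned to
#' a common grid, and smoothing is deliberately not offered because it
#' induces spurious local correlations in voxel-wise centrality.
#'
#' @param run A [bold_run()].
#' @param motion6 Motion table (rows = volumes of `run`).
#' @param wm_mask,csf_mask Optional confound masks.
#' @param band Pass band in Hz (default `c(0.01, 0.1)`).
#' @param drop_first Leading volumes to discard (default 5).
#' @return A list with the cleaned `run`, the truncated `motion` table and
#'   the [motion_summaries()] of the retained volumes.
#' @export
preprocess_run <- function(run, motion6, wm_mask = NULL, csf_mask = NULL,
                           band = c(0.01, 0.1), drop_first = 5L) {
  stopifnot(inherits(run, "bold_run"))
  motion6 <- as.matrix(motion6)
  if (nrow(motion6) != n_volumes(run)) {
    stop("motion table rows must match the number of volumes before dropping")
  }
  if (drop_first > 0L) {
    run <- drop_volumes(run, drop_first)
    motion6 <- motion6[-(seq_len(drop_first)), , drop = FALSE]
  }
  run <- filter_timeseries(run, band[1], band[2], detrend = TRUE)
  run <- nuisance_regress(run, motion6, wm_mask, csf_mask)
  list(run = run, motion = motion6, summary = motion_summaries(motion6))
}
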