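#' Define a spherical seed region of interest
#'
#' Selects the in-mask voxels whose centres lie within `radius_mm` of a
#' centre given in mm coordinates. Distances are computed centre-to-centre
#' through the image affine, so a 6-mm sphere on a 3-mm isotropic grid
#' contains the 33 voxels whose integer offsets satisfy
#' i^2 + j^2 + k^2 <= 4.
#'
#' @param center_mm Length-3 centre in mm.
#' @param radius_mm Sphere radius in mm.
#' @param mask 3D logical array.
#' @param affine 4x4 voxel-to-mm affine (0-based voxel indices); defaults to
#'   a centred isotropic affine built from `voxel_size`.
#' @param voxel_size Voxel edge lengths (used only when `affine` is `NULL`).
#' @param name Optional label carried through reports.
#' @return An object of class `sphere_roi` with `center_mm`, `radius_mm`,
#'   `voxel_set` (linear indices into the grid) and `name`.
#' @export
make_sphere_roi <- function(center_mm, radius_mm, mask, affine = NULL,
                            voxel_size = c(3, 3, 3), name = NULL) {
  dim3 <- dim(mask)
  if (is.null(affine)) affine <- default_affine(dim3, voxel_size)
  idx <- which(as.vector(mask))
  if (length(idx) == 0L) stop("mask is empty")
  ijk <- coords_from_index(idx, dim3)
  xyz <- voxel_to_mm(ijk, affine)
  d2 <- (xyz[, 1] - center_mm[1])^2 + (xyz[, 2] - center_mm[2])^2 +
    (xyz[, 3] - center_mm[3])^2
  member <- idx[d2 <= radius_mm^2 + 1e-9]
  if (length(member) == 0L) {
    stop(sprintf("sphere at (%g, %g, %g) mm, radius %g mm, contains no in-mask voxel",
                 center_mm[1], center_mm[2], center_mm[3], radius_mm))
  }
  structure(
    list(center_mm = as.numeric(center_mm), radius_mm = radius_mm,
         voxel_set = member, name = name),
    class = "sphere_roi"
  )
}

#' @export
print.sphere_roi <- function(x, ...) {
  cat(sprintf("<sphere_roi>%s centre (%g, %g, %g) mm, radius %g mm, %d voxels\n",
              if (is.null(x$name)) "" else paste0(" ", x$name),
              x$center_mm[1], x$center_mm[2], x$center_mm[3],
              x$radius_mm, length(x$voxel_set)))
  invisible(x)
}

#' Mean time series of a spherical ROI
#'
#' @param run A [bold_run()].
#' @param roi A [make_sphere_roi()] result on the same grid.
#' @return Numeric vector, the unweighted mean over member voxels at each
#'   time point.
#' @export
extract_roi_timeseries <- function(run, roi) {
  stopifnot(inherits(run, "bold_run"), inherits(roi, "sphere_roi"))
  d <- dim(run$data)
  if (any(roi$voxel_set > prod(d[1:3]))) stop("ROI voxels outside the run grid")
  mat <- matrix(run$data, nrow = prod(d[1:3]), ncol = d[4L])
  colMeans(mat[roi$voxel_set, , drop = FALSE])
}

#' Seed-to-voxel functional connectivity map
#'
#' Correlates the ROI mean time series with every in-mask voxel and applies
#' Fisher's r-to-z transform. Correlations are clipped to
#' +/-(1 - 1e-7) before `atanh` so the map is finite everywhere; constant
#' voxels get z = 0 and are reported in the `flagged` field.
#'
#' @param run A [bold_run()].
#' @param roi A [make_sphere_roi()].
#' @param mask Optional 3D logical mask (defaults to the run's mask).
#' @return An object of class `fc_map`: `z_values` per in-mask voxel, `map`
#'   (3D array, `NA` outside mask), `seed`, `flagged` (indices of constant
#'   voxels).
#' @export
seed_fc_map <- function(run, roi, mask = NULL) {
  stopifnot(inherits(run, "bold_run"), inherits(roi, "sphere_roi"))
  if (is.null(mask)) mask <- run$mask
  seed_ts <- extract_roi_timeseries(run, roi)
  if (stats::sd(seed_ts) == 0) stop("seed mean series is constant")
  mat <- masked_series(run$data, mask)
  sds <- apply(mat, 1L, stats::sd)
  const <- which(sds == 0 | !is.finite(sds))
  zc <- mat - rowMeans(mat)
  den <- sqrt(rowSums(zc^2))
  den[den == 0] <- 1
  sc <- seed_ts - mean(seed_ts)
  r <- as.vector(zc %*% sc) / (den * sqrt(sum(sc^2)))
  r[const] <- 0
  clip <- 1 - 1e-7
  z <- atanh(pmin(pmax(r, -clip), clip))
  z[const] <- 0
  structure(
    list(z_values = z, map = unmask_map(z, mask), seed = roi, flagged = const),
    class = "fc_map"
  )
}

#' @export
print.fc_map <- function(x, ...) {
  cat(sprintf("<fc_map> %d voxels, z range [%.3f, %.3f]%s\n",
              length(x$z_values), min(x$z_values), max(x$z_values),
              if (length(x$flagged)) sprintf(", %d constant voxel(s) zeroed",
                                             length(x$flagged)) else ""))
  invisible(x)
}

#' Count shared voxels between two spherical ROIs
#'
#' @param roi_a,roi_b [make_sphere_roi()] objects on the same grid.
#' @return Integer count of shared voxel indices.
#' @export
roi_overlap <- function(roi_a, roi_b) {
  length(intersect(roi_a$voxel_set, roi_b$voxel_set))
}

#' Greedily drop spatially overlapping ROIs
#'
#' Walks the ROI list in order and keeps an ROI only if it shares no voxel
#' with any ROI already kept; the later-listed member of an overlapping
#' pair is dropped. The rule is deterministic and logged via the returned
#' `dropped` attribute.
#'
#' @param rois List of [make_sphere_roi()] objects.
#' @return The retained sublist, with attribute `dropped` holding the
#'   indices of excluded ROIs.
#' @export
drop_overlapping_rois <- function(rois) {
  keep <- list()
  dropped <- integer(0)
  for (i in seq_along(rois)) {
    if (any(vapply(keep, function(k) roi_overlap(k, rois[[i]]) > 0L, logical(1)))) {
      dropped <- c(dropped, i)
    } else {
      keep[[length(keep) + 1L]] <- rois[[i]]
    }
  }
  attr(keep, "dropped") <- dropped
  keep
}
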