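#' @keywords internal
"_PACKAGE"

# Derive a stream-specific seed from a master seed. Keeps derived seeds in
# 32-bit integer range so set.seed() accepts them on every platform.
subseed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  as.integer((as.double(seed) * 7919 + stream * 104729) %% 2147483629)
}

# Convert 1-based voxel indices (n x 3) to mm coordinates using a NIfTI-style
# affine (maps 0-based voxel indices to mm).
voxel_to_mm <- function(ijk, affine) {
  ijk <- matrix(as.numeric(ijk), ncol = 3L)
  xyz1 <- cbind(ijk - 1, 1) %*% t(affine)
  xyz1[, 1:3, drop = FALSE]
}

# Default affine for an isotropic grid: diagonal voxel sizes, origin at the
# grid centre so coordinates behave like MNI-style mm offsets.
default_affine <- function(grid_shape, voxel_size) {
  voxel_size <- rep(voxel_size, length.out = 3L)
  aff <- diag(c(voxel_size, 1))
  aff[1:3, 4] <- -voxel_size * (grid_shape - 1) / 2
  aff
}

# Linear index helpers for 3D grids
coords_from_index <- function(idx, dim3) {
  idx0 <- idx - 1L
  i <- idx0 %% dim3[1L]
  j <- (idx0 %/% dim3[1L]) %% dim3[2L]
  k <- idx0 %/% (dim3[1L] * dim3[2L])
  cbind(i + 1L, j + 1L, k + 1L)
}

index_from_coords <- function(ijk, dim3) {
  (ijk[, 3L] - 1L) * dim3[1L] * dim3[2L] + (ijk[, 2L] - 1L) * dim3[1L] + ijk[, 1L]
}

# Extract the masked voxel x time matrix from a 4D array
masked_series <- function(data4d, mask) {
  d <- dim(data4d)
  mat <- matrix(data4d, nrow = prod(d[1:3]), ncol = d[4L])
  mat[as.vector(mask), , drop = FALSE]
}

# Write a voxel-vector back into a 3D array (NA outside mask)
unmask_map <- function(values, mask, fill = NA_real_) {
  out <- array(fill, dim = dim(mask))
  out[mask] <- values
  out
}
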