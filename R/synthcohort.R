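#' Configuration for a synthetic two-group BOLD cohort
#'
#' Defines the generative regime for a simulated resting-state cohort of
#' controls (group A) and patients (group B): grid geometry, scan length,
#' band-limited region covariance structure, a planted group effect on the
#' inter-regional covariance, planted hub voxels, voxel noise, and the
#' coupling between each clinical score and a per-subject latent
#' connectivity strength.
#'
#' The defaults emulate a typical tremor-dominant Parkinson's disease
#' resting-state study: 20 controls vs 16 patients, 180 volumes at
#' TR = 2 s band-limited to 0.01-0.1 Hz, and a diffuse positive increment
#' of inter-regional coupling in the patient group.
#'
#' @param n_group_a Number of control subjects (default 20).
#' @param n_group_b Number of patient subjects (default 16).
#' @param grid_shape Voxel counts per axis (default `c(12, 12, 12)`).
#' @param voxel_size Voxel edge length in mm (default 3, isotropic).
#' @param n_volumes Volumes per run (default 180).
#' @param tr Repetition time in seconds (default 2).
#' @param band Pass band in Hz (default `c(0.01, 0.1)`).
#' @param n_regions Number of contiguous slab regions the grid is split into
#'   (default 8). Ignored when `base_cov` has other dimensions.
#' @param base_cov Region-level covariance (correlation) matrix; default
#'   equicorrelation 0.3 across `n_regions` regions.
#' @param effect_delta Additive covariance increment applied for group B;
#'   default a uniform +0.15 on every off-diagonal pair (a widespread
#'   connectivity increase, modulated per subject by a latent severity).
#' @param hub_voxels Matrix of 1-based voxel coordinates of planted hub
#'   voxels (default: the single grid-centre voxel). Hubs carry the average
#'   of all region signals and therefore attain the largest expected
#'   correlation sum.
#' @param noise_sd Standard deviation of the white voxel noise relative to
#'   the unit-variance band-limited region signal (default 1).
#' @param motion_sd Random-walk step SD for translations in mm (default
#'   0.02); rotation steps are `motion_sd / 60` radians.
#' @param motion_bound Reflecting bound on translations in mm; rotations are
#'   bounded at `motion_bound * pi / 180` radians. Default 2.7 mm, safely
#'   inside the conventional 3 mm / 3 degree exclusion rule.
#' @param score_coupling Named list describing the clinical scores. Each
#'   entry has `center`, `slope` (per unit latent), `sd` (noise) and `range`
#'   (clipping bounds); defaults emulate illness duration (years), tremor
#'   level (1-4), H-Y stage (1-3), UPDRS (4-49) and MMSE (29-30).
#' @param seed Master integer seed; every random draw in the cohort is
#'   derived from it via a fixed splitting scheme.
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_group_a = 20L, n_group_b = 16L,
                             grid_shape = c(12L, 12L, 12L), voxel_size = 3,
                             n_volumes = 180L, tr = 2, band = c(0.01, 0.1),
                             n_regions = 8L, base_cov = NULL,
                             effect_delta = NULL, hub_voxels = NULL,
                             noise_sd = 1, motion_sd = 0.02,
                             motion_bound = 2.7,
                             score_coupling = default_score_coupling(),
                             seed = 1L) {
  if (is.null(base_cov)) {
    base_cov <- modular_base_cov(n_regions)
  }
  n_regions <- nrow(base_cov)
  if (is.null(effect_delta)) {
    effect_delta <- matrix(0.15, n_regions, n_regions)
    diag(effect_delta) <- 0
  }
  if (is.null(hub_voxels)) {
    hub_voxels <- matrix(ceiling(grid_shape / 2), nrow = 1L)
  }
  hub_voxels <- matrix(as.integer(hub_voxels), ncol = 3L)
  cfg <- structure(
    list(n_group_a = as.integer(n_group_a), n_group_b = as.integer(n_group_b),
         grid_shape = as.integer(grid_shape), voxel_size = voxel_size,
         n_volumes = as.integer(n_volumes), tr = tr, band = band,
         n_regions = as.integer(n_regions), base_cov = base_cov,
         effect_delta = effect_delta, hub_voxels = hub_voxels,
         noise_sd = noise_sd, motion_sd = motion_sd,
         motion_bound = motion_bound, score_coupling = score_coupling,
         seed = as.integer(seed)),
    class = "synthetic_config"
  )
  validate_synthetic_config(cfg)
  cfg
}

#' Modular region covariance matrix
#'
#' Block-structured correlation matrix: regions are split into
#' `n_modules` equal modules with correlation `r_within` inside a module
#' and `r_between` across modules. Resting-state ROI networks are modular,
#' and this structure is what makes the thresholded graphs small-world
#' (clustered yet short-pathed) rather than Erdos-Renyi-like.
#'
#' @param n_regions Number of regions.
#' @param r_within,r_between Within-/between-module correlation (defaults
#'   0.45 / 0.15).
#' @param n_modules Number of modules (default 2).
#' @return A symmetric positive semi-definite correlation matrix.
#' @export
modular_base_cov <- function(n_regions, r_within = 0.45, r_between = 0.15,
                             n_modules = 2L) {
  mod <- ceiling(seq_len(n_regions) * n_modules / n_regions)
  same <- outer(mod, mod, `==`)
  m <- ifelse(same, r_within, r_between)
  diag(m) <- 1
  m
}

default_score_coupling <- function() {
  list(
    duration = list(center = 2.5, slope = 1.2, sd = 0.8, range = c(0.4, 6)),
    tremor   = list(center = 2.0, slope = 0.6, sd = 0.4, range = c(1, 4)),
    hy       = list(center = 2.25, slope = 0.6, sd = 0.5, range = c(1, 3)),
    updrs    = list(center = 27.3, slope = 10, sd = 7, range = c(4, 49)),
    mmse     = list(center = 29.8, slope = 0, sd = 0.05, range = c(29, 30))
  )
}

validate_synthetic_config <- function(cfg) {
  if (cfg$n_volumes < 2L) stop("n_volumes must be at least 2")
  if (cfg$tr <= 0) stop("tr must be positive")
  nyq <- 1 / (2 * cfg$tr)
  if (!(cfg$band[1] < cfg$band[2] && cfg$band[2] < 1 / (2 * cfg$tr) + 1e-12)) {
    stop(sprintf("band must satisfy low < high < Nyquist = %g Hz", nyq))
  }
  if (!isSymmetric(unname(cfg$base_cov), tol = 1e-10)) {
    stop("base_cov must be symmetric")
  }
  ev <- eigen(cfg$base_cov, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-10) stop("base_cov must be positive semi-definite")
  grid_ok <- cfg$hub_voxels >= 1 &
    cfg$hub_voxels <= matrix(cfg$grid_shape, nrow(cfg$hub_voxels), 3, byrow = TRUE)
  if (!all(grid_ok)) stop("every hub voxel must lie inside the grid")
  invisible(cfg)
}

#' @export
print.synthetic_config <- function(x, ...) {
  cat(sprintf(paste0("<synthetic_config> %d + %d subjects, %s grid, %d volumes ",
                     "@ TR %g s, band %g-%g Hz, %d regions, %d hub(s), seed %d\n"),
              x$n_group_a, x$n_group_b, paste(x$grid_shape, collapse = "x"),
              x$n_volumes, x$tr, x$band[1], x$band[2], x$n_regions,
              nrow(x$hub_voxels), x$seed))
  invisible(x)
}

# Contiguous equal-size partition of the grid into n_regions regions
# (chunks of the voxel linear index, i.e. slabs along z that may split a
# slice). Never leaves a region empty, whatever the grid size.
region_labels_for <- function(cfg) {
  n_vox <- prod(cfg$grid_shape)
  if (cfg$n_regions > n_vox) stop("more regions than voxels")
  region <- ceiling(seq_len(n_vox) * cfg$n_regions / n_vox)
  array(as.integer(region), dim = cfg$grid_shape)
}

#' Generate a synthetic two-group BOLD cohort
#'
#' Each subject's voxel series is region-structured multivariate noise:
#' region latent signals are drawn from a multivariate normal with the
#' configured covariance (plus the group effect for patients, scaled by a
#' positive per-subject latent severity), band-pass shaped to the configured
#' band and standardized, then broadcast to member voxels with independent
#' white voxel noise. Planted hub voxels carry the mean of all region
#' signals plus reduced noise, making them the expected centrality maxima.
#' The whole cohort is a deterministic function of `config$seed`.
#'
#' @param config A [synthetic_config()].
#' @return A list with `runs` (list of [bold_run()]; controls first, then
#'   patients) and `truth`, a `synthetic_truth` object recording the
#'   configuration, the voxel-to-region map, group labels and the
#'   per-subject latent severities that clinical scores are coupled to.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  validate_synthetic_config(config)
  cfg <- config
  n_sub <- cfg$n_group_a + cfg$n_group_b
  group <- rep(c("A", "B"), c(cfg$n_group_a, cfg$n_group_b))
  dim3 <- cfg$grid_shape
  regions <- region_labels_for(cfg)
  mask <- array(TRUE, dim = dim3)
  region_vec <- as.vector(regions)
  n_vox <- prod(dim3)
  hub_idx <- index_from_coords(cfg$hub_voxels, dim3)

  sigma_b <- cfg$base_cov + cfg$effect_delta
  ev <- eigen(sigma_b, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-10) {
    stop("base_cov + effect_delta is not positive semi-definite; ",
         "reduce the planted effect")
  }

  set.seed(subseed(cfg$seed, 1L))
  # positive per-subject severity scaling of the group effect (patients only)
  severity <- ifelse(group == "B", exp(stats::rnorm(n_sub, 0, 0.25)), 0)
  runs <- vector("list", n_sub)
  for (s in seq_len(n_sub)) {
    set.seed(subseed(cfg$seed, 100L + s))
    sigma <- cfg$base_cov + severity[s] * cfg$effect_delta
    # guard: per-subject severity must keep the covariance PSD
    evs <- eigen(sigma, symmetric = TRUE, only.values = TRUE)$values
    if (min(evs) < -1e-10) sigma <- cfg$base_cov + cfg$effect_delta
    latent <- mvn_draw(cfg$n_volumes, sigma)                 # t x R
    latent <- bandshape_columns(latent, cfg$tr, cfg$band)     # unit-sd, in-band
    vox <- t(latent[, region_vec, drop = FALSE])              # n_vox x t
    vox <- vox + matrix(stats::rnorm(n_vox * cfg$n_volumes, 0, cfg$noise_sd),
                        n_vox, cfg$n_volumes)
    hub_sig <- rowMeans(latent)
    hub_sig <- hub_sig / stats::sd(hub_sig)
    for (h in hub_idx) {
      vox[h, ] <- hub_sig + stats::rnorm(cfg$n_volumes, 0, 0.2 * cfg$noise_sd)
    }
    runs[[s]] <- bold_run(aperm_to_xyzt(t(vox), dim3, cfg$n_volumes),
                          mask = mask, tr = cfg$tr, voxel_size = cfg$voxel_size)
  }
  truth <- structure(
    list(config = cfg, region_labels = regions, group_labels = group,
         true_scores_latent = severity, hub_index = hub_idx, mask = mask),
    class = "synthetic_truth"
  )
  list(runs = runs, truth = truth)
}

# reshape helper: we build (t, x, y, z); BOLD convention is (x, y, z, t)
aperm_to_xyzt <- function(arr, dim3, t) {
  aperm(array(arr, dim = c(t, dim3)), c(2, 3, 4, 1))
}

# Multivariate normal draw via eigen factor (handles PSD, not just PD)
mvn_draw <- function(n, sigma) {
  e <- eigen(sigma, symmetric = TRUE)
  vals <- pmax(e$values, 0)
  z <- matrix(stats::rnorm(n * ncol(sigma)), n, ncol(sigma))
  z %*% t(e$vectors %*% diag(sqrt(vals), ncol(sigma)))
}

# Band-pass each column with the ideal filter and rescale to unit SD so
# that realized voxel correlations stay close to the nominal covariance.
bandshape_columns <- function(mat, tr, band) {
  t <- nrow(mat)
  freqs <- seq(0, t - 1) / (t * tr)
  freqs <- pmin(freqs, 1 / tr - freqs)
  keep <- freqs >= band[1] & freqs <= band[2]
  ft <- stats::mvfft(mat)
  ft[!keep, ] <- 0
  out <- Re(stats::mvfft(ft, inverse = TRUE)) / t
  sds <- apply(out, 2L, stats::sd)
  sds[sds == 0] <- 1
  sweep(out, 2L, sds, "/")
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat(sprintf("<synthetic_truth> %d subjects (%d A / %d B), %d regions, %d hub voxel(s)\n",
              length(x$group_labels), sum(x$group_labels == "A"),
              sum(x$group_labels == "B"), x$config$n_regions,
              length(x$hub_index)))
  invisible(x)
}

#' Generate a clinical score table for a synthetic cohort
#'
#' Builds the per-subject clinical table: demographics for everyone, and for
#' patients each configured disease score as
#' `center + slope * latent + noise`, clipped to its plausible range. The
#' latent is the subject's severity from [generate_cohort()], so scores are
#' genuinely coupled to the planted connectivity increase. Controls carry
#' `NA` for disease scores, mirroring the usual dash entries in clinical
#' tables.
#'
#' @param truth A `synthetic_truth` from [generate_cohort()].
#' @return A data.frame with one row per subject: `subject`, `group`, `age`,
#'   `gender` and one column per configured score.
#' @export
generate_clinical <- function(truth) {
  stopifnot(inherits(truth, "synthetic_truth"))
  cfg <- truth$config
  coupling <- cfg$score_coupling
  if (length(coupling) == 0L) stop("score_coupling is empty")
  for (nm in names(coupling)) {
    sc <- coupling[[nm]]
    if (is.null(sc$slope) || is.null(sc$sd)) {
      stop("missing coupling spec (slope/sd) for score '", nm, "'")
    }
  }
  n_sub <- length(truth$group_labels)
  is_b <- truth$group_labels == "B"
  set.seed(subseed(cfg$seed, 2L))
  age <- round(ifelse(is_b, stats::rnorm(n_sub, 60.5, 11.8),
                      stats::rnorm(n_sub, 59.2, 8.7)))
  age <- pmin(pmax(age, 37), 81)
  gender <- ifelse(stats::runif(n_sub) < ifelse(is_b, 9 / 16, 11 / 20), "M", "F")
  out <- data.frame(
    subject = sprintf("sub-%03d", seq_len(n_sub)),
    group = truth$group_labels, age = age, gender = gender,
    stringsAsFactors = FALSE
  )
  latent_c <- truth$true_scores_latent -
    mean(truth$true_scores_latent[is_b])  # centre on the patient group
  for (nm in names(coupling)) {
    sc <- coupling[[nm]]
    val <- sc$center + sc$slope * latent_c + stats::rnorm(n_sub, 0, sc$sd)
    if (!is.null(sc$range)) val <- pmin(pmax(val, sc$range[1]), sc$range[2])
    val[!is_b] <- NA_real_
    out[[nm]] <- val
  }
  out
}

#' Generate per-subject head-motion traces
#'
#' Simulates six-column rigid-body motion traces (3 translations in mm, 3
#' rotations in radians) as reflecting random walks bounded well inside the
#' conventional 3 mm / 3 degree exclusion rule, one row per retained volume.
#'
#' @param config A [synthetic_config()].
#' @return A list of `n_volumes` x 6 matrices, one per subject (controls
#'   first).
#' @export
generate_motion_traces <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  cfg <- config
  n_sub <- cfg$n_group_a + cfg$n_group_b
  rot_sd <- cfg$motion_sd / 60
  bound_t <- cfg$motion_bound
  bound_r <- cfg$motion_bound * pi / 180
  lapply(seq_len(n_sub), function(s) {
    set.seed(subseed(cfg$seed, 500L + s))
    tr_walk <- apply(matrix(stats::rnorm(cfg$n_volumes * 3, 0, cfg$motion_sd),
                            cfg$n_volumes, 3), 2L, cumsum)
    ro_walk <- apply(matrix(stats::rnorm(cfg$n_volumes * 3, 0, rot_sd),
                            cfg$n_volumes, 3), 2L, cumsum)
    m <- cbind(reflect_bound(tr_walk, bound_t), reflect_bound(ro_walk, bound_r))
    colnames(m) <- c("tx", "ty", "tz", "rx", "ry", "rz")
    m
  })
}

# Fold a random walk back into [-bound, bound] (triangle-wave reflection)
reflect_bound <- function(x, bound) {
  if (bound <= 0) return(x * 0)
  y <- (x + bound) %% (4 * bound)
  ifelse(y > 2 * bound, 4 * bound - y, y) - bound
}

#' Write a synthetic cohort to disk
#'
#' Emits the cohort in the pipeline's external formats: one 4D NIfTI per
#' subject, one SPM-style `rp_sub-XXX.txt` whitespace-delimited motion trace
#' (translations mm, rotations radians), a tab-delimited `clinical.tsv` with
#' header, a brain-mask NIfTI, and a `truth.json` sidecar with the planted
#' ground truth.
#'
#' @param cohort Result of [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @param motion Optional list of motion traces from
#'   [generate_motion_traces()]; generated from the config when `NULL`.
#' @param clinical Optional clinical table; generated when `NULL`.
#' @return Invisibly, the directory path.
#' @export
write_cohort <- function(cohort, dir, motion = NULL, clinical = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  truth <- cohort$truth
  cfg <- truth$config
  if (is.null(motion)) motion <- generate_motion_traces(cfg)
  if (is.null(clinical)) clinical <- generate_clinical(truth)
  for (s in seq_along(cohort$runs)) {
    run <- cohort$runs[[s]]
    img <- RNifti::asNifti(run$data)
    RNifti::pixdim(img) <- c(run$voxel_size, run$tr)
    RNifti::writeNifti(img, file.path(dir, sprintf("sub-%03d_bold.nii.gz", s)))
    utils::write.table(
      format(motion[[s]], scientific = FALSE),
      file.path(dir, sprintf("rp_sub-%03d.txt", s)),
      row.names = FALSE, col.names = FALSE, quote = FALSE
    )
  }
  RNifti::writeNifti(RNifti::asNifti(array(as.numeric(truth$mask),
                                           dim = cfg$grid_shape)),
                     file.path(dir, "mask.nii.gz"))
  utils::write.table(clinical, file.path(dir, "clinical.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  tr_json <- list(
    seed = cfg$seed, n_group_a = cfg$n_group_a, n_group_b = cfg$n_group_b,
    grid_shape = cfg$grid_shape, n_volumes = cfg$n_volumes, tr = cfg$tr,
    band = cfg$band, n_regions = cfg$n_regions,
    base_cov = cfg$base_cov, effect_delta = cfg$effect_delta,
    hub_voxels = cfg$hub_voxels, group_labels = truth$group_labels,
    true_scores_latent = truth$true_scores_latent
  )
  jsonlite::write_json(tr_json, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
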