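#' Run the full discoordination analysis on a synthetic cohort
#'
#' One-call version of the whole pipeline on a simulated two-group cohort:
#' simulate -> temporal preprocessing -> voxel-wise weighted degree
#' centrality -> group GLM t-map with Monte-Carlo cluster-extent correction
#' -> sphere seeds at cluster peaks -> seed-based Fisher-z connectivity ->
#' ROI correlation networks -> sparsity-swept weighted efficiency with
#' degree-preserving null normalization -> permutation tests (FDR across
#' sparsities) and AUC tests -> brain-behavior partial Spearman -> ROC
#' discrimination on the most discriminative connection. Every output
#' format of the pipeline is written under `out_dir`.
#'
#' @param config A [synthetic_config()]; its seed drives all randomness.
#' @param out_dir Output directory. `NULL` skips all file output.
#' @param band Pass band in Hz for preprocessing.
#' @param drop_first Leading volumes to discard.
#' @param wdc_alpha Family-wise alpha for the centrality correlation floor.
#' @param height_p Height threshold for the group t-map.
#' @param n_cluster_sims Monte-Carlo simulations for the extent cutoff.
#' @param sparsities Sparsity grid for the efficiency sweep.
#' @param n_null Degree-preserving surrogates per sparsity for the
#'   group-mean networks.
#' @param n_perm Permutations for the network-metric tests.
#' @param seed_radius_mm Radius of the sphere seeds (default 6).
#' @param min_rois Minimum ROI count for the network stage; region-centroid
#'   seeds top up the set when fewer cluster peaks are available (logged).
#' @param write_inputs Also write the simulated cohort (NIfTI, motion
#'   traces, clinical table, truth sidecar) under `out_dir/cohort`.
#' @return A list of class `tremornet_result` with the fitted objects and a
#'   `summary` list (also written as `summary.json`).
#' @export
run_pipeline <- function(config = synthetic_config(), out_dir = NULL,
                         band = c(0.01, 0.1), drop_first = 5L,
                         wdc_alpha = 0.05, height_p = 0.01,
                         n_cluster_sims = 1000L,
                         sparsities = seq(0.08, 0.6, by = 0.02),
                         n_null = 100L, n_perm = 10000L,
                         seed_radius_mm = 6, min_rois = 8L,
                         write_inputs = FALSE) {
  stopifnot(inherits(config, "synthetic_config"))
  t0 <- Sys.time()
  log <- list(seed = config$seed, band = band, drop_first = drop_first,
              wdc_alpha = wdc_alpha, height_p = height_p,
              n_cluster_sims = n_cluster_sims, n_null = n_null,
              n_perm = n_perm, seed_radius_mm = seed_radius_mm)

  ## --- simulate -------------------------------------------------------
  cohort <- generate_cohort(config)
  truth <- cohort$truth
  motion <- generate_motion_traces(config)
  clinical <- generate_clinical(truth)
  n_sub <- length(cohort$runs)
  is_b <- truth$group_labels == "B"
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (write_inputs) {
      write_cohort(cohort, file.path(out_dir, "cohort"), motion, clinical)
    }
  }

  ## --- preprocess -----------------------------------------------------
  pre <- vector("list", n_sub)
  msum <- matrix(NA_real_, n_sub, 3,
                 dimnames = list(NULL, c("max_disp", "rms_disp", "mean_fd")))
  for (s in seq_len(n_sub)) {
    p <- preprocess_run(cohort$runs[[s]], motion[[s]], band = band,
                        drop_first = drop_first)
    pre[[s]] <- p$run
    msum[s, ] <- unlist(p$summary)
  }
  mask <- pre[[1L]]$mask
  covars <- data.frame(age = clinical$age,
                       gender = factor(clinical$gender),
                       msum)

  ## --- voxel-wise weighted degree centrality --------------------------
  wdc <- matrix(NA_real_, n_sub, sum(mask))
  for (s in seq_len(n_sub)) {
    wdc[s, ] <- compute_wdc_map(pre[[s]], alpha = wdc_alpha)$values
  }
  log$wdc_r_threshold <- bonferroni_r_threshold(wdc_alpha, sum(mask) - 1L,
                                                n_volumes(pre[[1L]]))
  log$n_gm_voxels <- sum(mask)

  ## --- group stats on WDC + cluster correction ------------------------
  stat <- glm_contrast_map(wdc, truth$group_labels, covariates = covars,
                           mask = mask, height_p = height_p)
  fwhm <- estimate_fwhm(wdc, mask)
  stat <- cluster_extent_correct(stat, n_sims = n_cluster_sims,
                                 fwhm_vox = fwhm, seed = config$seed)
  log$fwhm_vox <- fwhm
  log$extent_cutoff <- stat$extent_cutoff
  log$n_surviving_clusters <- length(stat$clusters$sizes)

  ## --- seeds at cluster peaks (fallback: largest uncorrected clusters) -
  affine <- pre[[1L]]$affine
  dim3 <- dim(mask)
  peaks <- cluster_peaks(stat, mask)
  log$seed_source <- if (nrow(peaks) > 0) "corrected_clusters" else "uncorrected_peaks"
  if (nrow(peaks) == 0L) {
    tv <- unmask_map(abs(stat$t_values), mask, fill = -Inf)
    peaks <- coords_from_index(which.max(tv), dim3)
  }
  peak_rois <- lapply(seq_len(nrow(peaks)), function(i) {
    make_sphere_roi(voxel_to_mm(peaks[i, , drop = FALSE], affine),
                    seed_radius_mm, mask, affine,
                    name = sprintf("peak%02d", i))
  })
  rois <- drop_overlapping_rois(peak_rois)
  n_dropped <- length(attr(rois, "dropped"))
  attributes(rois)$dropped <- NULL
  n_peaks <- length(rois)
  # top up with staggered region seeds so the network stage has enough nodes;
  # on grids too small to fit non-overlapping spheres, shrink the
  # supplemental radius (down to a single voxel) until >= 3 nodes fit
  supp_radius <- seed_radius_mm
  repeat {
    cands <- region_seed_candidates(truth$region_labels, affine)
    for (r in seq_len(nrow(cands))) {
      if (length(rois) >= min_rois) break
      cand <- make_sphere_roi(cands[r, ], supp_radius, mask, affine,
                              name = sprintf("region%02d", r))
      if (!any(vapply(rois, function(k) roi_overlap(k, cand) > 0L, logical(1)))) {
        rois[[length(rois) + 1L]] <- cand
      }
    }
    if (length(rois) >= min(3L, min_rois) || supp_radius < min(pre[[1L]]$voxel_size)) break
    supp_radius <- supp_radius / 2
  }
  if (length(rois) < 3L) stop("fewer than 3 non-overlapping ROIs fit this grid")
  log$supplemental_seed_radius_mm <- supp_radius
  log$n_rois_dropped_overlap <- n_dropped
  log$n_rois <- length(rois)
  log$n_peak_rois <- n_peaks

  ## --- seed-based functional connectivity (group-mean z maps) ---------
  fc_group_mean <- vector("list", length(rois))
  for (k in seq_along(rois)) {
    zs <- vapply(pre, function(run) seed_fc_map(run, rois[[k]])$z_values,
                 numeric(sum(mask)))
    fc_group_mean[[k]] <- list(
      roi = rois[[k]],
      mean_a = rowMeans(zs[, !is_b, drop = FALSE]),
      mean_b = rowMeans(zs[, is_b, drop = FALSE])
    )
  }

  ## --- ROI networks and efficiency sweep ------------------------------
  roi_series <- lapply(pre, function(run) {
    vapply(rois, function(r) extract_roi_timeseries(run, r),
           numeric(n_volumes(run)))
  })
  nets <- lapply(roi_series, roi_correlation_matrix)
  curves <- lapply(nets, efficiency_curve, sparsities = sparsities)
  eg <- t(vapply(curves, `[[`, numeric(length(sparsities)), "e_glob"))
  el <- t(vapply(curves, `[[`, numeric(length(sparsities)), "e_loc"))
  auc_g <- vapply(curves, `[[`, numeric(1), "auc_glob")
  auc_l <- vapply(curves, `[[`, numeric(1), "auc_loc")

  # group-mean networks: null normalization and small-world assessment
  mean_net_a <- mean_correlation_network(nets[!is_b])
  mean_net_b <- mean_correlation_network(nets[is_b])
  curve_a <- efficiency_curve(mean_net_a, sparsities, n_null = n_null,
                              seed = subseed(config$seed, 41L))
  curve_b <- efficiency_curve(mean_net_b, sparsities, n_null = n_null,
                              seed = subseed(config$seed, 42L))
  log$small_world_a <- curve_a$small_world
  log$small_world_b <- curve_b$small_world

  ## --- permutation tests + FDR across sparsities ----------------------
  pt_auc_g <- permutation_test_metric(auc_g[!is_b], auc_g[is_b], covars,
                                      n_perm, subseed(config$seed, 51L))
  pt_auc_l <- permutation_test_metric(auc_l[!is_b], auc_l[is_b], covars,
                                      n_perm, subseed(config$seed, 52L))
  p_g <- vapply(seq_along(sparsities), function(i) {
    permutation_test_metric(eg[!is_b, i], eg[is_b, i], covars, n_perm,
                            subseed(config$seed, 100L + i))$p
  }, numeric(1))
  p_l <- vapply(seq_along(sparsities), function(i) {
    permutation_test_metric(el[!is_b, i], el[is_b, i], covars, n_perm,
                            subseed(config$seed, 200L + i))$p
  }, numeric(1))
  fdr_g <- fdr_across_sparsities(p_g)
  fdr_l <- fdr_across_sparsities(p_l)

  ## --- brain-behavior partial Spearman (patients only) ----------------
  pat_cov <- covars[is_b, , drop = FALSE]
  safe_spearman <- function(x, y, cv) {
    tryCatch(partial_spearman(x, y, cv),
             error = function(e) {
               warning("brain-behavior correlation skipped: ", conditionMessage(e))
               list(rho = NA_real_, p = NA_real_, df = NA_integer_)
             })
  }
  spearman <- list(
    auc_glob_vs_tremor = safe_spearman(auc_g[is_b], clinical$tremor[is_b], pat_cov),
    auc_loc_vs_tremor  = safe_spearman(auc_l[is_b], clinical$tremor[is_b], pat_cov)
  )

  ## --- ROC on the most discriminative connection ----------------------
  zmats <- lapply(nets, function(n) atanh(pmin(pmax(n$corr, -1 + 1e-7), 1 - 1e-7)))
  npair <- length(rois)
  best <- pick_discriminative_edge(zmats, is_b)
  scores <- vapply(zmats, function(z) z[best[1L], best[2L]], numeric(1))
  flip <- mean(scores[is_b]) < mean(scores[!is_b])
  if (flip) scores <- -scores
  roc <- roc_analysis(scores[is_b], scores[!is_b])
  log$roc_edge <- sprintf("%s--%s%s", rois[[best[1L]]]$name, rois[[best[2L]]]$name,
                          if (flip) " (sign flipped)" else "")

  summary <- c(log, list(
    auc_glob_p = pt_auc_g$p, auc_loc_p = pt_auc_l$p,
    auc_glob_effect = pt_auc_g$observed, auc_loc_effect = pt_auc_l$observed,
    n_fdr_sig_glob = length(fdr_g), n_fdr_sig_loc = length(fdr_l),
    spearman_auc_loc_tremor_rho = spearman$auc_loc_vs_tremor$rho,
    spearman_auc_loc_tremor_p = spearman$auc_loc_vs_tremor$p,
    roc_auc = roc$auc,
    roc_sensitivity_pct = round(100 * roc$best_point$sensitivity, 1),
    roc_specificity_pct = round(100 * roc$best_point$specificity, 1),
    elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs"))
  ))

  result <- structure(
    list(truth = truth, clinical = clinical, motion_summaries = msum,
         wdc = wdc, stat = stat, rois = rois, fc_group_mean = fc_group_mean,
         networks = nets, curves = curves, curve_group_a = curve_a,
         curve_group_b = curve_b, auc_glob = auc_g, auc_loc = auc_l,
         p_glob = p_g, p_loc = p_l, fdr_glob = fdr_g, fdr_loc = fdr_l,
         perm_auc_glob = pt_auc_g, perm_auc_loc = pt_auc_l,
         spearman = spearman, roc = roc, mask = mask, summary = summary),
    class = "tremornet_result"
  )
  if (!is.null(out_dir)) write_pipeline_outputs(result, out_dir)
  result
}

#' @export
print.tremornet_result <- function(x, ...) {
  s <- x$summary
  cat("<tremornet_result>\n")
  cat(sprintf("  %d GM voxels, WDC r floor %.4f, %d surviving cluster(s), %d ROIs\n",
              s$n_gm_voxels, s$wdc_r_threshold, s$n_surviving_clusters, s$n_rois))
  cat(sprintf("  efficiency AUC: E_glob p = %.4g, E_loc p = %.4g (%d / %d sparsities FDR-significant)\n",
              s$auc_glob_p, s$auc_loc_p, s$n_fdr_sig_glob, s$n_fdr_sig_loc))
  cat(sprintf("  small-world: controls %s, patients %s\n",
              s$small_world_a, s$small_world_b))
  cat(sprintf("  ROC (%s): AUC = %.3f, sensitivity %.1f%%, specificity %.1f%%\n",
              s$roc_edge, s$roc_auc, s$roc_sensitivity_pct, s$roc_specificity_pct))
  invisible(x)
}

# Peak |t| voxel per surviving cluster, ordered by cluster size
cluster_peaks <- function(stat, mask) {
  if (is.null(stat$clusters) || length(stat$clusters$sizes) == 0L) {
    return(matrix(integer(0), 0, 3))
  }
  tmap <- unmask_map(abs(stat$t_values), mask, fill = -Inf)
  dim3 <- dim(mask)
  ord <- order(-stat$clusters$sizes)
  do.call(rbind, lapply(ord, function(ci) {
    vox <- which(stat$clusters$labels == ci)
    coords_from_index(vox[which.max(tmap[vox])], dim3)
  }))
}

# Staggered in-region seed centres (mm): one per region, cycling through
# four x-y quadrant positions so neighbouring slab seeds do not overlap.
region_seed_candidates <- function(region_labels, affine) {
  dim3 <- dim(region_labels)
  labs <- sort(unique(as.vector(region_labels)))
  quad <- rbind(c(0.3, 0.3), c(0.7, 0.7), c(0.3, 0.7), c(0.7, 0.3))
  do.call(rbind, lapply(seq_along(labs), function(li) {
    idx <- which(region_labels == labs[li])
    kz <- round(mean(coords_from_index(idx, dim3)[, 3L]))
    q <- quad[(li - 1L) %% 4L + 1L, ]
    ijk <- c(round(q[1] * dim3[1]), round(q[2] * dim3[2]), kz)
    voxel_to_mm(matrix(pmax(ijk, 1L), 1), affine)
  }))
}

mean_correlation_network <- function(nets) {
  corr <- Reduce(`+`, lapply(nets, `[[`, "corr")) / length(nets)
  structure(list(corr = corr, labels = nets[[1L]]$labels), class = "roi_network")
}

# ROI pair with the largest |two-sample t| on Fisher-z connectivity
pick_discriminative_edge <- function(zmats, is_b) {
  n <- nrow(zmats[[1L]])
  best <- c(1L, 2L); best_t <- -Inf
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      z <- vapply(zmats, function(m) m[i, j], numeric(1))
      tt <- tryCatch(abs(stats::t.test(z[is_b], z[!is_b])$statistic),
                     error = function(e) 0)
      if (tt > best_t) { best_t <- tt; best <- c(i, j) }
    }
  }
  best
}

write_pipeline_outputs <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  mask <- result$mask
  # t map and surviving-cluster mask as NIfTI
  RNifti::writeNifti(RNifti::asNifti(unmask_map(result$stat$t_values, mask, 0)),
                     file.path(out_dir, "wdc_group_tmap.nii.gz"))
  RNifti::writeNifti(RNifti::asNifti(array(as.numeric(result$stat$surviving_mask),
                                           dim(mask))),
                     file.path(out_dir, "wdc_clusters_corrected.nii.gz"))
  # group-mean seed FC z maps
  for (k in seq_along(result$fc_group_mean)) {
    fc <- result$fc_group_mean[[k]]
    RNifti::writeNifti(RNifti::asNifti(unmask_map(fc$mean_b - fc$mean_a, mask, 0)),
                       file.path(out_dir, sprintf("seedfc_%s_zdiff.nii.gz", fc$roi$name)))
  }
  # seed table
  seeds <- do.call(rbind, lapply(result$rois, function(r) {
    data.frame(name = r$name, x_mm = r$center_mm[1], y_mm = r$center_mm[2],
               z_mm = r$center_mm[3], radius_mm = r$radius_mm,
               n_voxels = length(r$voxel_set))
  }))
  utils::write.table(seeds, file.path(out_dir, "seeds.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  # group-mean correlation matrices
  is_b <- result$truth$group_labels == "B"
  for (gname in c("A", "B")) {
    sel <- if (gname == "A") !is_b else is_b
    m <- mean_correlation_network(result$networks[sel])$corr
    colnames(m) <- rownames(m) <- vapply(result$rois, `[[`, character(1), "name")
    utils::write.table(round(m, 6), file.path(out_dir, sprintf("roi_corr_group%s.tsv", gname)),
                       sep = "\t", quote = FALSE)
  }
  # group-mean graphs at sparsity 0.3 as weighted edge lists
  roi_names <- vapply(result$rois, `[[`, character(1), "name")
  for (gname in c("A", "B")) {
    sel <- if (gname == "A") !is_b else is_b
    g03 <- sparsity_threshold(mean_correlation_network(result$networks[sel]), 0.3)
    ed <- which(upper.tri(g03$adjacency) & g03$adjacency > 0, arr.ind = TRUE)
    utils::write.table(
      data.frame(from = roi_names[ed[, 1]], to = roi_names[ed[, 2]],
                 weight = round(g03$adjacency[ed], 6)),
      file.path(out_dir, sprintf("network_s0.3_group%s_edges.tsv", gname)),
      sep = "\t", row.names = FALSE, quote = FALSE
    )
  }
  # efficiency curves + tests
  norm_or_na <- function(v, n) if (is.null(v)) rep(NA_real_, n) else v
  ns <- length(result$curve_group_a$sparsities)
  curves <- data.frame(
    sparsity = result$curve_group_a$sparsities,
    e_glob_ctrl = result$curve_group_a$e_glob,
    e_loc_ctrl = result$curve_group_a$e_loc,
    e_glob_pat = result$curve_group_b$e_glob,
    e_loc_pat = result$curve_group_b$e_loc,
    e_glob_norm_ctrl = norm_or_na(result$curve_group_a$e_glob_norm, ns),
    e_loc_norm_ctrl = norm_or_na(result$curve_group_a$e_loc_norm, ns),
    e_glob_norm_pat = norm_or_na(result$curve_group_b$e_glob_norm, ns),
    e_loc_norm_pat = norm_or_na(result$curve_group_b$e_loc_norm, ns),
    p_glob = result$p_glob, p_loc = result$p_loc,
    fdr_sig_glob = seq_along(result$p_glob) %in% result$fdr_glob,
    fdr_sig_loc = seq_along(result$p_loc) %in% result$fdr_loc
  )
  utils::write.table(curves, file.path(out_dir, "efficiency_curves.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  # per-subject AUC table
  utils::write.table(
    data.frame(subject = result$clinical$subject, group = result$truth$group_labels,
               auc_glob = result$auc_glob, auc_loc = result$auc_loc),
    file.path(out_dir, "efficiency_auc.tsv"), sep = "\t", row.names = FALSE,
    quote = FALSE
  )
  # ROC table
  utils::write.table(
    data.frame(threshold = result$roc$thresholds,
               sensitivity = result$roc$sensitivity,
               specificity = result$roc$specificity),
    file.path(out_dir, "roc.tsv"), sep = "\t", row.names = FALSE, quote = FALSE
  )
  jsonlite::write_json(result$summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
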