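#' Voxel-wise GLM group-contrast map
#'
#' Fits, per voxel, a least-squares model of the map value on a group
#' indicator plus covariates, and returns the t statistic for the group
#' coefficient with two-sided p-values from the t distribution on the
#' residual degrees of freedom. With no covariates this reduces exactly to
#' the classical pooled two-sample t-test. Voxel-wise covariates (for
#' example grey-matter volume maps, to test the structural contribution to
#' functional differences) can be supplied and enter the model voxel by
#' voxel.
#'
#' @param maps Subject x voxel numeric matrix of per-subject map values.
#' @param group Factor or vector with exactly two levels; the t statistic is
#'   for level 2 minus level 1.
#' @param covariates Optional data.frame / matrix of subject-level
#'   covariates (e.g. gender, age, motion summaries).
#' @param voxel_covariates Optional subject x voxel matrix entering the
#'   design voxel-wise.
#' @param mask Optional 3D logical mask used to shape the output map.
#' @param height_p Uncorrected height threshold stored with the map for
#'   downstream cluster correction (default 0.01).
#' @return An object of class `stat_map`: `t_values`, `p_values`, `df`,
#'   `height_p`, and `map` (3D t array) when a mask is given.
#' @export
glm_contrast_map <- function(maps, group, covariates = NULL,
                             voxel_covariates = NULL, mask = NULL,
                             height_p = 0.01) {
  maps <- as.matrix(maps)
  n <- nrow(maps)
  g <- as.integer(factor(group)) - 1L
  if (length(unique(g)) != 2L) stop("group must have exactly two levels")
  if (min(table(g)) < 3L) stop("need at least 3 subjects per group")
  x0 <- cbind(intercept = 1, group = g)
  if (!is.null(covariates)) {
    cm <- stats::model.matrix(~ ., data = as.data.frame(covariates))[, -1, drop = FALSE]
    if (nrow(cm) != n) stop("covariate rows do not align with subjects")
    if (qr(cbind(x0, cm))$rank < ncol(x0) + ncol(cm)) {
      warning("covariates collinear with the design; variance inflation likely — check the design")
    }
    x0 <- cbind(x0, cm)
  }
  if (is.null(voxel_covariates)) {
    qx <- qr(x0)
    df <- n - qx$rank
    beta <- qr.coef(qx, maps)
    resid <- maps - x0 %*% beta
    sigma2 <- colSums(resid^2) / df
    xtxinv <- chol2inv(qr.R(qx))
    se <- sqrt(sigma2 * xtxinv[2L, 2L])
    tv <- beta[2L, ] / se
  } else {
    voxel_covariates <- as.matrix(voxel_covariates)
    if (!all(dim(voxel_covariates) == dim(maps))) {
      stop("voxel_covariates must match the dimensions of maps")
    }
    nv <- ncol(maps)
    tv <- numeric(nv)
    df <- n - ncol(x0) - 1L
    for (v in seq_len(nv)) {
      xv <- cbind(x0, gmv = voxel_covariates[, v])
      qv <- qr(xv)
      if (qv$rank < ncol(xv)) { tv[v] <- 0; next }
      b <- qr.coef(qv, maps[, v])
      r <- maps[, v] - xv %*% b
      s2 <- sum(r^2) / (n - qv$rank)
      xtxinv <- chol2inv(qr.R(qv))
      tv[v] <- b[2L] / sqrt(s2 * xtxinv[2L, 2L])
    }
  }
  tv[!is.finite(tv)] <- 0
  pv <- 2 * stats::pt(abs(tv), df = df, lower.tail = FALSE)
  structure(
    list(t_values = tv, p_values = pv, df = df, height_p = height_p,
         map = if (!is.null(mask)) unmask_map(tv, mask) else NULL,
         mask = mask),
    class = "stat_map"
  )
}

#' @export
print.stat_map <- function(x, ...) {
  cat(sprintf("<stat_map> %d voxels, df = %d, |t| max %.2f, height p < %g\n",
              length(x$t_values), x$df, max(abs(x$t_values)), x$height_p))
  if (!is.null(x$clusters)) {
    cat(sprintf("  %d cluster(s) survive extent >= %d voxels\n",
                length(x$clusters$sizes), x$extent_cutoff))
  }
  invisible(x)
}

# 26-connectivity connected components of a 3D logical array.
# Returns a label array (0 outside) and a vector of component sizes.
label_clusters_26 <- function(supra) {
  dim3 <- dim(supra)
  idx <- which(supra)
  labels <- integer(length(supra))
  if (length(idx) == 0L) {
    return(list(labels = array(labels, dim3), sizes = integer(0)))
  }
  offsets <- as.matrix(expand.grid(di = -1:1, dj = -1:1, dk = -1:1))
  offsets <- offsets[rowSums(abs(offsets)) > 0, , drop = FALSE]
  in_supra <- logical(length(supra))
  in_supra[idx] <- TRUE
  comp <- 0L
  sizes <- integer(0)
  coords <- coords_from_index(idx, dim3)
  rownames(coords) <- NULL
  lookup <- integer(length(supra))
  lookup[idx] <- seq_along(idx)
  visited <- logical(length(idx))
  for (start in seq_along(idx)) {
    if (visited[start]) next
    comp <- comp + 1L
    queue <- start
    visited[start] <- TRUE
    size <- 0L
    while (length(queue) > 0L) {
      cur <- queue[length(queue)]
      queue <- queue[-length(queue)]
      size <- size + 1L
      labels[idx[cur]] <- comp
      cc <- coords[cur, ]
      nb <- sweep(offsets, 2L, cc, `+`)
      ok <- nb[, 1] >= 1 & nb[, 1] <= dim3[1] &
        nb[, 2] >= 1 & nb[, 2] <= dim3[2] &
        nb[, 3] >= 1 & nb[, 3] <= dim3[3]
      nbi <- index_from_coords(nb[ok, , drop = FALSE], dim3)
      nbi <- nbi[in_supra[nbi]]
      for (ni in lookup[nbi]) {
        if (!visited[ni]) { visited[ni] <- TRUE; queue <- c(queue, ni) }
      }
    }
    sizes <- c(sizes, size)
  }
  list(labels = array(labels, dim3), sizes = sizes)
}

#' Estimate per-axis smoothness (FWHM) of residual maps
#'
#' Classical gradient-variance estimator: along each axis, the FWHM in
#' voxels is derived from the ratio of the variance of adjacent-voxel
#' differences to the variance of the field.
#'
#' @param maps Subject x voxel matrix of residual (or raw) maps.
#' @param mask 3D logical mask defining the voxel layout.
#' @return Numeric length-3 FWHM in voxel units (0 where the field looks
#'   unsmoothed).
#' @export
estimate_fwhm <- function(maps, mask) {
  dim3 <- dim(mask)
  fwhm <- numeric(3)
  vol <- array(NA_real_, dim3)
  acc_num <- numeric(3); acc_den <- numeric(3)
  for (s in seq_len(nrow(maps))) {
    vol[mask] <- maps[s, ]
    for (ax in 1:3) {
      d <- diff_along(vol, ax)
      d <- d[is.finite(d)]
      if (length(d) < 2) next
      acc_num[ax] <- acc_num[ax] + stats::var(d)
      acc_den[ax] <- acc_den[ax] + stats::var(vol[mask])
    }
  }
  for (ax in 1:3) {
    if (acc_den[ax] <= 0) next
    ratio <- acc_num[ax] / (2 * acc_den[ax])
    if (ratio <= 0 || ratio >= 1) next
    fwhm[ax] <- sqrt(-2 * log(2) / log(1 - ratio))
  }
  fwhm
}

diff_along <- function(vol, ax) {
  d <- dim(vol)
  if (ax == 1L) vol[-1, , , drop = FALSE] - vol[-d[1], , , drop = FALSE]
  else if (ax == 2L) vol[, -1, , drop = FALSE] - vol[, -d[2], , drop = FALSE]
  else vol[, , -1, drop = FALSE] - vol[, , -d[3], drop = FALSE]
}

#' Null distribution of maximum cluster extent
#'
#' Monte-Carlo simulation of smooth Gaussian null fields on the mask:
#' each simulated field is thresholded at the two-sided height level and the
#' largest 26-connected suprathreshold cluster size is recorded. The
#' `1 - alpha_fwe` quantile of these maxima is the extent cutoff used by
#' [cluster_extent_correct()].
#'
#' @param mask 3D logical analysis mask.
#' @param height_p Uncorrected two-sided height threshold.
#' @param n_sims Number of simulated fields (default 1000; below 100 a
#'   warning about quantile instability is raised).
#' @param fwhm_vox Per-axis Gaussian smoothness of the null fields in voxel
#'   units (default 0 = white noise).
#' @param seed Integer seed.
#' @return Integer vector of per-simulation maximum cluster sizes.
#' @export
cluster_null_distribution <- function(mask, height_p = 0.01, n_sims = 1000L,
                                      fwhm_vox = c(0, 0, 0), seed = 1L) {
  if (n_sims < 100L) warning("fewer than 100 simulations: extent quantile will be unstable")
  dim3 <- dim(mask)
  zcrit <- stats::qnorm(1 - height_p / 2)
  kern_fft <- NULL
  if (any(fwhm_vox > 0)) {
    sigma <- rep(fwhm_vox, length.out = 3L) / (2 * sqrt(2 * log(2)))
    kern <- gaussian_kernel_3d(dim3, sigma)
    kern_fft <- stats::fft(kern)
  }
  set.seed(subseed(seed, 77L))
  vapply(seq_len(n_sims), function(i) {
    field <- array(stats::rnorm(prod(dim3)), dim3)
    if (!is.null(kern_fft)) {
      field <- Re(stats::fft(stats::fft(field) * kern_fft, inverse = TRUE)) / prod(dim3)
      field <- field / stats::sd(field[mask])
    }
    supra <- abs(field) > zcrit & mask
    cl <- label_clusters_26(supra)
    if (length(cl$sizes) == 0L) 0L else max(cl$sizes)
  }, integer(1))
}

gaussian_kernel_3d <- function(dim3, sigma) {
  ax <- lapply(1:3, function(a) {
    n <- dim3[a]
    x <- pmin(0:(n - 1), n - (0:(n - 1)))  # circular distance
    k <- if (sigma[a] > 0) exp(-x^2 / (2 * sigma[a]^2)) else as.numeric(x == 0)
    k / sum(k)
  })
  outer(outer(ax[[1]], ax[[2]]), ax[[3]])
}

#' Cluster-extent correction of a statistical map
#'
#' Family-wise error control by cluster extent: voxels failing the
#' two-sided height threshold are discarded, the remaining voxels are
#' grouped into 26-connected clusters separately for positive and negative
#' t values, and clusters smaller than a Monte-Carlo extent cutoff are
#' removed. The cutoff is the `1 - alpha_fwe` quantile of the maximum null
#' cluster size over simulated Gaussian fields whose smoothness can be
#' matched to the residual maps.
#'
#' @param stat A `stat_map` from [glm_contrast_map()] (must carry a mask).
#' @param n_sims Null simulations (default 1000).
#' @param alpha_fwe Family-wise level (default 0.05).
#' @param fwhm_vox Smoothness of the null fields in voxels; pass the value
#'   from [estimate_fwhm()] to match the data (default 0).
#' @param seed Integer seed.
#' @param null_max_sizes Optional precomputed vector from
#'   [cluster_null_distribution()]; when supplied, `n_sims`, `fwhm_vox` and
#'   `seed` are ignored.
#' @return The `stat_map` augmented with `clusters` (labels + sizes),
#'   `extent_cutoff` and `surviving_mask` (3D logical).
#' @export
cluster_extent_correct <- function(stat, n_sims = 1000L, alpha_fwe = 0.05,
                                   fwhm_vox = c(0, 0, 0), seed = 1L,
                                   null_max_sizes = NULL) {
  stopifnot(inherits(stat, "stat_map"))
  if (is.null(stat$mask)) stop("stat map carries no mask; refit with `mask`")
  mask <- stat$mask
  if (is.null(null_max_sizes)) {
    null_max_sizes <- cluster_null_distribution(mask, stat$height_p, n_sims,
                                                fwhm_vox, seed)
  }
  cutoff <- as.integer(stats::quantile(null_max_sizes, 1 - alpha_fwe, type = 1))
  tcrit <- stats::qt(1 - stat$height_p / 2, df = stat$df)
  tmap <- unmask_map(stat$t_values, mask, fill = 0)
  surviving <- array(FALSE, dim(mask))
  all_labels <- array(0L, dim(mask))
  all_sizes <- integer(0)
  next_lab <- 0L
  for (sign_dir in c(1, -1)) {
    supra <- (sign_dir * tmap > tcrit) & mask
    cl <- label_clusters_26(supra)
    for (ci in seq_along(cl$sizes)) {
      if (cl$sizes[ci] >= cutoff && cutoff > 0) {
        next_lab <- next_lab + 1L
        vox <- cl$labels == ci
        surviving[vox] <- TRUE
        all_labels[vox] <- next_lab
        all_sizes <- c(all_sizes, cl$sizes[ci])
      }
    }
  }
  stat$clusters <- list(labels = all_labels, sizes = all_sizes)
  stat$extent_cutoff <- cutoff
  stat$surviving_mask <- surviving
  stat$null_max_sizes <- null_max_sizes
  stat
}

#' Covariate-adjusted permutation test for a network metric
#'
#' Freedman-Lane scheme: the metric is residualized on the covariates (with
#' intercept), the observed statistic is the difference of group means of
#' the residualized values (B minus A), and the permutation distribution is
#' obtained by shuffling group labels over the residuals. The p-value uses
#' the add-one convention `p = (1 + #{|perm| >= |obs|}) / (n_perm + 1)`.
#'
#' @param values_a,values_b Metric values for the two groups.
#' @param covariates Optional covariate table aligned with
#'   `c(values_a, values_b)`.
#' @param n_perm Number of permutations (default 10000, minimum 100).
#' @param seed Integer seed.
#' @return List with `p`, `observed` (adjusted mean difference) and
#'   `n_perm`.
#' @export
permutation_test_metric <- function(values_a, values_b, covariates = NULL,
                                    n_perm = 10000L, seed = 1L) {
  if (n_perm < 100L) stop("n_perm must be at least 100")
  y <- c(values_a, values_b)
  g <- rep(0:1, c(length(values_a), length(values_b)))
  if (stats::sd(y) == 0) {
    warning("metric is constant; permutation test is uninformative")
    return(list(p = 1, observed = 0, n_perm = n_perm))
  }
  if (!is.null(covariates)) {
    cm <- stats::model.matrix(~ ., data = as.data.frame(covariates))
    y <- stats::lm.fit(cm, y)$residuals
  }
  obs <- mean(y[g == 1]) - mean(y[g == 0])
  set.seed(subseed(seed, 31L))
  n <- length(y)
  n1 <- sum(g == 1)
  perm <- vapply(seq_len(n_perm), function(i) {
    idx <- sample.int(n, n1)
    mean(y[idx]) - mean(y[-idx])
  }, numeric(1))
  p <- (1 + sum(abs(perm) >= abs(obs))) / (n_perm + 1)
  list(p = p, observed = obs, n_perm = n_perm)
}

#' Benjamini-Hochberg rejection set across the sparsity grid
#'
#' Step-up FDR control over the per-sparsity p-values of a network metric.
#'
#' @param p_values Numeric vector of p-values (one per sparsity).
#' @param q Target false discovery rate (default 0.05).
#' @return Integer indices of rejected hypotheses (possibly empty).
#' @export
fdr_across_sparsities <- function(p_values, q = 0.05) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE)) stop("p-values must be in [0, 1]")
  which(stats::p.adjust(p_values, method = "BH") <= q)
}

#' Partial Spearman correlation
#'
#' Rank-transforms `x` and `y`, residualizes both rank vectors on the
#' covariates (with intercept), and reports the Pearson correlation of the
#' residuals with a t-approximation p-value on `n - 2 - k` degrees of
#' freedom. With no covariates this is exactly the ordinary Spearman
#' correlation.
#'
#' @param x,y Numeric vectors.
#' @param covariates Optional covariate table.
#' @return List with `rho`, `p`, `df`.
#' @export
partial_spearman <- function(x, y, covariates = NULL) {
  ok <- stats::complete.cases(x, y, if (is.null(covariates)) rep(TRUE, length(x)) else covariates)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  k <- 0L
  rx <- rank(x); ry <- rank(y)
  if (mean(duplicated(x)) > 0.5 || mean(duplicated(y)) > 0.5) {
    warning("more than half of the values are tied; rank correlation is unstable")
  }
  if (!is.null(covariates)) {
    cm <- stats::model.matrix(~ ., data = as.data.frame(covariates)[ok, , drop = FALSE])
    k <- ncol(cm) - 1L
    rx <- stats::lm.fit(cm, rx)$residuals
    ry <- stats::lm.fit(cm, ry)$residuals
  }
  if (n < k + 3L) stop("need at least covariates + 3 complete observations")
  rho <- stats::cor(rx, ry)
  df <- n - 2L - k
  tstat <- rho * sqrt(df / (1 - rho^2))
  p <- 2 * stats::pt(abs(tstat), df = df, lower.tail = FALSE)
  if (abs(rho) >= 1) p <- 0
  list(rho = rho, p = p, df = df)
}

#' ROC analysis of a discriminative score
#'
#' Sweeps every distinct score value as a decision threshold (score at or
#' above the threshold classifies as patient), reporting sensitivity and
#' specificity at each, the AUC via the Mann-Whitney identity (ties count
#' one half), and the Youden-optimal operating point maximizing
#' `sensitivity + specificity - 1`.
#'
#' @param scores_patients,scores_controls Numeric score vectors.
#' @return An object of class `roc_result`: `thresholds`, `sensitivity`,
#'   `specificity`, `auc`, `best_point` (list with `threshold`,
#'   `sensitivity`, `specificity`, `youden`).
#' @export
roc_analysis <- function(scores_patients, scores_controls) {
  if (length(scores_patients) < 1L || length(scores_controls) < 1L) {
    stop("need at least one score per group")
  }
  sp <- scores_patients; sc <- scores_controls
  thr <- sort(unique(c(sp, sc)))
  thr <- c(thr, max(thr) + 1)          # include the classify-none threshold
  sens <- vapply(thr, function(t) mean(sp >= t), numeric(1))
  spec <- vapply(thr, function(t) mean(sc < t), numeric(1))
  # Mann-Whitney identity: P(patient > control) + 0.5 P(tie)
  cmp <- outer(sp, sc, `-`)
  auc <- (sum(cmp > 0) + 0.5 * sum(cmp == 0)) / (length(sp) * length(sc))
  youden <- sens + spec - 1
  best <- which.max(youden)
  structure(
    list(thresholds = thr, sensitivity = sens, specificity = spec, auc = auc,
         best_point = list(threshold = thr[best], sensitivity = sens[best],
                           specificity = spec[best], youden = youden[best])),
    class = "roc_result"
  )
}

#' @export
print.roc_result <- function(x, ...) {
  bp <- x$best_point
  cat(sprintf("<roc_result> AUC = %.3f; best point: sensitivity %.1f%%, specificity %.1f%% (threshold %.4g)\n",
              x$auc, 100 * bp$sensitivity, 100 * bp$specificity, bp$threshold))
  invisible(x)
}
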