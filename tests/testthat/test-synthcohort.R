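test_that("config invariants are enforced", {
  expect_error(synthetic_config(n_volumes = 1), "n_volumes")
  expect_error(synthetic_config(tr = -1), "tr")
  expect_error(synthetic_config(band = c(0.1, 0.01)), "band")
  expect_error(synthetic_config(tr = 2, band = c(0.01, 0.3)), "band")
  bad <- matrix(c(1, 2, 0.5, 1), 2, 2)  # asymmetric
  expect_error(synthetic_config(base_cov = bad), "symmetric")
  notpsd <- matrix(c(1, 2, 2, 1), 2, 2)
  expect_error(synthetic_config(base_cov = notpsd), "semi-definite")
  expect_error(synthetic_config(grid_shape = c(4, 4, 4),
                                hub_voxels = matrix(c(9, 1, 1), 1)),
               "hub")
})

test_that("a non-PSD covariance after adding the group effect is rejected", {
  base <- diag(2)
  delta <- matrix(c(0, 3, 3, 0), 2, 2)  # pushes eigenvalues negative
  cfg <- synthetic_config(n_group_a = 2L, n_group_b = 2L,
                          grid_shape = c(3L, 3L, 3L), n_volumes = 20L,
                          n_regions = 2L, base_cov = base,
                          effect_delta = delta, seed = 1L)
  expect_error(generate_cohort(cfg), "positive semi-definite")
})

test_that("the same seed reproduces the cohort bit-identically", {
  cfg <- tiny_config(seed = 9L)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$runs, b$runs)
  expect_identical(a$truth$true_scores_latent, b$truth$true_scores_latent)
  expect_identical(generate_motion_traces(cfg), generate_motion_traces(cfg))
  expect_identical(generate_clinical(a$truth), generate_clinical(b$truth))
})

test_that("group labels partition subjects and hubs lie inside the mask", {
  co <- generate_cohort(tiny_config(seed = 5L))
  expect_equal(sum(co$truth$group_labels == "A"), 4L)
  expect_equal(sum(co$truth$group_labels == "B"), 4L)
  expect_true(all(co$truth$mask[co$truth$hub_index]))
})

test_that("with no group effect the two groups share the same correlation structure", {
  cfg <- synthetic_config(n_group_a = 12L, n_group_b = 12L,
                          grid_shape = c(4L, 4L, 4L), n_volumes = 120L,
                          n_regions = 4L,
                          effect_delta = matrix(0, 4, 4), seed = 21L)
  co <- generate_cohort(cfg)
  reg <- as.vector(co$truth$region_labels)
  mean_offdiag <- vapply(co$runs, function(r) {
    m <- sapply(1:4, function(g) {
      colMeans(matrix(r$data, ncol = dim(r$data)[4])[reg == g, , drop = FALSE])
    })
    cm <- cor(m)
    mean(cm[upper.tri(cm)])
  }, numeric(1))
  grp <- co$truth$group_labels
  # group means of the mean off-diagonal ROI correlation agree within
  # sampling error (SE of a correlation at ~40 effective dof, 12 subjects)
  expect_lt(abs(mean(mean_offdiag[grp == "A"]) - mean(mean_offdiag[grp == "B"])),
            0.12)
})

test_that("pooled empirical ROI correlation recovers the nominal value", {
  # two regions at r = 0.6, 180 volumes, 200 subjects: the pooled empirical
  # correlation of the region mean series must land within 0.05 of nominal
  bc <- matrix(c(1, 0.6, 0.6, 1), 2, 2)
  cfg <- synthetic_config(n_group_a = 200L, n_group_b = 0L,
                          grid_shape = c(4L, 4L, 4L), n_volumes = 180L,
                          n_regions = 2L, base_cov = bc,
                          effect_delta = matrix(0, 2, 2), seed = 11L)
  co <- generate_cohort(cfg)
  reg <- as.vector(co$truth$region_labels)
  rs <- vapply(co$runs, function(r) {
    m <- matrix(r$data, ncol = dim(r$data)[4])
    cor(colMeans(m[reg == 1, ]), colMeans(m[reg == 2, ]))
  }, numeric(1))
  expect_lt(abs(mean(rs) - 0.6), 0.05)
})

test_that("generated series concentrate their power in the configured band", {
  cfg <- synthetic_config(n_group_a = 1L, n_group_b = 0L,
                          grid_shape = c(3L, 3L, 3L), n_volumes = 180L,
                          n_regions = 3L, noise_sd = 0, seed = 13L)
  co <- generate_cohort(cfg)
  run <- co$runs[[1]]
  mat <- matrix(run$data, ncol = 180)
  mat <- mat[-co$truth$hub_index[1], ]  # hub carries extra (in-band) noise
  freqs <- seq(0, 179) / (180 * run$tr)
  freqs <- pmin(freqs, 1 / run$tr - freqs)
  inband <- freqs >= 0.01 & freqs <= 0.1
  pow <- abs(mvfft(t(mat)))^2
  expect_gt(sum(pow[inband, ]) / sum(pow), 0.8)
})

test_that("group-B-minus-group-A ROI correlation approaches the planted increment", {
  bc <- matrix(c(1, 0.2, 0.2, 1), 2, 2)
  dl <- matrix(c(0, 0.3, 0.3, 0), 2, 2)
  cfg <- synthetic_config(n_group_a = 80L, n_group_b = 80L,
                          grid_shape = c(4L, 4L, 4L), n_volumes = 180L,
                          n_regions = 2L, base_cov = bc, effect_delta = dl,
                          seed = 31L)
  co <- generate_cohort(cfg)
  reg <- as.vector(co$truth$region_labels)
  rs <- vapply(co$runs, function(r) {
    m <- matrix(r$data, ncol = dim(r$data)[4])
    cor(colMeans(m[reg == 1, ]), colMeans(m[reg == 2, ]))
  }, numeric(1))
  grp <- co$truth$group_labels
  diff_obs <- mean(rs[grp == "B"]) - mean(rs[grp == "A"])
  # patients draw a lognormal severity with mean ~1.03, so the implied mean
  # increment is ~0.31; allow Monte-Carlo slack at n = 80 per group
  expect_gt(diff_obs, 0.2)
  expect_lt(diff_obs, 0.4)
})

test_that("clinical scores follow the configured coupling", {
  sc <- list(sev = list(center = 0, slope = 2, sd = 0, range = NULL))
  cfg <- tiny_config(seed = 17L, score_coupling = sc,
                     n_group_a = 2L, n_group_b = 6L)
  co <- generate_cohort(cfg)
  cl <- generate_clinical(co$truth)
  is_b <- co$truth$group_labels == "B"
  # zero noise + positive slope: score is a strictly monotone map of latent
  expect_equal(cor(cl$sev[is_b], co$truth$true_scores_latent[is_b],
                   method = "spearman"), 1)
  # controls carry missing codes, not zeros
  expect_true(all(is.na(cl$sev[!is_b])))
  # zero slope: no coupling on average over many cohorts
  sc0 <- list(sev = list(center = 0, slope = 0, sd = 1, range = NULL))
  rs <- vapply(1:60, function(k) {
    cfgk <- tiny_config(seed = 100L + k, score_coupling = sc0,
                        n_group_a = 2L, n_group_b = 10L)
    cok <- generate_cohort(cfgk)
    clk <- generate_clinical(cok$truth)
    bk <- cok$truth$group_labels == "B"
    cor(clk$sev[bk], cok$truth$true_scores_latent[bk], method = "spearman")
  }, numeric(1))
  expect_lt(abs(mean(rs)), 0.1)
})

test_that("missing coupling specification names the offending score", {
  cfg <- tiny_config(score_coupling = list(tremor = list(center = 2)))
  co <- generate_cohort(cfg)
  expect_error(generate_clinical(co$truth), "tremor")
})

test_that("a coupling tuned for rho = 0.6 at n = 16 is recovered on average", {
  # slope/noise chosen so the latent-score Pearson correlation is 0.6;
  # oracle: direct simulation from the same latent distribution
  set.seed(99)
  sd_l <- sd(exp(rnorm(2e5, 0, 0.25)))
  noise <- sd_l * sqrt(1 / 0.36 - 1)
  n_rep <- 400L
  oracle <- vapply(seq_len(n_rep), function(k) {
    l <- exp(rnorm(16, 0, 0.25))
    cor(l, l + rnorm(16, 0, noise), method = "spearman")
  }, numeric(1))
  sc <- list(sev = list(center = 0, slope = 1, sd = noise, range = NULL))
  recovered <- vapply(seq_len(n_rep), function(k) {
    cfgk <- synthetic_config(n_group_a = 0L, n_group_b = 16L,
                             grid_shape = c(2L, 2L, 2L), n_volumes = 16L,
                             n_regions = 2L, score_coupling = sc,
                             seed = 5000L + k)
    cok <- generate_cohort(cfgk)
    clk <- generate_clinical(cok$truth)
    partial_spearman(clk$sev, cok$truth$true_scores_latent)$rho
  }, numeric(1))
  se <- sqrt(var(oracle) / n_rep + var(recovered) / n_rep)
  expect_lt(abs(mean(recovered) - mean(oracle)), 1.96 * se + 0.02)
})

test_that("motion traces are bounded, deterministic and degenerate at zero amplitude", {
  cfg <- synthetic_config(n_group_a = 10L, n_group_b = 10L,
                          grid_shape = c(3L, 3L, 3L), n_volumes = 180L,
                          n_regions = 3L, seed = 23L)
  tr1 <- generate_motion_traces(cfg)
  expect_length(tr1, 20L)
  expect_true(all(vapply(tr1, nrow, integer(1)) == 180L))
  # default bounds never trip the 3 mm / 3 degree exclusion rule
  max_trans <- max(vapply(tr1, function(m) max(abs(m[, 1:3])), numeric(1)))
  max_rot <- max(vapply(tr1, function(m) max(abs(m[, 4:6])), numeric(1)))
  expect_lt(max_trans, 3)
  expect_lt(max_rot, 3 * pi / 180)
  expect_identical(tr1, generate_motion_traces(cfg))
  # zero amplitude degenerates to all-zero traces and zero FD
  cfg0 <- synthetic_config(n_group_a = 1L, n_group_b = 1L,
                           grid_shape = c(3L, 3L, 3L), n_volumes = 20L,
                           n_regions = 3L, motion_sd = 0, seed = 2L)
  tr0 <- generate_motion_traces(cfg0)
  expect_true(all(tr0[[1]] == 0))
  expect_equal(motion_summaries(tr0[[1]])$mean_fd, 0)
})

test_that("written cohorts round-trip through the declared file formats", {
  dir <- withr::local_tempdir()
  cfg <- tiny_config(seed = 3L)
  co <- generate_cohort(cfg)
  write_cohort(co, dir)
  expect_true(file.exists(file.path(dir, "sub-001_bold.nii.gz")))
  img <- RNifti::readNifti(file.path(dir, "sub-001_bold.nii.gz"))
  expect_equal(dim(img), c(4L, 4L, 4L, 40L))
  expect_equal(array(as.array(img), dim(img)), co$runs[[1]]$data,
               tolerance = 1e-6)
  rp <- as.matrix(read.table(file.path(dir, "rp_sub-001.txt")))
  expect_equal(dim(rp), c(40L, 6L))
  cl <- read.table(file.path(dir, "clinical.tsv"), sep = "\t", header = TRUE)
  expect_equal(nrow(cl), 8L)
  truth <- jsonlite::read_json(file.path(dir, "truth.json"), simplifyVector = TRUE)
  expect_equal(truth$seed, 3L)
  expect_equal(truth$group_labels, co$truth$group_labels)
})
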