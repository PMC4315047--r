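test_that("ROI correlation matrices match the pairwise oracle", {
  set.seed(31)
  x <- matrix(rnorm(60 * 5), 60, 5)
  net <- roi_correlation_matrix(x)
  for (i in 1:4) for (j in (i + 1):5) {
    expect_equal(net$corr[i, j], cor(x[, i], x[, j]), tolerance = 1e-12)
  }
  expect_equal(diag(net$corr), rep(1, 5))
  expect_true(isSymmetric(net$corr))
  # duplicated series give off-diagonal 1
  y <- cbind(x[, 1], x[, 1], x[, 2])
  expect_equal(roi_correlation_matrix(y)$corr[1, 2], 1)
  # constant ROI names the offender
  z <- cbind(a = x[, 1], b = x[, 2], c = rep(1, 60))
  expect_error(roi_correlation_matrix(z), "c")
  expect_error(roi_correlation_matrix(x[, 1:2]), "3 ROIs")
})

test_that("sparsity thresholding keeps the right edge count and nests", {
  set.seed(33)
  x <- matrix(rnorm(100 * 5), 100, 5) + rnorm(100)  # shared signal: positive r
  net <- roi_correlation_matrix(x)
  g <- sparsity_threshold(net, 0.5)
  expect_equal(edge_count(g), round(0.5 * 10))
  expect_equal(diag(g$adjacency), rep(0, 5))
  # s = 1 with all-positive correlations reproduces the matrix off-diagonal
  pos <- abs(net$corr); diag(pos) <- 1
  g1 <- sparsity_threshold(pos, 1)
  expect_equal(g1$adjacency, pos - diag(5), tolerance = 1e-12)
  # nesting across the full grid
  grid <- seq(0.08, 0.6, by = 0.02)
  set.seed(34)
  big <- roi_correlation_matrix(matrix(rnorm(80 * 12), 80, 12) + rnorm(80))
  prev <- NULL
  for (s in grid) {
    gs <- suppressWarnings(sparsity_threshold(big, s))
    edges <- which(gs$adjacency > 0)
    if (!is.null(prev)) expect_true(all(prev %in% edges))
    prev <- edges
  }
})

test_that("requesting more edges than positive correlations warns and records sparsity", {
  corr <- diag(4)
  corr[1, 2] <- corr[2, 1] <- 0.5
  corr[3, 4] <- corr[4, 3] <- -0.4
  expect_warning(g <- sparsity_threshold(corr, 0.9), "positive")
  expect_equal(edge_count(g), 1L)
  expect_equal(g$sparsity, 1 / 6)
})

test_that("efficiency matches closed forms on canonical graphs", {
  full <- matrix(1, 4, 4); diag(full) <- 0
  expect_equal(global_efficiency(full), 1)
  expect_equal(global_efficiency(matrix(0, 4, 4)), 0)
  path <- matrix(0, 3, 3)
  path[1, 2] <- path[2, 1] <- 0.5
  path[2, 3] <- path[3, 2] <- 0.5
  expect_equal(global_efficiency(path), 5 / 12)   # d = 2, 2, 4 by hand
  tri <- matrix(1, 3, 3); diag(tri) <- 0
  expect_equal(local_efficiency(tri), 1)
  star <- matrix(0, 4, 4); star[1, 2:4] <- star[2:4, 1] <- 1
  expect_equal(local_efficiency(star), 0)
})

test_that("weighted efficiencies equal the brute-force path oracle", {
  set.seed(35)
  for (k in 1:20) {
    adj <- random_weighted_graph(sample(4:8, 1), p = 0.5)
    expect_lt(abs(global_efficiency(adj) - brute_force_global_efficiency(adj)),
              1e-12)
    expect_lt(abs(local_efficiency(adj) - brute_force_local_efficiency(adj)),
              1e-12)
  }
})

test_that("shortest paths agree with an independent Dijkstra implementation", {
  skip_if_not_installed("igraph")
  set.seed(36)
  for (k in 1:25) {
    adj <- random_weighted_graph(sample(5:12, 1), p = 0.4)
    if (all(adj == 0)) next
    d_mine <- tremornet:::shortest_path_lengths(adj)
    ig <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                              weighted = TRUE)
    d_ig <- igraph::distances(ig, weights = 1 / igraph::E(ig)$weight,
                              algorithm = "dijkstra")
    expect_equal(unname(d_mine), unname(d_ig), tolerance = 1e-12)
  }
})

test_that("unit-weight efficiencies equal binary efficiencies", {
  set.seed(37)
  adj <- random_weighted_graph(8, p = 0.5)
  bin <- (adj > 0) * 1
  expect_equal(global_efficiency(bin), brute_force_global_efficiency(bin),
               tolerance = 1e-12)
  # weighted equals binary when all weights are 1
  expect_equal(global_efficiency(bin), global_efficiency((adj > 0) * 1L))
})

test_that("global efficiency is non-decreasing along the nested sweep", {
  set.seed(38)
  net <- roi_correlation_matrix(matrix(rnorm(60 * 10), 60, 10))
  # a random matrix can run out of positive correlations at high sparsity;
  # that path warns and caps the achieved sparsity, which is fine here
  cv <- suppressWarnings(efficiency_curve(net, seq(0.08, 0.6, by = 0.02)))
  expect_true(all(diff(cv$e_glob) >= -1e-12))
  expect_true(all(cv$e_glob >= 0 & cv$e_glob <= 10 / 9 + 1e-12))
})

test_that("null surrogates preserve nodes, edges, degrees and weights", {
  set.seed(39)
  adj <- random_weighted_graph(10, p = 0.4)
  g <- structure(list(adjacency = adj, sparsity = edge_count(adj) / 45),
                 class = "weighted_graph")
  nulls <- generate_null_ensemble(g, n_null = 20, seed = 6)
  for (nl in nulls) {
    expect_equal(dim(nl$adjacency), dim(adj))
    expect_equal(edge_count(nl), edge_count(adj))
    expect_equal(degree_sequence(nl), degree_sequence(adj))
    expect_equal(sort(nl$adjacency[upper.tri(nl$adjacency) & nl$adjacency > 0]),
                 sort(adj[upper.tri(adj) & adj > 0]))
  }
  # deterministic given the seed
  again <- generate_null_ensemble(g, n_null = 20, seed = 6)
  expect_identical(nulls, again)
  expect_false(identical(nulls[[1]]$adjacency, nulls[[2]]$adjacency))
})

test_that("rewiring a ring lattice raises mean null global efficiency", {
  ring <- ring_lattice_graph(16, k = 2)
  nulls <- generate_null_ensemble(ring, n_null = 50, seed = 8)
  e_null <- vapply(nulls, global_efficiency, numeric(1))
  expect_gt(mean(e_null), global_efficiency(ring))
})

test_that("normalization is exact under self-normalization and scale-consistent", {
  real <- c(0.5, 0.6, 0.7)
  nulls <- rbind(real, real, real)
  expect_equal(normalized_efficiency(real, nulls), c(1, 1, 1))
  # e_loc_norm = 1 fails the strict "> 1" small-world requirement
  expect_false(small_world_flag(rep(1, 3), rep(1, 3)))
  expect_true(small_world_flag(c(1.3, 1.2, 1.1), c(1.02, 0.98, 1.0)))
  expect_false(small_world_flag(c(1.3, 1.2, 1.1), c(1.5, 1.6, 1.4)))
  # doubling all weights doubles real and null efficiencies alike
  set.seed(40)
  adj <- random_weighted_graph(8, p = 0.5)
  nulls1 <- generate_null_ensemble(adj, n_null = 10, seed = 3)
  r1 <- normalized_efficiency(global_efficiency(adj),
                              matrix(vapply(nulls1, global_efficiency,
                                            numeric(1)), ncol = 1))
  nulls2 <- generate_null_ensemble(2 * adj, n_null = 10, seed = 3)
  r2 <- normalized_efficiency(global_efficiency(2 * adj),
                              matrix(vapply(nulls2, global_efficiency,
                                            numeric(1)), ncol = 1))
  expect_equal(r1, r2, tolerance = 1e-12)
  expect_warning(out <- normalized_efficiency(c(1, 1), rbind(c(0, 1))), "zero null")
  expect_true(is.na(out[1]))
})

test_that("a modular network is small-world against degree-matched nulls", {
  # dense blocks with sparse bridges: high clustering, short paths
  set.seed(41)
  cfg <- synthetic_config(n_group_a = 6L, n_group_b = 0L,
                          grid_shape = c(4L, 4L, 4L), n_volumes = 160L,
                          n_regions = 8L, noise_sd = 0.3, seed = 43L)
  co <- generate_cohort(cfg)
  reg <- as.vector(co$truth$region_labels)
  nets <- lapply(co$runs, function(r) {
    m <- sapply(1:8, function(g) colMeans(matrix(r$data, ncol = 160)[reg == g, , drop = FALSE]))
    roi_correlation_matrix(m)
  })
  corr <- Reduce(`+`, lapply(nets, `[[`, "corr")) / length(nets)
  cv <- efficiency_curve(corr, seq(0.2, 0.5, by = 0.05), n_null = 30, seed = 2)
  expect_gt(mean(cv$e_loc_norm, na.rm = TRUE), 1)
})

test_that("the trapezoid AUC matches closed forms and an independent oracle", {
  grid <- seq(0.08, 0.6, by = 0.02)
  expect_equal(metric_auc(grid, rep(3, 27)), 0.52 * 3)
  expect_equal(metric_auc(c(0.08, 0.6), c(0, 1)), 0.26)
  set.seed(42)
  v <- runif(27)
  oracle <- sum(vapply(seq_len(26), function(i) {
    (grid[i + 1] - grid[i]) * (v[i] + v[i + 1]) / 2
  }, numeric(1)))
  expect_equal(metric_auc(grid, v), oracle, tolerance = 1e-12)
  expect_equal(metric_auc(grid, rep(0, 27)), 0)
  expect_error(metric_auc(grid, runif(5)), "lengths")
  expect_error(metric_auc(c(0.1, 0.1, 0.2), 1:3), "increasing")
})
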