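# Independent oracles and fixture builders shared across the test files.
# Everything here is deliberately naive (exhaustive enumeration, direct
# formulas) so it cannot share a bug with the implementation it checks.

# --- exhaustive shortest paths ---------------------------------------------

# All-pairs shortest path lengths by recursive enumeration of every simple
# path (edge length = 1 / weight). Only feasible for <= 8 nodes.
brute_force_distances <- function(adj) {
  n <- nrow(adj)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  nbrs <- lapply(seq_len(n), function(i) which(adj[i, ] > 0))
  explore <- function(node, target, visited, len) {
    if (node == target) {
      if (len < d[source, target]) d[source, target] <<- len
      return(invisible())
    }
    for (nb in nbrs[[node]]) {
      if (!visited[nb]) {
        visited[nb] <- TRUE
        explore(nb, target, visited, len + 1 / adj[node, nb])
        visited[nb] <- FALSE
      }
    }
  }
  for (source in seq_len(n)) {
    for (target in seq_len(n)) {
      if (source == target) next
      visited <- logical(n)
      visited[source] <- TRUE
      explore(source, target, visited, 0)
    }
  }
  d
}

brute_force_global_efficiency <- function(adj) {
  n <- nrow(adj)
  if (n < 2 || all(adj == 0)) return(0)
  d <- brute_force_distances(adj)
  inv <- 1 / d
  diag(inv) <- 0
  sum(inv[is.finite(inv)]) / (n * (n - 1))
}

brute_force_local_efficiency <- function(adj) {
  n <- nrow(adj)
  vals <- vapply(seq_len(n), function(i) {
    nb <- which(adj[i, ] > 0)
    if (length(nb) < 2) return(0)
    brute_force_global_efficiency(adj[nb, nb, drop = FALSE])
  }, numeric(1))
  mean(vals)
}

# --- naive weighted degree centrality --------------------------------------

naive_wdc <- function(series, alpha = 0.05,
                      n_tests_mode = c("per_voxel", "pairwise")) {
  n_tests_mode <- match.arg(n_tests_mode)
  n <- nrow(series)
  n_tests <- if (n_tests_mode == "per_voxel") n - 1 else n * (n - 1) / 2
  r_thr <- bonferroni_r_threshold(alpha, n_tests, ncol(series))
  r <- cor(t(series))
  r[r < r_thr] <- 0
  diag(r) <- 0
  rowSums(r)
}

# --- random graphs ----------------------------------------------------------

random_weighted_graph <- function(n, p = 0.45, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  adj <- matrix(0, n, n)
  ut <- which(upper.tri(adj))
  on <- ut[runif(length(ut)) < p]
  adj[on] <- runif(length(on), 0.1, 1)
  adj + t(adj)
}

ring_lattice_graph <- function(n, k = 2) {
  adj <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (off in seq_len(k)) {
      j <- (i + off - 1) %% n + 1
      adj[i, j] <- adj[j, i] <- 1
    }
  }
  adj
}

degree_sequence <- function(g) {
  adj <- if (inherits(g, "weighted_graph")) g$adjacency else g
  sort(colSums(adj > 0))
}

edge_count <- function(g) {
  adj <- if (inherits(g, "weighted_graph")) g$adjacency else g
  sum(adj[upper.tri(adj)] > 0)
}

# --- small cohort fixtures ---------------------------------------------------

tiny_config <- function(n_group_a = 4L, n_group_b = 4L, seed = 42L, ...) {
  synthetic_config(
    n_group_a = n_group_a, n_group_b = n_group_b, grid_shape = c(4L, 4L, 4L),
    n_volumes = 40L, n_regions = 4L, seed = seed, ...
  )
}

# A bold_run with fully scripted voxel series (voxels x time matrix laid out
# on a small grid); handy for closed-form filter and regression checks.
run_from_matrix <- function(mat, tr = 2, dim3 = NULL) {
  n_vox <- nrow(mat)
  if (is.null(dim3)) dim3 <- c(n_vox, 1L, 1L)
  stopifnot(prod(dim3) == n_vox)
  arr <- array(as.numeric(mat), dim = c(dim3, ncol(mat)))
  bold_run(arr, tr = tr)
}
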