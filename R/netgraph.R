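#' ROI-to-ROI correlation network
#'
#' Pairwise Pearson correlation of ROI mean time series: a symmetric matrix
#' with unit diagonal, the raw material for sparsity-thresholded weighted
#' graphs.
#'
#' @param series_set Time x ROI numeric matrix (or data.frame) of ROI mean
#'   series; columns may be named.
#' @return An object of class `roi_network` with `corr` and `labels`.
#' @export
roi_correlation_matrix <- function(series_set) {
  m <- as.matrix(series_set)
  if (ncol(m) < 3L) stop("need at least 3 ROIs")
  sds <- apply(m, 2L, stats::sd)
  if (any(sds == 0)) {
    bad <- colnames(m)[sds == 0]
    if (is.null(bad)) bad <- which(sds == 0)
    stop("constant ROI series: ", paste(bad, collapse = ", "))
  }
  corr <- stats::cor(m)
  corr <- (corr + t(corr)) / 2
  diag(corr) <- 1
  labels <- colnames(m)
  if (is.null(labels)) labels <- sprintf("roi%02d", seq_len(ncol(m)))
  structure(list(corr = corr, labels = labels), class = "roi_network")
}

#' @export
print.roi_network <- function(x, ...) {
  n <- nrow(x$corr)
  off <- x$corr[upper.tri(x$corr)]
  cat(sprintf("<roi_network> %d ROIs, mean off-diagonal r = %.3f\n", n, mean(off)))
  invisible(x)
}

#' Threshold a correlation network at a target sparsity
#'
#' Keeps the `round(s * N(N-1)/2)` largest positive correlations as weighted
#' edges (weights are the correlation values themselves); everything else,
#' including all negative correlations, is zero. Edges are ranked by value
#' with ties broken by lexicographic node-pair order, so edge sets are
#' nested across increasing sparsity. If fewer positive correlations exist
#' than requested, all positives are kept, the achieved sparsity is
#' recorded, and a warning is raised.
#'
#' @param net A [roi_correlation_matrix()] result, or a bare symmetric
#'   correlation matrix.
#' @param s Target sparsity in `(0, 1]`: edge fraction out of all node
#'   pairs.
#' @return An object of class `weighted_graph` with `adjacency` (symmetric,
#'   zero diagonal) and `sparsity` (achieved).
#' @export
sparsity_threshold <- function(net, s) {
  corr <- if (inherits(net, "roi_network")) net$corr else as.matrix(net)
  if (!(s > 0 && s <= 1)) stop("sparsity must be in (0, 1]")
  n <- nrow(corr)
  n_pairs <- n * (n - 1) / 2
  m_target <- round(s * n_pairs)
  ut <- which(upper.tri(corr), arr.ind = TRUE)
  vals <- corr[upper.tri(corr)]
  pos <- vals > 0
  ord <- order(-vals, ut[, 1L], ut[, 2L])
  ord <- ord[pos[ord]]
  if (length(ord) < m_target) {
    warning(sprintf("only %d positive correlations for %d requested edges; keeping all positives",
                    length(ord), m_target))
    keep <- ord
  } else {
    keep <- ord[seq_len(m_target)]
  }
  adj <- matrix(0, n, n)
  adj[cbind(ut[keep, 1L], ut[keep, 2L])] <- vals[keep]
  adj <- adj + t(adj)
  structure(list(adjacency = adj, sparsity = length(keep) / n_pairs),
            class = "weighted_graph")
}

#' @export
print.weighted_graph <- function(x, ...) {
  n <- nrow(x$adjacency)
  m <- sum(x$adjacency[upper.tri(x$adjacency)] > 0)
  cat(sprintf("<weighted_graph> %d nodes, %d edges, sparsity %.3f\n",
              n, m, x$sparsity))
  invisible(x)
}

graph_adjacency <- function(g) {
  if (inherits(g, "weighted_graph")) g$adjacency else as.matrix(g)
}

# All-pairs shortest path lengths with edge length = 1 / weight
# (Floyd-Warshall, vectorized over the intermediate node; the networks here
# have at most a few dozen nodes so O(N^3) is immediate).
shortest_path_lengths <- function(adj) {
  n <- nrow(adj)
  d <- ifelse(adj > 0, 1 / adj, Inf)
  diag(d) <- 0
  for (k in seq_len(n)) {
    dk <- outer(d[, k], d[k, ], `+`)
    upd <- dk < d
    if (any(upd)) d[upd] <- dk[upd]
  }
  d
}

#' Weighted global efficiency
#'
#' Mean inverse shortest-path length over all ordered node pairs,
#' `E = 1/(N(N-1)) * sum_{i != j} 1/d_ij`, where `d_ij` is the smallest sum
#' of edge lengths (length = reciprocal of edge weight) over all paths.
#' Disconnected pairs contribute 0 (the `1/d -> 0` convention).
#'
#' @param g A `weighted_graph` or a symmetric non-negative adjacency matrix.
#' @return Scalar efficiency (0 for an edgeless or single-node graph).
#' @export
global_efficiency <- function(g) {
  adj <- graph_adjacency(g)
  n <- nrow(adj)
  if (n < 2L || all(adj == 0)) return(0)
  d <- shortest_path_lengths(adj)
  inv <- 1 / d
  diag(inv) <- 0
  sum(inv[is.finite(inv)]) / (n * (n - 1))
}

#' Weighted local efficiency
#'
#' Mean over nodes of the global efficiency of the node's neighbour-induced
#' subgraph (neighbours = nodes with a direct edge to the index node;
#' subgraph keeps the original weights among them). Nodes with fewer than
#' two neighbours contribute 0. Measures fault tolerance: how well a node's
#' neighbourhood communicates when the node is removed.
#'
#' @inheritParams global_efficiency
#' @return Scalar local efficiency.
#' @export
local_efficiency <- function(g) {
  adj <- graph_adjacency(g)
  n <- nrow(adj)
  if (n == 0L) return(0)
  eff <- vapply(seq_len(n), function(i) {
    nb <- which(adj[i, ] > 0)
    if (length(nb) < 2L) return(0)
    global_efficiency(adj[nb, nb, drop = FALSE])
  }, numeric(1))
  mean(eff)
}

edge_list <- function(adj) {
  ut <- which(upper.tri(adj) & adj > 0, arr.ind = TRUE)
  cbind(ut, w = adj[ut])
}

#' Degree-preserving random surrogates of a weighted graph
#'
#' Maslov-Sneppen double-edge swaps on the binary topology: repeatedly pick
#' two edges (a,b), (c,d) with four distinct endpoints and rewire them to
#' (a,d), (c,b), rejecting swaps that would create self-loops or duplicate
#' edges. Each edge carries its weight with it through the swap, so node
#' count, edge count, the full binary degree sequence and the weight
#' multiset are all preserved exactly. Deterministic given `seed`.
#'
#' @param g A `weighted_graph` or adjacency matrix.
#' @param n_null Number of surrogates (default 100).
#' @param n_swaps_per_edge Accepted swaps per edge (default 10).
#' @param seed Integer seed for the ensemble.
#' @return List of `weighted_graph` surrogates. If a graph is so dense that
#'   the retry budget is exhausted before the target swap count, a warning
#'   is raised and the surrogate is returned with fewer swaps.
#' @export
generate_null_ensemble <- function(g, n_null = 100L, n_swaps_per_edge = 10L,
                                   seed = 1L) {
  adj <- graph_adjacency(g)
  el <- edge_list(adj)
  m <- nrow(el)
  if (m < 2L) stop("need at least 2 edges to swap")
  n <- nrow(adj)
  sp <- if (inherits(g, "weighted_graph")) g$sparsity else m / (n * (n - 1) / 2)
  target <- n_swaps_per_edge * m
  budget <- 100L * target
  n_short <- 0L
  out <- lapply(seq_len(n_null), function(r) {
    set.seed(subseed(seed, 9000L + r))
    e <- el
    present <- adj > 0
    done <- 0L; tries <- 0L
    while (done < target && tries < budget) {
      tries <- tries + 1L
      pick <- sample.int(m, 2L)
      a <- e[pick[1L], 1L]; b <- e[pick[1L], 2L]
      c_ <- e[pick[2L], 1L]; d <- e[pick[2L], 2L]
      # randomize which endpoints pair up
      if (stats::runif(1) < 0.5) { tmp <- c_; c_ <- d; d <- tmp }
      if (length(unique(c(a, b, c_, d))) < 4L) next
      if (present[a, d] || present[c_, b]) next
      present[a, b] <- present[b, a] <- FALSE
      present[c_, d] <- present[d, c_] <- FALSE
      present[a, d] <- present[d, a] <- TRUE
      present[c_, b] <- present[b, c_] <- TRUE
      e[pick[1L], 1:2] <- c(min(a, d), max(a, d))
      e[pick[2L], 1:2] <- c(min(c_, b), max(c_, b))
      done <- done + 1L
    }
    if (done < target) n_short <<- n_short + 1L
    nadj <- matrix(0, n, n)
    nadj[e[, 1:2, drop = FALSE]] <- e[, 3L]
    nadj <- nadj + t(nadj)
    structure(list(adjacency = nadj, sparsity = sp), class = "weighted_graph")
  })
  if (n_short > 0L) {
    warning(sprintf("%d of %d null(s) reached the retry budget before %d swaps (graph too dense or too small)",
                    n_short, n_null, target))
  }
  out
}

#' Null-normalized efficiency and small-world assessment
#'
#' Divides each real efficiency value by the mean of the corresponding
#' null-ensemble values. A network is flagged small-world when, over at
#' least `majority` of the sparsity grid, the normalized local efficiency
#' exceeds 1 while the normalized global efficiency stays within
#' `tolerance` of 1.
#'
#' @param real Numeric vector of real efficiencies over the sparsity grid.
#' @param null_values Matrix of null efficiencies, `n_null` rows x grid
#'   columns (a vector is treated as one null).
#' @param tolerance Allowed deviation of normalized global efficiency from 1
#'   when judging small-worldness (default 0.2). Only used when `glob_norm`
#'   is supplied to `small_world_flag`.
#' @return `normalized_efficiency()` returns the ratio vector (`NA` where
#'   the null mean is zero, with a warning). `small_world_flag()` combines
#'   two normalized curves into a logical flag.
#' @export
normalized_efficiency <- function(real, null_values) {
  if (is.vector(null_values)) null_values <- matrix(null_values, nrow = 1L)
  if (ncol(null_values) != length(real)) stop("null grid does not match the real curve")
  mu <- colMeans(null_values)
  out <- real / mu
  if (any(mu == 0)) {
    warning("zero null mean at ", sum(mu == 0), " sparsity value(s); ratio undefined there")
    out[mu == 0] <- NA_real_
  }
  out
}

#' @rdname normalized_efficiency
#' @param loc_norm,glob_norm Normalized local/global efficiency curves.
#' @param majority Fraction of grid points that must satisfy the criterion
#'   (default 0.5).
#' @export
small_world_flag <- function(loc_norm, glob_norm, tolerance = 0.2,
                             majority = 0.5) {
  ok <- loc_norm > 1 & abs(glob_norm - 1) <= tolerance
  mean(ok, na.rm = TRUE) >= majority
}

#' Area under a metric-versus-sparsity curve
#'
#' Trapezoidal integral of a network metric over the sparsity grid, the
#' standard threshold-free summary.
#'
#' @param sparsities Strictly increasing grid (>= 2 points).
#' @param values Metric values at each grid point.
#' @return Scalar area.
#' @export
metric_auc <- function(sparsities, values) {
  if (length(sparsities) != length(values)) stop("grid and values lengths differ")
  if (length(sparsities) < 2L) stop("need at least 2 grid points")
  if (any(diff(sparsities) <= 0)) stop("sparsities must be strictly increasing")
  sum(diff(sparsities) * (values[-1] + values[-length(values)]) / 2)
}

#' Efficiency curves over a sparsity sweep
#'
#' Thresholds a correlation network at every sparsity in the grid, computes
#' weighted global and local efficiency, optionally normalizes both by a
#' degree-preserving null ensemble per sparsity, and summarizes each raw
#' curve by its trapezoidal AUC.
#'
#' @param net A [roi_correlation_matrix()] result or correlation matrix.
#' @param sparsities Sparsity grid (default `seq(0.08, 0.6, by = 0.02)`).
#' @param n_null Null surrogates per sparsity (default 0 = skip
#'   normalization; the convention in group analyses is 100).
#' @param n_swaps_per_edge Swaps per edge for the nulls (default 10).
#' @param seed Seed for the null ensembles.
#' @return An object of class `efficiency_curve`: `sparsities`, `e_glob`,
#'   `e_loc`, `auc_glob`, `auc_loc`, and when `n_null > 0` also
#'   `e_glob_norm`, `e_loc_norm` and `small_world`.
#' @export
efficiency_curve <- function(net, sparsities = seq(0.08, 0.6, by = 0.02),
                             n_null = 0L, n_swaps_per_edge = 10L, seed = 1L) {
  graphs <- lapply(sparsities, function(s) sparsity_threshold(net, s))
  e_glob <- vapply(graphs, global_efficiency, numeric(1))
  e_loc <- vapply(graphs, local_efficiency, numeric(1))
  out <- list(sparsities = sparsities, e_glob = e_glob, e_loc = e_loc,
              auc_glob = metric_auc(sparsities, e_glob),
              auc_loc = metric_auc(sparsities, e_loc))
  if (n_null > 0L) {
    null_g <- matrix(NA_real_, n_null, length(sparsities))
    null_l <- matrix(NA_real_, n_null, length(sparsities))
    for (i in seq_along(sparsities)) {
      adj <- graphs[[i]]$adjacency
      if (sum(adj[upper.tri(adj)] > 0) < 2L) {
        # nothing to rewire: the graph is its own (only) degree-matched null
        null_g[, i] <- e_glob[i]
        null_l[, i] <- e_loc[i]
        next
      }
      nulls <- generate_null_ensemble(graphs[[i]], n_null = n_null,
                                      n_swaps_per_edge = n_swaps_per_edge,
                                      seed = subseed(seed, i))
      null_g[, i] <- vapply(nulls, global_efficiency, numeric(1))
      null_l[, i] <- vapply(nulls, local_efficiency, numeric(1))
    }
    out$e_glob_norm <- normalized_efficiency(e_glob, null_g)
    out$e_loc_norm <- normalized_efficiency(e_loc, null_l)
    out$small_world <- small_world_flag(out$e_loc_norm, out$e_glob_norm)
  }
  structure(out, class = "efficiency_curve")
}

#' @export
print.efficiency_curve <- function(x, ...) {
  cat(sprintf("<efficiency_curve> %d sparsities in [%.2f, %.2f]; AUC E_glob %.4f, E_loc %.4f\n",
              length(x$sparsities), min(x$sparsities), max(x$sparsities),
              x$auc_glob, x$auc_loc))
  if (!is.null(x$small_world)) {
    cat(sprintf("  normalized: E_glob %.3f-%.3f, E_loc %.3f-%.3f; small-world: %s\n",
                min(x$e_glob_norm, na.rm = TRUE), max(x$e_glob_norm, na.rm = TRUE),
                min(x$e_loc_norm, na.rm = TRUE), max(x$e_loc_norm, na.rm = TRUE),
                x$small_world))
  }
  invisible(x)
}
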