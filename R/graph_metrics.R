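# Whole-brain and hemispheric network measures on FA-weighted connectomes.
# Conventions follow the weighted-network defaults of the Brain Connectivity
# Toolbox: edge length = 1/weight for shortest paths, Onnela max-normalized
# clustering, Louvain modularity at resolution 1.

as_weight_matrix <- function(x) {
  w <- if (inherits(x, "connectome")) x$fa else as.matrix(x)
  if (!isSymmetric(unname(w), tol = 1e-8)) stop_data("weight matrix must be symmetric")
  if (any(w < 0)) stop_data("negative edge weights are not supported")
  diag(w) <- 0
  w
}

#' Connection density
#'
#' Fraction of realized undirected edges: nonzero off-diagonal pairs over
#' N(N-1)/2.
#'
#' @param connectome a `connectome` or symmetric weight matrix.
#' @return fraction in [0, 1].
#' @export
connectome_density <- function(connectome) {
  w <- as_weight_matrix(connectome)
  n <- nrow(w)
  if (n < 2) stop_data("density needs at least 2 nodes")
  sum(w[upper.tri(w)] > 0) / (n * (n - 1) / 2)
}

#' Mean nodal strength
#'
#' Mean over nodes of s_i = sum_j w_ij.
#'
#' @inheritParams connectome_density
#' @return mean strength in weight units.
#' @export
mean_strength <- function(connectome) {
  w <- as_weight_matrix(connectome)
  mean(rowSums(w))
}

#' Weighted global efficiency
#'
#' E_glob = (1/(N(N-1))) * sum_{i != j} 1/d_ij with d_ij the shortest-path
#' length under edge lengths 1/w_ij; unreachable pairs contribute 0 (keeps
#' efficiency monotone under edge addition).
#'
#' @inheritParams connectome_density
#' @return fraction (<= 1 when all weights <= 1).
#' @export
global_efficiency <- function(connectome) {
  w <- as_weight_matrix(connectome)
  n <- nrow(w)
  if (n < 2) return(0)
  if (all(w == 0)) return(0)
  g <- igraph::graph_from_adjacency_matrix(w, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  d <- igraph::distances(g, weights = 1 / igraph::E(g)$weight)
  inv <- 1 / d
  diag(inv) <- 0
  inv[is.infinite(d)] <- 0
  sum(inv) / (n * (n - 1))
}

#' Mean weighted clustering coefficient (Onnela)
#'
#' Weights are first scaled by the maximum off-diagonal weight; per node,
#' C_i = (1/(k_i(k_i-1))) * sum over neighbor pairs of the geometric mean of
#' the three scaled triangle weights. Nodes with degree < 2 contribute 0.
#'
#' @inheritParams connectome_density
#' @return mean of C_i over all nodes.
#' @export
mean_clustering <- function(connectome) {
  w <- as_weight_matrix(connectome)
  mx <- max(w)
  if (mx == 0) return(0)
  wh <- (w / mx)^(1 / 3)
  k <- rowSums(w > 0)
  tri <- diag(wh %*% wh %*% wh)          # 2 * sum of cube-root triangle products
  ci <- ifelse(k >= 2, tri / (k * (k - 1)), 0)
  mean(ci)
}

#' Maximized Newman-Girvan modularity
#'
#' Weighted modularity at resolution 1. Graphs up to `exact_max_nodes` are
#' solved exactly (integer-programming optimum via igraph); larger graphs --
#' the realistic connectome case -- use Louvain, keeping the best of
#' `n_repetitions` vertex-permuted seeded restarts (greedy Louvain alone can
#' sit in a local optimum even on toy graphs). Deterministic given `seed`.
#'
#' @inheritParams connectome_density
#' @param n_repetitions number of Louvain restarts (>= 1).
#' @param seed integer seed.
#' @param exact_max_nodes size threshold for exact optimization.
#' @return list with `Q` and integer `partition`.
#' @export
graph_modularity <- function(connectome, n_repetitions = 100L, seed = 1L,
                             exact_max_nodes = 12L) {
  w <- as_weight_matrix(connectome)
  if (all(w == 0)) stop_data("modularity undefined for an empty graph (m = 0)")
  if (n_repetitions < 1) stop_config("n_repetitions must be >= 1")
  n <- nrow(w)
  if (n <= exact_max_nodes) {
    g <- igraph::graph_from_adjacency_matrix(w, mode = "undirected",
                                             weighted = TRUE, diag = FALSE)
    cl <- igraph::cluster_optimal(g, weights = igraph::E(g)$weight)
    return(list(Q = igraph::modularity(g, igraph::membership(cl),
                                       weights = igraph::E(g)$weight),
                partition = as.integer(igraph::membership(cl))))
  }
  best <- NULL
  with_seed(seed, {
    for (r in seq_len(n_repetitions)) {
      # Louvain's greedy passes depend on vertex order; random permutations
      # make the seeded restarts genuinely diverse
      perm <- if (r == 1) seq_len(n) else sample.int(n)
      gp <- igraph::graph_from_adjacency_matrix(w[perm, perm],
                                                mode = "undirected",
                                                weighted = TRUE, diag = FALSE)
      cl <- igraph::cluster_louvain(gp, weights = igraph::E(gp)$weight)
      memb <- integer(n)
      memb[perm] <- as.integer(igraph::membership(cl))
      q <- igraph::modularity(gp, igraph::membership(cl),
                              weights = igraph::E(gp)$weight)
      if (is.null(best) || q > best$Q) best <- list(Q = q, partition = memb)
    }
  })
  best
}

#' Intra-hemispheric efficiency
#'
#' Global efficiency of the left- and right-hemisphere subnetworks
#' (inter-hemispheric edges removed), averaged. Midline nodes are excluded.
#'
#' @inheritParams connectome_density
#' @param node_table node metadata with `node_id` and `hemisphere`.
#' @return arithmetic mean of the two hemispheric efficiencies.
#' @export
intra_hemispheric_efficiency <- function(connectome, node_table) {
  w <- as_weight_matrix(connectome)
  eff <- vapply(c("L", "R"), function(h) {
    idx <- node_table$node_id[node_table$hemisphere == h]
    if (length(idx) < 2)
      stop_data("hemisphere ", h, " has fewer than 2 nodes")
    global_efficiency(w[idx, idx, drop = FALSE])
  }, numeric(1))
  mean(eff)
}

#' Commissural-ratio / intra-hemispheric-efficiency conservation index
#'
#' @param cr commissural ratio in [0, 1].
#' @param e_intra intra-hemispheric efficiency (> 0 for a defined ratio).
#' @return `cr / e_intra`; NA with a warning when `e_intra` is 0.
#' @export
conservation_ratio <- function(cr, e_intra) {
  if (is.na(e_intra) || e_intra == 0) {
    warning("intra-hemispheric efficiency is 0; conservation ratio undefined")
    return(NA_real_)
  }
  cr / e_intra
}

#' All graph metrics for one subject's connectome
#'
#' @param connectome a `connectome` (FA matrix used for all weighted
#'   metrics; density shares the same sparsity pattern as the count matrix).
#' @param disconnection optional `disconnection_result` supplying the
#'   commissural ratio and disconnection percentages.
#' @param n_repetitions,seed passed to [graph_modularity()].
#' @return one-row data.frame of metric values.
#' @export
graph_metric_set <- function(connectome, disconnection = NULL,
                             n_repetitions = 100L, seed = 1L) {
  stopifnot(inherits(connectome, "connectome"))
  nodes <- connectome$nodes
  e_intra <- intra_hemispheric_efficiency(connectome, nodes)
  cr <- if (!is.null(disconnection)) disconnection$commissural_ratio else NA_real_
  data.frame(
    density = connectome_density(connectome),
    efficiency = global_efficiency(connectome),
    mean_strength = mean_strength(connectome),
    clustering = mean_clustering(connectome),
    modularity = graph_modularity(connectome, n_repetitions, seed)$Q,
    commissural_ratio = cr,
    intra_hemi_efficiency = e_intra,
    conservation_ratio = if (is.na(cr)) NA_real_ else conservation_ratio(cr, e_intra),
    inter_disc_pct = if (!is.null(disconnection)) disconnection$inter_disc_pct else NA_real_,
    intra_disc_pct = if (!is.null(disconnection)) disconnection$intra_disc_pct else NA_real_
  )
}
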