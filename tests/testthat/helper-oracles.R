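# Independent brute-force oracles and fixture builders, kept deliberately
# naive so they share no code path with the package implementation.

rand_weight_matrix <- function(n, p = 0.5, seed = 1) {
  set.seed(seed)
  w <- matrix(0, n, n)
  ut <- upper.tri(w)
  w[ut] <- rbinom(sum(ut), 1, p) * runif(sum(ut), 0.1, 1)
  w + t(w)
}

brute_density <- function(w) {
  n <- nrow(w)
  e <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) if (w[i, j] > 0) e <- e + 1
  e / (n * (n - 1) / 2)
}

brute_strength <- function(w) {
  s <- numeric(nrow(w))
  for (i in seq_len(nrow(w))) for (j in seq_len(ncol(w))) s[i] <- s[i] + w[i, j]
  mean(s)
}

brute_efficiency <- function(w) {
  n <- nrow(w)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  for (i in 1:n) for (j in 1:n) if (i != j && w[i, j] > 0) d[i, j] <- 1 / w[i, j]
  for (k in 1:n) for (i in 1:n) for (j in 1:n)
    if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  tot <- 0
  for (i in 1:n) for (j in 1:n)
    if (i != j && is.finite(d[i, j])) tot <- tot + 1 / d[i, j]
  tot / (n * (n - 1))
}

brute_clustering <- function(w) {
  n <- nrow(w)
  wh <- w / max(w)
  ci <- numeric(n)
  for (i in 1:n) {
    k <- sum(w[i, ] > 0)
    if (k < 2) next
    acc <- 0
    for (j in 1:n) for (h in 1:n)
      if (j != i && h != i && j != h)
        acc <- acc + (wh[i, j] * wh[i, h] * wh[j, h])^(1 / 3)
    ci[i] <- acc / (k * (k - 1))
  }
  mean(ci)
}

all_partitions <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in all_partitions(n - 1)) {
    for (cc in 1:(max(p) + 1)) out[[length(out) + 1]] <- c(p, cc)
  }
  out
}

brute_modularity <- function(w) {
  m <- sum(w) / 2
  s <- rowSums(w)
  best <- -Inf
  for (p in all_partitions(nrow(w))) {
    same <- outer(p, p, "==")
    q <- sum((w - outer(s, s) / (2 * m)) * same) / (2 * m)
    if (q > best) best <- q
  }
  best
}

# parcellation with one labeled voxel per node at given 1-based voxel indices
make_point_parcellation <- function(voxels, hemis, supra = NULL,
                                    grid = c(20L, 20L, 20L), vs = 1) {
  lab <- array(0L, dim = grid)
  for (i in seq_len(nrow(voxels))) lab[voxels[i, 1], voxels[i, 2], voxels[i, 3]] <- i
  n <- nrow(voxels)
  structure(list(
    label_grid = lab, voxel_size = vs,
    nodes = data.frame(node_id = seq_len(n), hemisphere = hemis,
                       supratentorial = supra %||% rep(TRUE, n),
                       cx = (voxels[, 1] - 0.5) * vs,
                       cy = (voxels[, 2] - 0.5) * vs,
                       cz = (voxels[, 3] - 0.5) * vs,
                       stringsAsFactors = FALSE)),
    class = "parcellation")
}

# straight-line tractogram from explicit endpoint coordinates
make_tractogram <- function(starts, ends, fa = NULL, k = 5) {
  n <- nrow(starts)
  sl <- lapply(seq_len(n), function(i) {
    t <- seq(0, 1, length.out = k)
    cbind(starts[i, 1] + t * (ends[i, 1] - starts[i, 1]),
          starts[i, 2] + t * (ends[i, 2] - starts[i, 2]),
          starts[i, 3] + t * (ends[i, 3] - starts[i, 3]))
  })
  structure(list(streamlines = sl, fa = fa %||% rep(0.5, n)),
            class = "tractogram")
}

# independent tally of disconnection classes and counts
brute_disconnection <- function(assignments, hits, nodes) {
  hem <- nodes$hemisphere[match(assignments$node_a, nodes$node_id)]
  hem_b <- nodes$hemisphere[match(assignments$node_b, nodes$node_id)]
  sup <- nodes$supratentorial[match(assignments$node_a, nodes$node_id)]
  sup_b <- nodes$supratentorial[match(assignments$node_b, nodes$node_id)]
  tot <- c(intra = 0, inter = 0, other = 0)
  les <- c(intra = 0, inter = 0, other = 0)
  for (i in seq_len(nrow(assignments))) {
    if (assignments$excluded[i]) next
    cls <- if (hem[i] %in% c("L", "R") && hem_b[i] %in% c("L", "R") &&
               hem[i] != hem_b[i]) "inter"
    else if (hem[i] %in% c("L", "R") && hem[i] == hem_b[i] &&
             sup[i] && sup_b[i]) "intra"
    else "other"
    tot[cls] <- tot[cls] + 1
    if (hits[i]) les[cls] <- les[cls] + 1
  }
  list(tot = tot, les = les)
}

brute_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    cand <- Inf
    for (j in i:m) cand <- min(cand, m * p[o[j]] / j)
    q[o[i]] <- min(cand, 1)
  }
  q
}

brute_auc <- function(scores, labels) {
  pos <- scores[as.logical(labels)]
  neg <- scores[!as.logical(labels)]
  tot <- 0
  for (a in pos) for (b in neg)
    tot <- tot + if (a > b) 1 else if (a == b) 0.5 else 0
  tot / (length(pos) * length(neg))
}

small_config <- function(seed = 11, ...) {
  sim_config(n_hc = 140, n_aoms = 120, n_loms = 60, seed = seed, ...)
}
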