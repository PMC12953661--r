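unit_graph <- function(n) { w <- matrix(1, n, n); diag(w) <- 0; w }

test_that("density, strength, efficiency, clustering on worked examples", {
  expect_equal(connectome_density(unit_graph(4)), 1)
  w <- matrix(0, 4, 4)
  w[1, 2] <- w[2, 1] <- 1; w[2, 3] <- w[3, 2] <- 0.5; w[3, 4] <- w[4, 3] <- 2
  expect_equal(connectome_density(w), 0.5)  # 3 of 6 pairs
  expect_equal(connectome_density(matrix(0, 5, 5)), 0)
  expect_error(connectome_density(matrix(0, 1, 1)), "2 nodes")

  expect_equal(mean_strength(unit_graph(3)), 2)
  expect_equal(mean_strength(matrix(0, 3, 3)), 0)

  expect_equal(global_efficiency(unit_graph(4)), 1)
  path3 <- matrix(0, 3, 3)
  path3[1, 2] <- path3[2, 1] <- path3[2, 3] <- path3[3, 2] <- 1
  expect_equal(global_efficiency(path3), 5 / 6)
  expect_equal(global_efficiency(matrix(0, 3, 3)), 0)
  expect_error(global_efficiency(-unit_graph(3)), "negative")

  expect_equal(mean_clustering(unit_graph(3)), 1)
  expect_equal(mean_clustering(path3), 0)
  tri <- matrix(0, 3, 3)
  tri[1, 2] <- tri[2, 1] <- 1; tri[1, 3] <- tri[3, 1] <- 1
  tri[2, 3] <- tri[3, 2] <- 0.125
  expect_equal(mean_clustering(tri), brute_clustering(tri))
})

test_that("graph metrics match brute-force oracles on random graphs <= 8 nodes", {
  for (n in 4:8) for (s in 1:3) {
    w <- rand_weight_matrix(n, 0.6, seed = n * 10 + s)
    if (all(w == 0)) next
    expect_equal(connectome_density(w), brute_density(w))
    expect_equal(mean_strength(w), brute_strength(w))
    expect_equal(global_efficiency(w), brute_efficiency(w))
    expect_equal(mean_clustering(w), brute_clustering(w))
  }
})

test_that("Louvain modularity equals exhaustive partition optimum", {
  m <- matrix(0, 8, 8)
  m[1:4, 1:4] <- 1; m[5:8, 5:8] <- 1; diag(m) <- 0
  m[4, 5] <- m[5, 4] <- 1
  r <- graph_modularity(m, 50, seed = 3)
  expect_equal(r$Q, brute_modularity(m))
  expect_equal(length(unique(r$partition)), 2)
  # complete graph: one community, Q = 0
  r2 <- graph_modularity(unit_graph(5), 20, seed = 3)
  expect_equal(r2$Q, 0)
  expect_equal(length(unique(r2$partition)), 1)
  for (s in 1:3) {
    w <- rand_weight_matrix(6 + s %% 3, 0.5, seed = 100 + s)
    if (all(w == 0)) next
    expect_equal(graph_modularity(w, 100, seed = 1)$Q, brute_modularity(w),
                 tolerance = 1e-12)
  }
  r3a <- graph_modularity(m, 20, seed = 9)
  r3b <- graph_modularity(m, 20, seed = 9)
  expect_identical(r3a, r3b)
  expect_error(graph_modularity(matrix(0, 4, 4)), "m = 0")
})

test_that("intra-hemispheric efficiency and conservation ratio", {
  nodes <- data.frame(node_id = 1:6, hemisphere = rep(c("L", "R"), each = 3),
                      supratentorial = TRUE)
  # identical complete hemispheres, no inter edges -> efficiency 1
  w <- matrix(0, 6, 6)
  w[1:3, 1:3] <- 1; w[4:6, 4:6] <- 1; diag(w) <- 0
  expect_equal(intra_hemispheric_efficiency(w, nodes), 1)
  # symmetric graph: equals either hemisphere's own efficiency
  h <- rand_weight_matrix(3, 1, seed = 2)
  w2 <- matrix(0, 6, 6); w2[1:3, 1:3] <- h; w2[4:6, 4:6] <- h
  expect_equal(intra_hemispheric_efficiency(w2, nodes), global_efficiency(h))
  # random 12-node graph vs brute-force per-hemisphere computation
  nodes12 <- data.frame(node_id = 1:12,
                        hemisphere = rep(c("L", "R"), each = 6),
                        supratentorial = TRUE)
  w3 <- rand_weight_matrix(12, 0.5, seed = 5)
  manual <- mean(c(brute_efficiency(w3[1:6, 1:6]),
                   brute_efficiency(w3[7:12, 7:12])))
  expect_equal(intra_hemispheric_efficiency(w3, nodes12), manual)
  expect_error(intra_hemispheric_efficiency(w3, data.frame(
    node_id = 1:12, hemisphere = c("L", rep("R", 11)),
    supratentorial = TRUE)), "fewer than 2")

  expect_equal(conservation_ratio(0.2, 0.5), 0.4)
  expect_equal(conservation_ratio(0, 0.5), 0)
  expect_warning(cr0 <- conservation_ratio(0.2, 0), "undefined")
  expect_true(is.na(cr0))
})

test_that("metrics are permutation invariant and scale as expected", {
  w <- rand_weight_matrix(7, 0.6, seed = 21)
  perm <- sample(7)
  wp <- w[perm, perm]
  expect_equal(connectome_density(wp), connectome_density(w))
  expect_equal(mean_strength(wp), mean_strength(w))
  expect_equal(global_efficiency(wp), global_efficiency(w))
  expect_equal(mean_clustering(wp), mean_clustering(w))
  expect_equal(graph_modularity(wp, 50, 1)$Q, graph_modularity(w, 50, 1)$Q,
               tolerance = 1e-12)
  cc <- 3.7
  expect_equal(connectome_density(cc * w), connectome_density(w))
  expect_equal(mean_clustering(cc * w), mean_clustering(w))
  expect_equal(graph_modularity(cc * w, 50, 1)$Q,
               graph_modularity(w, 50, 1)$Q, tolerance = 1e-12)
  expect_equal(mean_strength(cc * w), cc * mean_strength(w))
  expect_equal(global_efficiency(cc * w), cc * global_efficiency(w))
})

test_that("graph_metric_set composes the per-subject metric row", {
  p <- simulate_parcellation(12, c(24, 24, 24), 1)
  tr <- simulate_tractogram(p, 400, 0.25, seed = 3)
  asg <- assign_endpoints(tr, p)
  cn <- build_connectome(asg, tr, p$nodes)
  les <- simulate_lesions(c(24, 24, 24), 1, 1, seed = 4)
  dx <- disconnection_indices(asg, intersect_lesions(tr, les), p$nodes)
  gm <- graph_metric_set(cn, dx, n_repetitions = 10, seed = 1)
  expect_equal(gm$conservation_ratio,
               gm$commissural_ratio / gm$intra_hemi_efficiency)
  expect_equal(gm$commissural_ratio, dx$commissural_ratio)
  expect_true(gm$density > 0 && gm$density <= 1)
})
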