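# Two-node-per-hemisphere parcellation on a 20 mm cube, single-voxel regions
# at known positions; streamlines are constructed, never simulated, so every
# expected count is known by construction.
four_node_parc <- function(supra = c(TRUE, TRUE, TRUE, TRUE)) {
  make_point_parcellation(
    voxels = rbind(c(3, 10, 10), c(5, 10, 16), c(16, 10, 10), c(16, 10, 16)),
    hemis = c("L", "L", "R", "R"), supra = supra)
}

node_center <- function(p, id) {
  unlist(p$nodes[p$nodes$node_id == id, c("cx", "cy", "cz")], use.names = FALSE)
}

test_that("endpoints map to containing nodes with radius fallback", {
  p <- four_node_parc()
  a <- node_center(p, 1); b <- node_center(p, 3)
  tr <- make_tractogram(rbind(a), rbind(b))
  asg <- assign_endpoints(tr, p)
  expect_equal(asg$node_a, 1L)
  expect_equal(asg$node_b, 3L)
  expect_false(asg$excluded)
  # endpoint in background, 1.2 mm from the node-1 voxel center
  off <- a + c(0, 1.7, 0)  # voxel (3,11,10): background, 1.2mm off that center? no:
  # distance from a + (0,1.7,0) to node-1 voxel center is 1.7mm; use 1.2
  off <- a + c(0, 1.2, 0)
  tr2 <- make_tractogram(rbind(off), rbind(b))
  expect_equal(assign_endpoints(tr2, p, search_radius_mm = 2)$node_a, 1L)
  expect_true(assign_endpoints(tr2, p, search_radius_mm = 1)$excluded)
  # both endpoints in the same node: excluded as a self loop
  tr3 <- make_tractogram(rbind(a), rbind(a + c(0.2, 0, 0)))
  asg3 <- assign_endpoints(tr3, p)
  expect_true(asg3$excluded)
  expect_equal(asg3$reason, "self_loop")
})

test_that("connectome matrices match brute-force tallies", {
  p <- four_node_parc()
  # 10 streamlines all linking (1,2), FA 0.5 each
  a <- node_center(p, 1); b <- node_center(p, 2)
  tr <- make_tractogram(matrix(rep(a, 10), ncol = 3, byrow = TRUE),
                        matrix(rep(b, 10), ncol = 3, byrow = TRUE),
                        fa = rep(0.5, 10))
  cn <- build_connectome(assign_endpoints(tr, p), tr, p$nodes)
  expect_equal(cn$count[1, 2], 10)
  expect_equal(cn$fa[1, 2], 0.5)
  expect_true(isSymmetric(cn$count))
  expect_true(all(diag(cn$count) == 0))
  expect_true(all(cn$fa[cn$count == 0] == 0))
  # no assigned streamlines -> zero matrices
  bg <- c(10, 1, 1)
  tr0 <- make_tractogram(rbind(bg), rbind(bg + 0.1))
  cn0 <- build_connectome(assign_endpoints(tr0, p, 0), tr0, p$nodes)
  expect_true(all(cn0$count == 0) && all(cn0$fa == 0))
  # mixed random pairs vs independent tally
  set.seed(42)
  ids <- cbind(sample(1:4, 120, TRUE), sample(1:4, 120, TRUE))
  trm <- make_tractogram(t(apply(ids, 1, function(r) node_center(p, r[1]))),
                         t(apply(ids, 1, function(r) node_center(p, r[2]))),
                         fa = runif(120, 0.2, 0.9))
  asg <- assign_endpoints(trm, p)
  cn <- build_connectome(asg, trm, p$nodes)
  for (i in 1:4) for (j in 1:4) {
    if (i == j) next
    manual <- sum((ids[, 1] == i & ids[, 2] == j) |
                  (ids[, 1] == j & ids[, 2] == i))
    expect_equal(cn$count[i, j], manual)
    if (manual > 0) {
      keep <- (ids[, 1] == i & ids[, 2] == j) | (ids[, 1] == j & ids[, 2] == i)
      expect_equal(cn$fa[i, j], mean(trm$fa[keep]))
    }
  }
})

test_that("lesion intersection flags exactly the constructed streamlines", {
  p <- four_node_parc()
  mask <- array(FALSE, dim = c(20, 20, 20))
  mask[10, 10, 10] <- TRUE  # lesion voxel spanning [9,10)x[9,10)x[9,10) mm
  les <- structure(list(mask = mask, voxel_size = 1, lv_ml = 1e-3),
                   class = "lesion_mask")
  a <- node_center(p, 1); b <- node_center(p, 3)   # y=z=9.5: passes through
  up <- c(0, 3, 3)
  starts <- rbind(a, a + up, a, a + up, a, a, a + up, a, a, a + up)
  ends   <- rbind(b, b + up, b, b + up, b, b, b + up, b, b, b + up)
  tr <- make_tractogram(starts, ends, k = 40)
  hits <- intersect_lesions(tr, les)
  through <- c(TRUE, FALSE, TRUE, FALSE, TRUE, TRUE, FALSE, TRUE, TRUE, FALSE)
  expect_identical(hits, through)
  empty <- structure(list(mask = array(FALSE, dim = c(20, 20, 20)),
                          voxel_size = 1, lv_ml = 0), class = "lesion_mask")
  expect_identical(intersect_lesions(tr, empty), rep(FALSE, 10))
})

test_that("disconnection indices: direct ratios, CR, and class conservation", {
  nodes <- data.frame(node_id = 1:4, hemisphere = c("L", "L", "R", "R"),
                      supratentorial = TRUE)
  # 10 intra (1-2), 3 lesioned; 20 inter (1-3) of 100 total
  asg <- data.frame(node_a = c(rep(1, 90), rep(1, 10)),
                    node_b = c(rep(3, 20), rep(2, 70), rep(2, 10)),
                    excluded = FALSE, reason = NA_character_)
  # classes: first 20 inter, remaining 80 intra
  hits <- rep(FALSE, 100)
  hits[21:23] <- TRUE
  dx <- disconnection_indices(asg, hits, nodes)
  expect_equal(dx$commissural_ratio, 0.20)
  expect_equal(dx$intra_disc_pct, 100 * 3 / 80)
  expect_equal(sum(dx$class_totals), dx$s_total)
  expect_true(all(dx$class_lesioned <= dx$class_totals))
  # 3 of 10 intra-class streamlines lesioned -> 30%
  asg2 <- data.frame(node_a = rep(1, 10), node_b = rep(2, 10),
                     excluded = FALSE, reason = NA_character_)
  dx2 <- disconnection_indices(asg2, c(rep(TRUE, 3), rep(FALSE, 7)), nodes)
  expect_equal(dx2$intra_disc_pct, 30)
  expect_true(is.na(dx2$inter_disc_pct))  # empty class is missing, not 0
  # total-denominator switch
  dx2t <- disconnection_indices(asg2, c(rep(TRUE, 3), rep(FALSE, 7)), nodes,
                                denominator = "total")
  expect_equal(dx2t$intra_disc_pct, 30)
  expect_equal(dx2$disconnectivity[1, 2], 0.3)
})

test_that("disconnection matches brute-force classification on 200 streamlines", {
  p <- four_node_parc(supra = c(TRUE, FALSE, TRUE, TRUE))
  set.seed(7)
  ids <- cbind(sample(1:4, 200, TRUE), sample(1:4, 200, TRUE))
  tr <- make_tractogram(t(apply(ids, 1, function(r) node_center(p, r[1]))),
                        t(apply(ids, 1, function(r) node_center(p, r[2]))),
                        k = 30)
  asg <- assign_endpoints(tr, p)
  les <- simulate_lesions(c(20, 20, 20), 1, 1.5, seed = 3)
  hits <- intersect_lesions(tr, les)
  dx <- disconnection_indices(asg, hits, p$nodes)
  oracle <- brute_disconnection(asg, hits, p$nodes)
  expect_equal(unname(dx$class_totals), unname(oracle$tot))
  expect_equal(unname(dx$class_lesioned), unname(oracle$les))
})

test_that("growing the lesion mask never decreases disconnection indices", {
  p <- four_node_parc()
  set.seed(9)
  ids <- cbind(sample(1:4, 150, TRUE), sample(1:4, 150, TRUE))
  tr <- make_tractogram(t(apply(ids, 1, function(r) node_center(p, r[1]))),
                        t(apply(ids, 1, function(r) node_center(p, r[2]))),
                        k = 30)
  asg <- assign_endpoints(tr, p)
  les1 <- simulate_lesions(c(20, 20, 20), 1, 0.8, seed = 5)
  les2 <- les1
  les2$mask <- les1$mask | simulate_lesions(c(20, 20, 20), 1, 1.5, seed = 6)$mask
  d1 <- disconnection_indices(asg, intersect_lesions(tr, les1), p$nodes)
  d2 <- disconnection_indices(asg, intersect_lesions(tr, les2), p$nodes)
  for (f in c("intra_disc_pct", "inter_disc_pct")) {
    if (!is.na(d1[[f]])) expect_gte(d2[[f]], d1[[f]])
  }
  expect_true(all(d2$class_lesioned >= d1$class_lesioned))
})
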