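test_that("cohort generator honors group constraints and determinism", {
  cfg <- small_config(seed = 5)
  co <- simulate_cohort(cfg)
  expect_equal(nrow(co), 320)
  loms <- co[co$group == "LOMS", ]
  aoms <- co[co$group == "AOMS", ]
  expect_true(all(loms$age_at_onset >= 45))
  expect_true(all(aoms$age_at_onset >= 18 & aoms$age_at_onset <= 45))
  expect_true(all(co$disease_duration[co$group != "HC"] <= 6))
  pat <- co$group != "HC"
  expect_equal(co$age_at_mri[pat] - co$age_at_onset[pat],
               co$disease_duration[pat])
  expect_true(all(co$sdmt_impaired == (co$sdmt_z < -1.5)))
  # byte-identical regeneration from the same config
  expect_identical(co, simulate_cohort(cfg))
  expect_false(identical(co, simulate_cohort(small_config(seed = 6))))
})

test_that("impairment rate matches the configured logistic intercept", {
  cfg <- sim_config(n_hc = 10, n_aoms = 10000, n_loms = 10,
                    impairment_model = list(intercept = qlogis(0.39),
                                            coef = numeric(0)),
                    seed = 3)
  co <- simulate_cohort(cfg)
  frac <- mean(co$sdmt_impaired[co$group == "AOMS"])
  se <- sqrt(0.39 * 0.61 / 10000)
  expect_lt(abs(frac - 0.39), 2 * se)
})

test_that("null effect profile leaves groups exchangeable in expectation", {
  prof <- setNames(lapply(zscored_metrics(), function(m) c(aoms = 0, loms = 0)),
                   zscored_metrics())
  cfg <- sim_config(n_hc = 1500, n_aoms = 1500, n_loms = 1500,
                    metric_effect_profile = prof, seed = 8)
  co <- simulate_cohort(cfg)
  mt <- simulate_metric_table(co, cfg)
  zr <- zscore_table(co, mt, metrics = c("density", "modularity"))
  # patient mean z combines 1/sqrt(n) sampling noise with reference-model
  # estimation error; 0.15 is the recovery tolerance used throughout
  for (m in c("density", "modularity")) {
    for (g in c("AOMS", "LOMS"))
      expect_lt(abs(mean(zr$z[[m]][zr$z$group == g])), 0.15)
  }
})

test_that("unknown metric in the effect profile is a configuration error", {
  expect_error(sim_config(metric_effect_profile = list(bogus = c(aoms = 1, loms = 1))),
               "unknown metric")
  expect_error(sim_config(n_aoms = -5), "non-negative")
  expect_error(sim_config(center_sigma_multipliers = rep(0, 7)), "> 0")
})

test_that("center SD multipliers control residual heteroscedasticity", {
  cfg <- sim_config(n_centers = 2, n_hc = 4000, n_aoms = 0, n_loms = 0,
                    center_sigma_multipliers = c(1, 2), seed = 13)
  co <- simulate_cohort(cfg)
  mt <- simulate_metric_table(co, cfg)
  d <- merge(co, mt, by = "subject_id")
  res_sd <- vapply(1:2, function(cc) {
    dc <- d[d$center_id == cc, ]
    sd(resid(lm(density ~ sex * I(age_at_mri), data = dc)))
  }, numeric(1))
  expect_equal(res_sd[2] / res_sd[1], 2, tolerance = 0.1)
})

test_that("injected group shift is recovered through the normative model", {
  # LOMS density shift -1.667 (the reported group difference magnitude)
  cfg <- sim_config(n_aoms = 500, n_loms = 500, seed = 2)
  co <- simulate_cohort(cfg)
  mt <- simulate_metric_table(co, cfg)
  zr <- zscore_table(co, mt, metrics = "density")
  rec <- mean(zr$z$density[zr$z$group == "LOMS"])
  expect_lt(abs(rec - (-1.667)), 0.15)
})

test_that("parcellation lays out hemispheres, partitions voxels, sizes node table", {
  p <- simulate_parcellation(4, c(20, 20, 20), 1)
  expect_equal(sum(p$nodes$hemisphere == "L"), 2)
  expect_equal(sum(p$nodes$hemisphere == "R"), 2)
  # disjoint regions: every labeled voxel has exactly one label by storage;
  # all node ids present and consistent with the node table
  expect_setequal(setdiff(unique(as.vector(p$label_grid)), 0L), p$nodes$node_id)
  mid <- 10  # midsagittal plane at x = 10 mm
  for (i in p$nodes$node_id) {
    vox <- which(p$label_grid == i, arr.ind = TRUE)
    xs <- (vox[, 1] - 0.5) * p$voxel_size
    if (p$nodes$hemisphere[i] == "L") expect_true(all(xs < mid))
    if (p$nodes$hemisphere[i] == "R") expect_true(all(xs > mid))
  }
  p253 <- simulate_parcellation(253, c(48, 48, 48), 1)
  expect_equal(nrow(p253$nodes), 253)
  expect_equal(sum(p253$nodes$hemisphere == "MID"), 1)
  expect_error(simulate_parcellation(5000, c(10, 10, 10)), "capacity")
})

test_that("tractogram respects commissural fraction and endpoint contracts", {
  p <- simulate_parcellation(8, c(24, 24, 24), 1)
  tr0 <- simulate_tractogram(p, 200, commissural_fraction = 0, seed = 4)
  asg0 <- assign_endpoints(tr0, p, search_radius_mm = 0)
  hem <- setNames(p$nodes$hemisphere, p$nodes$node_id)
  crossing <- hem[as.character(asg0$node_a)] != hem[as.character(asg0$node_b)]
  expect_true(all(!crossing[!asg0$excluded]))
  tr <- simulate_tractogram(p, 1000, commissural_fraction = 0.2, seed = 4)
  asg <- assign_endpoints(tr, p, search_radius_mm = 0)
  obs <- mean(hem[as.character(asg$node_a)] != hem[as.character(asg$node_b)],
              na.rm = TRUE)
  expect_lt(abs(obs - 0.2), 3 * sqrt(0.2 * 0.8 / 1000))
  expect_true(all(tr$fa > 0 & tr$fa <= 1))
  expect_true(all(vapply(tr$streamlines, nrow, integer(1)) >= 2))
  tr2 <- simulate_tractogram(p, 1000, commissural_fraction = 0.2, seed = 4)
  expect_identical(tr$streamlines, tr2$streamlines)
})

test_that("lesion masks meet volume targets and unit arithmetic", {
  les0 <- simulate_lesions(c(20, 20, 20), 1, 0, seed = 1)
  expect_equal(sum(les0$mask), 0)
  expect_equal(les0$lv_ml, 0)
  les <- simulate_lesions(c(30, 30, 30), 1, 2, n_foci = 3, seed = 2)
  # lv_ml is voxel count times voxel volume, in mL
  expect_equal(les$lv_ml, sum(les$mask) * 1 / 1000)
  expect_lt(abs(les$lv_ml - 2), 2 / 3 + 1e-9)  # within one focus-volume
  expect_identical(les$mask, simulate_lesions(c(30, 30, 30), 1, 2,
                                              n_foci = 3, seed = 2)$mask)
  expect_error(simulate_lesions(c(5, 5, 5), 1, 10), "exceeds grid")
})
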