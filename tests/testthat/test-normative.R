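make_hc <- function(n_per_center, centers = 3, beta = c(10, 1, -0.05, 0.02),
                    sigma = c(1, 2, 0.5), seed = 1) {
  set.seed(seed)
  n <- n_per_center * centers
  center <- rep(seq_len(centers), each = n_per_center)
  sex <- sample(c("F", "M"), n, TRUE)
  age <- runif(n, 18, 77)
  male <- as.numeric(sex == "M")
  agec <- age - mean(age)
  mu <- beta[1] + beta[2] * male + beta[3] * agec + beta[4] * male * agec +
    0.5 * (center - 2)
  y <- mu + rnorm(n, 0, sigma[center])
  data.frame(sex = sex, age = age, center = center, y = y, group = "HC",
             subject_id = sprintf("H%03d", 1:n))
}

test_that("FGLS recovers mean coefficients and center SDs", {
  hc <- make_hc(200, seed = 3)
  m <- fit_reference(hc, "y")
  expect_true(m$converged)
  # beta recovery within 3 analytic SEs of the weighted fit
  X <- cbind(1, as.numeric(hc$sex == "M"), hc$age - mean(hc$age),
             as.numeric(hc$sex == "M") * (hc$age - mean(hc$age)),
             hc$center == 2, hc$center == 3)
  w <- 1 / m$sigma[as.character(hc$center)]^2
  se <- sqrt(diag(solve(t(X) %*% (X * w))))
  truth <- c(9.5, 1, -0.05, 0.02, 0.5, 1.0)  # intercept is center 1: 10 - 0.5
  expect_true(all(abs(m$coefficients - truth) < 3 * se))
  expect_true(all(abs(m$sigma / c(1, 2, 0.5) - 1) < 0.1))
})

test_that("homoscedastic limit reduces to OLS; single center collapses design", {
  hc <- make_hc(150, sigma = c(1, 1, 1), seed = 5)
  m <- fit_reference(hc, "y", heteroscedastic = FALSE)
  ols <- lm(y ~ male * agec + factor(center),
            data = transform(hc, male = as.numeric(sex == "M"),
                             agec = age - mean(age)))
  expect_equal(unname(m$coefficients[c("(Intercept)", "male", "age_c",
                                       "male_age")]),
               unname(coef(ols)[c("(Intercept)", "male", "agec",
                                  "male:agec")]), tolerance = 1e-6)
  hc1 <- make_hc(200, centers = 1, sigma = 1, seed = 6)
  m1 <- fit_reference(hc1, "y")
  ols1 <- lm(y ~ male * agec,
             data = transform(hc1, male = as.numeric(sex == "M"),
                              agec = age - mean(age)))
  expect_equal(unname(m1$coefficients), unname(coef(ols1)), tolerance = 1e-8)
})

test_that("zscore arithmetic, calibration, and error paths", {
  hc <- make_hc(170, seed = 7)
  m <- fit_reference(hc, "y")
  # y = yhat -> 0 ; y = yhat + sigma_c -> 1
  yhat <- hc$y - m$sigma[as.character(hc$center)] *
    zscore(hc$y, hc$sex, hc$age, hc$center, m)
  expect_equal(zscore(yhat[1:5], hc$sex[1:5], hc$age[1:5], hc$center[1:5], m),
               rep(0, 5))
  expect_equal(zscore(yhat[1:5] + m$sigma[as.character(hc$center[1:5])],
                      hc$sex[1:5], hc$age[1:5], hc$center[1:5], m),
               rep(1, 5))
  z <- zscore(hc$y, hc$sex, hc$age, hc$center, m)
  # per-center mean exactly 0 by least-squares orthogonality; SD near 1
  expect_true(all(abs(tapply(z, hc$center, mean)) < 1e-10))
  expect_true(sd(z) > 0.9 && sd(z) < 1.1)
  expect_error(zscore(1, "F", 40, 99, m), "not in reference model")
  expect_warning(zscore(1, "F", 90, 1, m), "age range")
  hc_small <- hc[c(1:50, 201), ]  # center 2 has a single row
  expect_error(fit_reference(hc_small, "y"), "fewer than 2")
})

test_that("z-scores are invariant under affine rescaling of the metric", {
  hc <- make_hc(120, seed = 9)
  m <- fit_reference(hc, "y")
  z <- zscore(hc$y, hc$sex, hc$age, hc$center, m)
  hc2 <- hc
  hc2$y <- 3.2 * hc$y - 40
  m2 <- fit_reference(hc2, "y")
  z2 <- zscore(hc2$y, hc2$sex, hc2$age, hc2$center, m2)
  expect_equal(z2, z, tolerance = 1e-6)
})

test_that("zscore_table composes per-metric scoring and isolates failures", {
  cfg <- small_config(seed = 17)
  co <- simulate_cohort(cfg)
  mt <- simulate_metric_table(co, cfg)
  zr <- zscore_table(co, mt, metrics = c("density", "nbv"))
  expect_setequal(names(zr$z), c("subject_id", "group", "center_id",
                                 "density", "nbv"))
  expect_equal(nrow(zr$z), sum(co$group != "HC"))
  # single metric matches row-wise zscore()
  hc <- merge(co[co$group == "HC", ], mt, by = "subject_id")
  pat <- merge(co[co$group != "HC", ], mt, by = "subject_id")
  m <- fit_reference(hc, "density")
  manual <- suppressWarnings(
    zscore(pat$density, pat$sex, pat$age_at_mri, pat$center_id, m))
  expect_equal(zr$z$density[match(pat$subject_id, zr$z$subject_id)], manual)
  # empty metric list -> ids only
  zr0 <- zscore_table(co, mt, metrics = character(0))
  expect_equal(names(zr0$z), c("subject_id", "group", "center_id"))
  # a broken metric fails alone, others proceed
  mt_bad <- mt
  mt_bad$nbv[3] <- NA
  expect_warning(zrb <- zscore_table(co, mt_bad, metrics = c("density", "nbv")),
                 "failed")
  expect_true("density" %in% names(zrb$z))
  expect_false("nbv" %in% names(zrb$z))
  expect_match(zrb$failures[["nbv"]], "missing")
})
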