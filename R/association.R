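# Univariable odds-ratio models for SDMT impairment with the study's unit
# scalings, group-interaction tests under robust (sandwich) covariance, and
# the balanced downsampled bootstrap.

glm_sandwich <- function(fit) {
  X <- model.matrix(fit)
  mu <- fitted(fit)
  y <- fit$y
  W <- mu * (1 - mu)
  bread <- solve(crossprod(X, X * W))
  meat <- crossprod(X, X * (y - mu)^2)
  bread %*% meat %*% bread
}

check_separation <- function(fit, label, terms = "x") {
  # only the terms under inference matter; a sparse nuisance center dummy
  # may separate without invalidating the predictor's sandwich inference
  b <- coef(fit)[intersect(terms, names(coef(fit)))]
  if (!fit$converged || any(!is.finite(b)) || max(abs(b)) > 15)
    stop_convergence("(quasi-)separation or non-convergence in logistic model",
                     " for predictor '", label, "'")
}

#' Univariable robust logistic association with SDMT impairment
#'
#' Maximum-likelihood logistic point estimates with heteroscedasticity-robust
#' (sandwich, HC0) standard errors -- the working implementation of a robust
#' quasi-likelihood estimation approach. Odds ratios are reported per the
#' study's units: per year (age, duration), per 10% increase in lesion
#' volume (predictor entered as log LV, OR = exp(beta * ln 1.1)), per 1
#' percentage point of disconnection, per 1 z-unit otherwise.
#'
#' @param outcome binary (logical/0-1) impairment indicator.
#' @param predictor numeric or binary predictor, on its raw scale (pass raw
#'   LV in mL with `unit = "per_10pct_lv"`; the log is taken internally).
#' @param covariates optional data.frame of adjustment covariates (the study
#'   adjusts LV and disconnection models for center).
#' @param unit `"per_unit"` (default), `"per_10pct_lv"`, or `"log_or"`.
#' @param conf_level confidence level for the Wald CI.
#' @param label predictor name for reporting.
#' @return one-row data.frame: predictor, or, ci_lo, ci_hi, p, beta, se,
#'   unit, n.
#' @export
univariable_or <- function(outcome, predictor, covariates = NULL,
                           unit = c("per_unit", "per_10pct_lv"),
                           conf_level = 0.95, label = "predictor") {
  unit <- match.arg(unit)
  y <- as.numeric(outcome)
  if (length(unique(y[!is.na(y)])) < 2) stop_data("outcome is constant")
  x <- predictor
  if (unit == "per_10pct_lv") {
    if (any(x <= 0)) x[x <= 0] <- min(x[x > 0]) / 2
    x <- log(x)
  }
  d <- data.frame(y = y, x = x)
  if (!is.null(covariates)) d <- cbind(d, covariates)
  d <- d[complete.cases(d), ]
  fit <- glm(y ~ ., family = binomial(), data = d)
  check_separation(fit, label)
  V <- glm_sandwich(fit)
  b <- coef(fit)[["x"]]
  se <- sqrt(V["x", "x"])
  scale <- if (unit == "per_10pct_lv") log(1.1) else 1
  zq <- qnorm(1 - (1 - conf_level) / 2)
  p <- 2 * pnorm(-abs(b / se))
  data.frame(predictor = label,
             or = exp(b * scale),
             ci_lo = exp((b - zq * se) * scale),
             ci_hi = exp((b + zq * se) * scale),
             p = p, beta = b * scale, se = se * scale,
             unit = unit, n = nrow(d), stringsAsFactors = FALSE)
}

#' Group-by-predictor interaction test
#'
#' Wald p-value for the group x predictor coefficient of a logistic model
#' under sandwich covariance (does the association differ between late- and
#' adult-onset patients?).
#'
#' @inheritParams univariable_or
#' @param group two-level factor (e.g. AOMS/LOMS).
#' @return list with `p`, `beta`, `se`.
#' @export
interaction_test <- function(outcome, predictor, group, covariates = NULL,
                             unit = c("per_unit", "per_10pct_lv"),
                             label = "predictor") {
  unit <- match.arg(unit)
  g <- droplevels(as.factor(group))
  if (nlevels(g) < 2) stop_data("group indicator is constant")
  if (nlevels(g) > 2) stop_data("exactly two groups required")
  x <- predictor
  if (unit == "per_10pct_lv") {
    if (any(x <= 0)) x[x <= 0] <- min(x[x > 0]) / 2
    x <- log(x)
  }
  d <- data.frame(y = as.numeric(outcome), x = x, g = g)
  if (!is.null(covariates)) d <- cbind(d, covariates)
  d <- d[complete.cases(d), ]
  fit <- glm(y ~ . + x:g, family = binomial(), data = d)
  term0 <- grep("^x($|:)", names(coef(fit)), value = TRUE)
  check_separation(fit, label, terms = term0)
  V <- glm_sandwich(fit)
  term <- grep("^x:g", colnames(V), value = TRUE)
  b <- coef(fit)[[term]]
  se <- sqrt(V[term, term])
  list(p = 2 * pnorm(-abs(b / se)), beta = b, se = se)
}

#' Balanced downsampled bootstrap
#'
#' Per replicate, draws `n_per_group` subjects with replacement from each
#' group (equalizing group influence), reruns `stat_fn`, and reports
#' empirical percentile confidence intervals plus a two-sided bootstrap
#' p-value: 2 * min(fraction of replicate statistics <= null, >= null),
#' floored at 1/reps. Replicates that fail (e.g. separation) are dropped and
#' counted; more than 20% failures is an error.
#'
#' @param stat_fn function(data) returning a single numeric statistic on a
#'   scale where `null_value` is the null (log-OR scale with null 0 for the
#'   association models).
#' @param data data.frame of the analysis sample.
#' @param group column name defining the resampling strata.
#' @param n_per_group samples drawn per group per replicate (default 80).
#' @param reps bootstrap replicates (study default 5000; scale down for
#'   testing).
#' @param seed integer seed; replicates are deterministic given it.
#' @param conf_level percentile CI level.
#' @param null_value null for the bootstrap p.
#' @param transform function applied to the replicate statistics before the
#'   CI is taken (e.g. `exp` to report CIs on the OR scale).
#' @return list with `ci`, `p`, `reps_used`, `failures`, `stats`.
#' @export
balanced_bootstrap <- function(stat_fn, data, group, n_per_group = 80L,
                               reps = 5000L, seed = 1L, conf_level = 0.95,
                               null_value = 0, transform = identity) {
  g <- as.factor(data[[group]])
  if (any(table(g) < 3)) stop_data("each group needs at least 3 members")
  idx_by_g <- split(seq_len(nrow(data)), g)
  stats <- rep(NA_real_, reps)
  with_seed(seed, {
    for (r in seq_len(reps)) {
      take <- unlist(lapply(idx_by_g, function(i)
        i[sample.int(length(i), n_per_group, replace = TRUE)]))
      stats[r] <- tryCatch(stat_fn(data[take, , drop = FALSE]),
                           error = function(e) NA_real_)
    }
  })
  fails <- sum(is.na(stats))
  if (fails > 0.2 * reps)
    stop_convergence(fails, " of ", reps, " bootstrap replicates failed")
  ok <- stats[!is.na(stats)]
  alpha <- 1 - conf_level
  ci <- quantile(transform(ok), c(alpha / 2, 1 - alpha / 2), names = FALSE,
                 type = 6)
  if (all(ok == ok[1])) {
    # degenerate analysis: no sampling variability, no evidence either way
    p <- 1
  } else {
    p <- 2 * min(mean(ok <= null_value), mean(ok >= null_value))
    p <- min(1, max(p, 1 / reps))
  }
  list(ci = ci, p = p, reps_used = length(ok), failures = fails, stats = stats)
}
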