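# Group-comparison machinery: contingency and rank tests for demographics,
# robust regression on normative z-scores, log-scale lesion volume with a
# delta-method back-transform, quasi-binomial disconnection models, and
# Benjamini-Hochberg FDR over each results table.

#' Contingency-table test
#'
#' Pearson chi-square WITHOUT continuity correction, or Fisher's exact test
#' with the minimum-likelihood two-sided rule (the defaults of the major
#' statistics packages; both reproduce the study's printed p-values).
#'
#' @param counts matrix of non-negative integer counts (groups in rows).
#' @param method `"chisq"` or `"fisher"`.
#' @return list with `statistic` (chisq only), `p`, `method`.
#' @export
contingency_test <- function(counts, method = c("chisq", "fisher")) {
  method <- match.arg(method)
  counts <- as.matrix(counts)
  if (any(counts < 0) || any(counts != round(counts)))
    stop_data("counts must be non-negative integers")
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0))
    stop_data("contingency table has a zero margin")
  if (method == "chisq") {
    ht <- suppressWarnings(chisq.test(counts, correct = FALSE))
    list(statistic = unname(ht$statistic), p = ht$p.value, method = "chisq")
  } else {
    ht <- fisher.test(counts)
    list(statistic = NA_real_, p = ht$p.value, method = "fisher")
  }
}

#' Mann-Whitney (Wilcoxon rank-sum) test
#'
#' Exact two-sided p for small untied samples (both n <= 20), otherwise the
#' normal approximation with tie correction (no continuity correction).
#'
#' @param x,y numeric samples.
#' @return list with `U`, `p`, `exact`.
#' @export
mann_whitney <- function(x, y) {
  if (!length(x) || !length(y)) stop_data("both samples must be non-empty")
  exact <- length(x) <= 20 && length(y) <= 20 && !anyDuplicated(c(x, y))
  ht <- suppressWarnings(
    wilcox.test(x, y, exact = exact, correct = FALSE))
  list(U = unname(ht$statistic), p = ht$p.value, exact = exact)
}

rlm_fit <- function(formula, data) {
  fit <- MASS::rlm(formula, data = data, psi = MASS::psi.huber, k = 1.345,
                   scale.est = "MAD", maxit = 100)
  if (!fit$converged) stop_convergence("robust regression did not converge")
  fit
}

rlm_wald <- function(fit, contrast) {
  V <- vcov(fit)
  est <- sum(contrast * coef(fit))
  se <- sqrt(drop(t(contrast) %*% V %*% contrast))
  p <- 2 * pnorm(-abs(est / se))
  c(estimate = est, se = se, p = p)
}

#' Robust comparison of normative z-scores
#'
#' M-estimation (Huber psi, k = 1.345, MAD scale) of per-group mean z-scores
#' with tests of mean z = 0 within each group (is the patient group abnormal
#' relative to the healthy reference?) and a between-group difference test.
#'
#' @param z numeric z-scores.
#' @param group factor/character with exactly two patient groups.
#' @return data.frame rows: one per group (estimate, se, p vs 0) and one
#'   `difference` row.
#' @export
robust_z_comparison <- function(z, group) {
  group <- as.factor(droplevels(as.factor(group)))
  if (nlevels(group) != 2) stop_data("exactly two patient groups required")
  if (any(table(group) < 3)) stop_data("each group needs at least 3 subjects")
  if (sd(z) == 0) {
    # degenerate input: no residual scale for M-estimation; answer directly
    lv <- levels(group)
    return(data.frame(
      term = c(lv, "difference"),
      estimate = c(z[1], z[1], 0), se = 0,
      p = c(as.numeric(z[1] != 0), as.numeric(z[1] != 0), 1)))
  }
  d <- data.frame(z = z, g = group)
  fit <- rlm_fit(z ~ 0 + g, d)
  lv <- levels(group)
  rows <- lapply(seq_along(lv), function(i) {
    ct <- as.numeric(seq_along(lv) == i)
    w <- rlm_wald(fit, ct)
    data.frame(term = lv[i], estimate = w["estimate"], se = w["se"],
               p = w["p"], row.names = NULL)
  })
  fit2 <- rlm_fit(z ~ g, d)
  w2 <- rlm_wald(fit2, c(0, 1))
  out <- rbind(do.call(rbind, rows),
               data.frame(term = "difference", estimate = w2["estimate"],
                          se = w2["se"], p = w2["p"], row.names = NULL))
  rownames(out) <- NULL
  out
}

marginal_contrasts <- function(X, group_col_idx, lv) {
  # contrast vectors giving each group's marginal mean over the observed
  # covariate distribution: average design row with group set to each level
  lapply(seq_along(lv), function(i) {
    Xi <- X
    Xi[, group_col_idx] <- 0
    if (i > 1) Xi[, group_col_idx[i - 1]] <- 1
    colMeans(Xi)
  })
}

#' Compare lesion volume on the log scale with delta-method back-transform
#'
#' Robust (Huber) linear regression of log LV on group, sex and center;
#' group marginal means on the log scale are mapped back to mL by the delta
#' method (mean = exp(mu), SE = exp(mu) * SE(mu)). Zero volumes are offset
#' by half the smallest positive LV before the log (configurable convention;
#' the source analysis is silent on zeros).
#'
#' @param lv_ml lesion volumes (mL).
#' @param group,sex,center covariates.
#' @param zero_offset offset for zero LV; default half the minimum positive.
#' @return list with `by_group` (back-transformed mean, se per group) and
#'   `between` (estimate on log scale, se, p).
#' @export
compare_lesion_volume <- function(lv_ml, group, sex, center,
                                  zero_offset = NULL) {
  if (all(lv_ml <= 0)) stop_data("all lesion volumes are zero")
  if (any(lv_ml < 0)) stop_data("negative lesion volumes")
  if (any(lv_ml == 0)) {
    off <- zero_offset %||% (min(lv_ml[lv_ml > 0]) / 2)
    lv_ml[lv_ml == 0] <- off
  }
  g <- droplevels(as.factor(group))
  if (nlevels(g) != 2) stop_data("exactly two groups required")
  d <- data.frame(y = log(lv_ml), g = g, sex = as.factor(sex),
                  center = as.factor(center))
  fit <- rlm_fit(y ~ g + sex + center, d)
  X <- model.matrix(~ g + sex + center, d)
  gidx <- which(colnames(X) %in% paste0("g", levels(g)[-1]))
  cts <- marginal_contrasts(X, gidx, levels(g))
  by_group <- do.call(rbind, lapply(seq_along(cts), function(i) {
    w <- rlm_wald(fit, cts[[i]])
    data.frame(group = levels(g)[i],
               mean_ml = exp(w["estimate"]),
               se_ml = exp(w["estimate"]) * w["se"], row.names = NULL)
  }))
  bw <- rlm_wald(fit, as.numeric(seq_along(coef(fit)) == gidx))
  list(by_group = by_group,
       between = data.frame(estimate_log = bw["estimate"], se = bw["se"],
                            p = bw["p"], row.names = NULL))
}

#' Compare disconnection proportions with quasi-binomial regression
#'
#' Logit-link quasi-binomial model of the per-subject lesioned-streamline
#' proportion on group, sex and center, with estimated dispersion. Group
#' means are marginal predicted probabilities (averaged over the observed
#' sex/center distribution) on the percent scale.
#'
#' @param proportions values in [0, 1].
#' @param group,sex,center covariates.
#' @param trials optional per-subject streamline counts (prior weights);
#'   with counts supplied, overdispersed data yield dispersion > 1.
#' @return list with `by_group` (estimated mean percent, se) `between`
#'   (group coefficient p) and `dispersion`.
#' @export
compare_disconnection <- function(proportions, group, sex, center,
                                  trials = NULL) {
  check_prob(proportions, "proportions")
  g <- droplevels(as.factor(group))
  if (nlevels(g) != 2) stop_data("exactly two groups required")
  d <- data.frame(p = proportions, g = g, sex = as.factor(sex),
                  center = as.factor(center))
  d$.w <- trials %||% rep(1, nrow(d))
  fit <- glm(p ~ g + sex + center, family = quasibinomial(), data = d,
             weights = .w)
  sm <- summary(fit)
  co <- sm$coefficients
  gterm <- paste0("g", levels(g)[2])
  by_group <- do.call(rbind, lapply(levels(g), function(lev) {
    nd <- d; nd$g <- factor(lev, levels = levels(g))
    mu <- predict(fit, newdata = nd, type = "response")
    # delta-method SE of the marginal mean via the link-scale covariance
    X <- model.matrix(~ g + sex + center, nd)
    grad <- colMeans(X * (mu * (1 - mu)))
    se <- sqrt(drop(t(grad) %*% vcov(fit) %*% grad))
    data.frame(group = lev, mean_pct = 100 * mean(mu), se_pct = 100 * se,
               row.names = NULL)
  }))
  list(by_group = by_group,
       between = data.frame(estimate = co[gterm, "Estimate"],
                            se = co[gterm, "Std. Error"],
                            p = co[gterm, "Pr(>|t|)"], row.names = NULL),
       dispersion = sm$dispersion)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up BH with monotonicity enforcement; apply to the full set of
#' p-values of one results table (families are never pooled across tables).
#'
#' @param p p-values in [0, 1].
#' @return q-values, same length and order.
#' @export
fdr_adjust <- function(p) {
  check_prob(p[!is.na(p)], "p-values")
  p.adjust(p, method = "BH")
}
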