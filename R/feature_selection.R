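# Center-adjusted elastic-net logistic regression ranking substrates of
# SDMT impairment, 1-SE-rule tuning on 5-fold cross-validated deviance, and
# downsampled-bootstrap selection frequencies.

stratified_folds <- function(y, nfolds, seed) {
  with_seed(seed, {
    for (try in 1:10) {
      foldid <- integer(length(y))
      for (cls in unique(y)) {
        i <- which(y == cls)
        foldid[i] <- sample(rep_len(seq_len(nfolds), length(i)))
      }
      ok <- all(vapply(seq_len(nfolds), function(f)
        length(unique(y[foldid == f])) == 2, logical(1)))
      if (ok) return(foldid)
    }
    stop_data("could not build folds with both outcome classes present")
  })
}

#' Rank-based AUC
#'
#' Mann-Whitney AUC with tie correction: the probability a random positive
#' scores above a random negative (ties count 1/2).
#'
#' @param scores numeric scores (higher = more likely positive).
#' @param labels binary labels.
#' @return AUC in [0, 1].
#' @export
auc_rank <- function(scores, labels) {
  y <- as.logical(labels)
  n1 <- sum(y); n0 <- sum(!y)
  if (n1 == 0 || n0 == 0) stop_data("both classes must be present")
  r <- rank(scores)
  (sum(r[y]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Elastic-net logistic selection with the 1-SE rule
#'
#' Predictors are standardized (mean 0, SD 1); center indicators enter
#' UNPENALIZED ("center-adjusted" read as adjustment, not a selection
#' candidate). The penalty path is tuned by 5-fold cross-validated binomial
#' deviance with stratified folds; the chosen lambda is the largest whose
#' mean deviance lies within one standard error of the minimum. Reported
#' standardized ORs are exp(standardized beta); AUC is in-sample on the full
#' fit (mirroring a full-sample analysis) with the cross-validated AUC also
#' reported, clearly labeled.
#'
#' @param X data.frame/matrix of raw-scale predictors (>= 2 columns).
#' @param y binary outcome.
#' @param center optional center id vector; expanded to unpenalized
#'   indicator columns.
#' @param alpha elastic-net mixing parameter (1 = lasso); the source
#'   analysis does not state it, default 0.5.
#' @param nfolds cross-validation folds.
#' @param seed integer seed (fold assignment).
#' @return object of class `selection_result`: coefficient table
#'   (standardized beta, standardized OR, selected flag), `lambda`, `alpha`,
#'   `auc_insample`, `auc_cv`, `selected`.
#' @export
elastic_net_select <- function(X, y, center = NULL, alpha = 0.5,
                               nfolds = 5L, seed = 1L) {
  X <- as.data.frame(X)
  if (ncol(X) < 2) stop_config("need at least 2 predictors")
  y <- as.numeric(y)
  if (length(unique(y)) != 2) stop_data("outcome must be binary")
  sds <- vapply(X, sd, numeric(1))
  const <- sds == 0 | !is.finite(sds)
  if (any(const)) {
    warning("dropping constant predictor(s): ",
            paste(names(X)[const], collapse = ", "))
    X <- X[!const]
  }
  Xs <- scale(as.matrix(X))
  pnames <- colnames(Xs)
  pf <- rep(1, ncol(Xs))
  if (!is.null(center)) {
    cf <- as.factor(center)
    if (nlevels(cf) > 1) {
      cd <- model.matrix(~ cf)[, -1, drop = FALSE]
      colnames(cd) <- paste0(".center", levels(cf)[-1])
      Xs <- cbind(Xs, cd)
      pf <- c(pf, rep(0, ncol(cd)))
    }
  }
  foldid <- stratified_folds(y, nfolds, substream_seed(seed, "folds"))
  cv <- with_seed(substream_seed(seed, "glmnet"),
                  glmnet::cv.glmnet(Xs, y, family = "binomial", alpha = alpha,
                                    foldid = foldid, penalty.factor = pf,
                                    standardize = FALSE,
                                    type.measure = "deviance"))
  lam <- cv$lambda.1se   # largest lambda with cvm <= min(cvm) + its SE
  bm <- as.matrix(coef(cv$glmnet.fit, s = lam))
  beta <- setNames(bm[, 1], rownames(bm))[-1]     # drop intercept
  bet <- beta[pnames]
  eta <- drop(predict(cv$glmnet.fit, newx = Xs, s = lam))
  # held-out scores for an honest cross-validated AUC at the same lambda
  eta_cv <- rep(NA_real_, length(y))
  for (f in sort(unique(foldid))) {
    hold <- foldid == f
    fit_f <- with_seed(substream_seed(seed, paste0("cvfit", f)),
                       glmnet::glmnet(Xs[!hold, , drop = FALSE], y[!hold],
                                      family = "binomial", alpha = alpha,
                                      penalty.factor = pf, standardize = FALSE))
    eta_cv[hold] <- drop(predict(fit_f, newx = Xs[hold, , drop = FALSE], s = lam))
  }
  tab <- data.frame(predictor = pnames,
                    beta_std = unname(bet),
                    or_std = unname(exp(bet)),
                    selected = unname(bet != 0),
                    stringsAsFactors = FALSE)
  structure(list(coefficients = tab, lambda = lam,
                 lambda_min = cv$lambda.min, alpha = alpha,
                 auc_insample = auc_rank(eta, y),
                 auc_cv = auc_rank(eta_cv, y),
                 selected = pnames[bet != 0],
                 cv = list(lambda = cv$lambda, cvm = cv$cvm, cvsd = cv$cvsd)),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat("Elastic-net selection (alpha = ", x$alpha, ", lambda[1SE] = ",
      signif(x$lambda, 3), ")\n", sep = "")
  cat("in-sample AUC = ", round(x$auc_insample, 3),
      " | cross-validated AUC = ", round(x$auc_cv, 3), "\n", sep = "")
  sel <- x$coefficients[x$coefficients$selected, ]
  if (nrow(sel)) print(sel, row.names = FALSE) else cat("no predictors selected\n")
  invisible(x)
}

#' Bootstrap selection frequencies under balanced downsampling
#'
#' Repeats the full elastic-net tuning on bootstrap samples of `n` subjects
#' drawn with replacement from the analysis group's data (the study
#' downsamples each onset group's own model to n = 80), and reports the
#' percentage of replicates in which each predictor has a nonzero
#' coefficient.
#'
#' @inheritParams elastic_net_select
#' @param n downsampled size per replicate.
#' @param reps replicates (study default 5000; scale down for testing).
#' @return data.frame: predictor, freq_pct; attribute `failures`.
#' @export
selection_frequencies <- function(X, y, center = NULL, alpha = 0.5, n = 80L,
                                  reps = 5000L, seed = 1L, nfolds = 5L) {
  X <- as.data.frame(X)
  y <- as.numeric(y)
  counts <- setNames(rep(0, ncol(X)), names(X))
  fails <- 0L
  rep_seeds <- with_seed(substream_seed(seed, "repseeds"),
                         sample.int(2147483646L, reps))
  for (r in seq_len(reps)) {
    res <- tryCatch({
      take <- with_seed(rep_seeds[r], sample.int(length(y), n, replace = TRUE))
      if (length(unique(y[take])) < 2) stop("one class only")
      fit <- elastic_net_select(X[take, , drop = FALSE], y[take],
                                center = if (is.null(center)) NULL else center[take],
                                alpha = alpha, nfolds = nfolds,
                                seed = rep_seeds[r])
      fit$selected
    }, error = function(e) NULL, warning = function(w) NULL)
    if (is.null(res)) fails <- fails + 1L else counts[res] <- counts[res] + 1
  }
  used <- reps - fails
  if (used < 0.8 * reps)
    stop_convergence(fails, " of ", reps, " selection replicates failed")
  out <- data.frame(predictor = names(counts),
                    freq_pct = 100 * unname(counts) / used,
                    stringsAsFactors = FALSE)
  attr(out, "failures") <- fails
  out
}
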