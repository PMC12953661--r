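# Multicenter normative reference models: linear mean structure
# (sex + age + sex:age + center) fitted to healthy controls by feasible
# generalized least squares with center-specific residual variances, then
# used to convert patient measures to z-scores.

reference_design <- function(sex, age, center, age_center, center_levels) {
  male <- as.numeric(sex == "M")
  age_c <- age - age_center
  X <- cbind(`(Intercept)` = 1, male = male, age_c = age_c,
             male_age = male * age_c)
  if (length(center_levels) > 1) {
    for (cl in center_levels[-1])
      X <- cbind(X, as.numeric(as.character(center) == cl))
    colnames(X)[(ncol(X) - length(center_levels) + 2):ncol(X)] <-
      paste0("center", center_levels[-1])
  }
  X
}

#' Fit a heteroscedastic normative reference model on healthy controls
#'
#' Mean model: metric ~ sex + age + sex:age + center (sex coded F=0/M=1, age
#' centered at the HC mean). Residual variances are center-specific and
#' estimated by iterating weighted least squares and per-center residual
#' variance to convergence (feasible GLS). Center variances use residual
#' degrees of freedom (n_c minus the center's share of model parameters) to
#' reduce small-center bias.
#'
#' @param hc data.frame of healthy-control rows with columns `sex`, `age`
#'   (or `age_at_mri`), `center` (or `center_id`) and the metric column.
#' @param metric name of the metric column.
#' @param tol relative convergence tolerance on the center SDs.
#' @param max_iter maximum FGLS iterations.
#' @param heteroscedastic if FALSE, a single shared residual SD is used and
#'   the fit reduces exactly to ordinary least squares.
#' @return object of class `reference_model` with coefficients, per-center
#'   residual SDs, the age-centering constant, and fit diagnostics.
#' @export
fit_reference <- function(hc, metric, tol = 1e-8, max_iter = 50L,
                          heteroscedastic = TRUE) {
  age <- hc$age %||% hc$age_at_mri
  center <- as.character(hc$center %||% hc$center_id)
  y <- hc[[metric]]
  if (is.null(y)) stop_data("metric column '", metric, "' not found")
  keep <- complete.cases(y, age, hc$sex, center)
  if (!all(keep)) stop_data("metric column '", metric, "' has missing values")
  tab <- table(center)
  small <- names(tab)[tab < 2]
  if (length(small))
    stop_data("center(s) with fewer than 2 HC: ", paste(small, collapse = ", "))
  center_levels <- sort(unique(center))
  age_center <- mean(age)
  X <- reference_design(hc$sex, age, center, age_center, center_levels)
  p <- ncol(X)
  n <- length(y)
  sigma <- setNames(rep(sd(y), length(center_levels)), center_levels)
  trace <- numeric(0)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    w <- 1 / sigma[center]^2
    fit <- lm.wfit(X, y, w)
    res <- y - X %*% fit$coefficients
    new_sigma <- sigma
    if (heteroscedastic) {
      for (cl in center_levels) {
        i <- center == cl
        df <- sum(i) - p * sum(i) / n   # center's share of model df
        if (df <= 0) df <- max(sum(i) - 1, 1)
        new_sigma[cl] <- sqrt(sum(res[i]^2) / df)
      }
    } else {
      new_sigma[] <- sqrt(sum(res^2) / (n - p))
    }
    delta <- max(abs(new_sigma - sigma) / pmax(sigma, .Machine$double.eps))
    trace <- c(trace, delta)
    sigma <- new_sigma
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged)
    stop_convergence("FGLS did not converge for '", metric, "' after ",
                     max_iter, " iterations; relative changes: ",
                     paste(signif(tail(trace, 5), 3), collapse = ", "))
  structure(list(
    metric = metric, coefficients = setNames(drop(fit$coefficients), colnames(X)),
    sigma = sigma, age_center = age_center, center_levels = center_levels,
    age_range = range(age), n_per_center = as.integer(tab[center_levels]),
    converged = converged, iterations = it
  ), class = "reference_model")
}

#' @export
print.reference_model <- function(x, ...) {
  cat("Normative reference model for '", x$metric, "' (",
      length(x$center_levels), " centers, FGLS ", x$iterations,
      " iterations)\n", sep = "")
  print(signif(x$coefficients, 4))
  cat("per-center residual SD:\n")
  print(signif(x$sigma, 4))
  invisible(x)
}

predict_reference <- function(model, sex, age, center) {
  center <- as.character(center)
  unseen <- setdiff(unique(center), model$center_levels)
  if (length(unseen))
    stop_data("center(s) not in reference model: ", paste(unseen, collapse = ", "))
  X <- reference_design(sex, age, center, model$age_center, model$center_levels)
  drop(X %*% model$coefficients)
}

#' Convert raw measures to normative z-scores
#'
#' z = (y - yhat(sex, age, center)) / sigma_center; the raw-scale direction
#' is preserved (a larger-than-expected value gives a positive z). Patients
#' may be scored at ages outside the HC range (the reference spans the MS
#' age spectrum by design) but doing so raises a warning.
#'
#' @param y raw metric values.
#' @param sex,age,center patient covariates.
#' @param model a `reference_model`.
#' @return numeric z-scores.
#' @export
zscore <- function(y, sex, age, center, model) {
  stopifnot(inherits(model, "reference_model"))
  if (any(age < model$age_range[1] - 1e-9 | age > model$age_range[2] + 1e-9))
    warning("scoring ", sum(age < model$age_range[1] | age > model$age_range[2]),
            " subject(s) outside the HC age range [",
            signif(model$age_range[1], 3), ", ", signif(model$age_range[2], 3), "]")
  yhat <- predict_reference(model, sex, age, center)
  unname((y - yhat) / model$sigma[as.character(center)])
}

#' Z-score a patient metric table against HC reference models
#'
#' Fits one reference model per metric on the HC subset and converts every
#' patient row to z-scores. Lesion volume and disconnection percentages are
#' never z-scored (they are analyzed on their own scales). Per-metric
#' failures are collected and reported; other metrics proceed.
#'
#' @param cohort subject records (must include HC rows).
#' @param metrics_table output of [simulate_metric_table()] or measured
#'   equivalents, keyed by `subject_id`.
#' @param metrics metric names to score; defaults to [zscored_metrics()].
#' @return list with `z` (patient rows; subject_id, group, plus one z column
#'   per metric), `models` (named list of `reference_model`s), `failures`
#'   (named character vector of error messages).
#' @export
zscore_table <- function(cohort, metrics_table, metrics = zscored_metrics()) {
  dat <- merge(cohort, metrics_table, by = "subject_id", sort = FALSE)
  hc <- dat[dat$group == "HC", ]
  pat <- dat[dat$group != "HC", ]
  if (!nrow(hc)) stop_data("no HC rows to fit reference models on")
  out <- data.frame(subject_id = pat$subject_id, group = pat$group,
                    center_id = pat$center_id, stringsAsFactors = FALSE)
  models <- list()
  failures <- character(0)
  for (m in metrics) {
    res <- tryCatch({
      mod <- fit_reference(hc, m)
      z <- suppressWarnings(
        zscore(pat[[m]], pat$sex, pat$age_at_mri, pat$center_id, mod))
      list(mod = mod, z = z)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures[m] <- conditionMessage(res)
    } else {
      models[[m]] <- res$mod
      out[[m]] <- res$z
    }
  }
  if (length(failures))
    warning("z-scoring failed for: ", paste(names(failures), collapse = ", "))
  list(z = out, models = models, failures = failures)
}
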