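#' Metric columns handled by the pipeline
#'
#' `zscored_metrics()` lists the measures converted to normative z-scores;
#' lesion volume (compared on the log scale) and the two disconnection
#' percentages (compared with quasi-binomial models) stay on their raw scale.
#'
#' @return character vector of column names.
#' @export
zscored_metrics <- function() {
  c("nbv", "ngmv", "nwmv", "density", "efficiency", "mean_strength",
    "clustering", "modularity", "commissural_ratio",
    "intra_hemi_efficiency", "conservation_ratio")
}

#' @rdname zscored_metrics
#' @export
metric_columns <- function() {
  c("lv_ml", zscored_metrics(), "inter_disc_pct", "intra_disc_pct")
}

# Group mean z-shifts of the magnitude observed in the source cohort
# (network metrics and normalized volumes, in HC-SD units).
default_effect_profile <- function() {
  list(
    nbv                   = c(aoms = -0.523, loms = -0.813),
    ngmv                  = c(aoms = -0.455, loms = -0.746),
    nwmv                  = c(aoms = -0.331, loms = -0.307),
    density               = c(aoms = -0.979, loms = -1.667),
    efficiency            = c(aoms = -1.071, loms = -1.136),
    mean_strength         = c(aoms = -1.299, loms = -1.690),
    clustering            = c(aoms = -1.050, loms = -1.180),
    modularity            = c(aoms =  0.568, loms =  0.994),
    commissural_ratio     = c(aoms = -0.705, loms = -0.779),
    intra_hemi_efficiency = c(aoms = -0.092, loms =  0.003),
    conservation_ratio    = c(aoms = -0.590, loms = -0.763)
  )
}

# raw-scale HC reference for each z-scored metric: mean and between-subject SD
metric_scales <- function() {
  data.frame(
    metric = zscored_metrics(),
    mean = c(1500, 800, 700, 0.35, 0.25, 12, 0.30, 0.55, 0.12, 0.25, 0.50),
    sd   = c(60, 40, 35, 0.02, 0.02, 1.5, 0.025, 0.04, 0.015, 0.02, 0.06),
    stringsAsFactors = FALSE
  )
}

#' Configuration for the synthetic multicenter cohort
#'
#' Defaults reproduce the stated world of the study population: 7 centers,
#' 519 HC aged 18-77, 294 adult-onset (onset 18-45 y) and 80 late-onset
#' (onset >= 45 y) MS patients with at most 6 years of disease duration,
#' group-level metric shifts of the reported magnitude, heteroscedastic
#' center noise, and a logistic SDMT-impairment model with a ~39% base rate.
#'
#' @param n_centers number of acquisition centers.
#' @param n_hc,n_aoms,n_loms group sizes.
#' @param age_hc,onset_aoms,onset_loms age windows (years); ages are uniform
#'   within windows.
#' @param max_duration maximum disease duration (years).
#' @param sex_ratio named fractions of female participants per group.
#' @param education_p named probabilities of >= 13 years of education.
#' @param pms_p named probabilities of a progressive phenotype.
#' @param metric_effect_profile named list; per metric a vector
#'   `c(aoms=, loms=)` of mean z-shifts in HC-SD units.
#' @param disc_means mean disconnection percentages, rows inter/intra,
#'   columns hc/aoms/loms.
#' @param lv_meanlog,lv_sdlog log-normal lesion-volume parameters per patient
#'   group (mL scale).
#' @param impairment_model list with `intercept` (log-odds) and `coef`, a
#'   named vector of log-odds effects per 1 SD of the named predictor
#'   (standardized over patients).
#' @param center_sigma_multipliers positive per-center residual-SD factors.
#' @param sex_effect,age_effect,interaction_effect reference-model mean
#'   structure, in HC-SD units (per year for age terms).
#' @param seed master seed; all generators derive named substreams from it.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n_centers = 7L,
                       n_hc = 519L, n_aoms = 294L, n_loms = 80L,
                       age_hc = c(18, 77),
                       onset_aoms = c(18, 45),
                       onset_loms = c(45, 66),
                       max_duration = 6,
                       sex_ratio = c(hc = 0.56, aoms = 0.65, loms = 0.60),
                       education_p = c(hc = 0.83, aoms = 0.72, loms = 0.50),
                       pms_p = c(aoms = 0.04, loms = 0.10),
                       metric_effect_profile = default_effect_profile(),
                       disc_means = rbind(inter = c(hc = 0, aoms = 8.38, loms = 11.18),
                                          intra = c(hc = 0, aoms = 1.70, loms = 2.41)),
                       lv_meanlog = c(aoms = log(1.934) - 0.405,
                                      loms = log(2.910) - 0.405),
                       lv_sdlog = 0.9,
                       impairment_model = list(
                         intercept = qlogis(0.39),
                         coef = c(lv_ml = 0.35, intra_disc_pct = 0.35,
                                  clustering = -0.25, mean_strength = -0.25,
                                  efficiency = -0.20)),
                       center_sigma_multipliers = seq(0.8, 1.2,
                                                      length.out = n_centers),
                       sex_effect = 0.2, age_effect = -0.02,
                       interaction_effect = 0.005,
                       seed = 20260910L) {
  cfg <- list(n_centers = as.integer(n_centers), n_hc = as.integer(n_hc),
              n_aoms = as.integer(n_aoms), n_loms = as.integer(n_loms),
              age_hc = age_hc, onset_aoms = onset_aoms,
              onset_loms = onset_loms, max_duration = max_duration,
              sex_ratio = sex_ratio, education_p = education_p, pms_p = pms_p,
              metric_effect_profile = metric_effect_profile,
              disc_means = disc_means, lv_meanlog = lv_meanlog,
              lv_sdlog = lv_sdlog, impairment_model = impairment_model,
              center_sigma_multipliers = center_sigma_multipliers,
              sex_effect = sex_effect, age_effect = age_effect,
              interaction_effect = interaction_effect,
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  with(cfg, {
    if (n_centers < 1L) stop_config("n_centers must be >= 1")
    if (any(c(n_hc, n_aoms, n_loms) < 0L))
      stop_config("group sizes must be non-negative")
    if (length(center_sigma_multipliers) != n_centers)
      stop_config("center_sigma_multipliers must have one entry per center")
    if (any(center_sigma_multipliers <= 0))
      stop_config("center SD multipliers must be > 0")
    check_prob(sex_ratio, "sex_ratio")
    check_prob(education_p, "education_p")
    check_prob(pms_p, "pms_p")
    if (onset_loms[1] < 45) stop_config("LOMS onset window must start at >= 45")
    if (onset_aoms[1] < 18 || onset_aoms[2] > 45)
      stop_config("AOMS onset window must lie within (18, 45)")
    if (max_duration > 6) stop_config("disease duration cap is 6 years")
    bad <- setdiff(names(metric_effect_profile), zscored_metrics())
    if (length(bad))
      stop_config("unknown metric in effect profile: ",
                  paste(bad, collapse = ", "))
  })
  cfg
}

#' Simulate a multicenter cohort of subject records
#'
#' Draws demographics per group (uniform ages in the configured windows,
#' center assignment, sex, education, phenotype, EDSS), then draws SDMT
#' impairment from the configured logistic model applied to that subject's
#' jointly generated metric predictors (the metric table is regenerated
#' bit-identically by [simulate_metric_table()] from the same config).
#' `sdmt_z` is filled consistently with the impairment flag by a truncated
#' normal draw around the -1.5 SD cutoff.
#'
#' @param config a [sim_config()].
#' @return data.frame of subject records, one row per participant.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cohort <- with_seed(substream_seed(config$seed, "cohort"),
                      draw_demographics(config))
  metrics <- simulate_metric_table(cohort, config, .check = FALSE)
  with_seed(substream_seed(config$seed, "impairment"),
            draw_impairment(cohort, metrics, config))
}

draw_demographics <- function(cfg) {
  n <- cfg$n_hc + cfg$n_aoms + cfg$n_loms
  if (n == 0L) stop_config("empty cohort requested")
  group <- rep(c("HC", "AOMS", "LOMS"), c(cfg$n_hc, cfg$n_aoms, cfg$n_loms))
  key <- c(HC = "hc", AOMS = "aoms", LOMS = "loms")[group]
  center_id <- sample.int(cfg$n_centers, n, replace = TRUE)
  sex <- ifelse(runif(n) < cfg$sex_ratio[key], "F", "M")
  onset <- rep(NA_real_, n)
  onset[group == "AOMS"] <- runif(cfg$n_aoms, cfg$onset_aoms[1], cfg$onset_aoms[2])
  onset[group == "LOMS"] <- runif(cfg$n_loms, cfg$onset_loms[1], cfg$onset_loms[2])
  duration <- ifelse(group == "HC", NA_real_, runif(n, 0.2, cfg$max_duration))
  age <- ifelse(group == "HC", runif(n, cfg$age_hc[1], cfg$age_hc[2]),
                onset + duration)
  edss <- rep(NA_real_, n)
  edss[group == "AOMS"] <- pmin(7, pmax(0, round(rnorm(cfg$n_aoms, 1.6, 0.9) * 2) / 2))
  edss[group == "LOMS"] <- pmin(7, pmax(0, round(rnorm(cfg$n_loms, 2.4, 1.1) * 2) / 2))
  phen <- rep(NA_character_, n)
  phen[group == "AOMS"] <- ifelse(runif(cfg$n_aoms) < cfg$pms_p["aoms"], "PMS", "RRMS")
  phen[group == "LOMS"] <- ifelse(runif(cfg$n_loms) < cfg$pms_p["loms"], "PMS", "RRMS")
  data.frame(
    subject_id = sprintf("S%04d", seq_len(n)),
    center_id = center_id,
    group = group, sex = sex,
    age_at_mri = age, age_at_onset = onset, disease_duration = duration,
    education_ge13 = runif(n) < cfg$education_p[key],
    edss = edss, phenotype = phen,
    sdmt_z = NA_real_, sdmt_impaired = NA,
    stringsAsFactors = FALSE
  )
}

draw_impairment <- function(cohort, metrics, cfg) {
  n <- nrow(cohort)
  pat <- cohort$group != "HC"
  im <- cfg$impairment_model
  eta <- rep(im$intercept %||% 0, n)
  if (length(im$coef)) {
    pool <- cbind(metrics[metric_columns()],
                  age_at_mri = cohort$age_at_mri,
                  disease_duration = cohort$disease_duration,
                  sex_male = as.numeric(cohort$sex == "M"))
    bad <- setdiff(names(im$coef), names(pool))
    if (length(bad))
      stop_config("impairment model names unknown predictors: ",
                  paste(bad, collapse = ", "))
    for (nm in names(im$coef)) {
      x <- pool[[nm]]
      mu <- mean(x[pat], na.rm = TRUE)
      s <- sd(x[pat], na.rm = TRUE)
      if (!is.finite(s) || s == 0) s <- 1
      eta <- eta + im$coef[[nm]] * ifelse(is.na(x), 0, (x - mu) / s)
    }
  }
  imp <- rep(NA, n)
  imp[pat] <- runif(sum(pat)) < plogis(eta[pat])
  # HC carry a reference-normal SDMT z; patients' z respects the cutoff
  z <- rnorm(n)
  z[pat & imp] <- -1.5 - abs(rnorm(sum(pat & imp, na.rm = TRUE), 0, 0.8))
  z[pat & !imp] <- -1.5 + abs(rnorm(sum(pat & !imp, na.rm = TRUE), 0.2, 0.9))
  cohort$sdmt_z <- z
  cohort$sdmt_impaired <- z < -1.5
  cohort
}

#' Simulate the per-subject metric table
#'
#' Each z-scored metric is generated as a center-specific intercept plus sex,
#' age and sex-by-age effects, a group shift expressed in HC-SD units (so the
#' injected shift is exactly the expected normative z regardless of center),
#' and heteroscedastic Gaussian noise whose SD is the metric's base SD times
#' the center multiplier. Lesion volume is log-normal with group-specific
#' location (HC: 0); disconnection percentages are logit-normal around the
#' configured group means.
#'
#' @param cohort output of [simulate_cohort()] (or its demographic columns).
#' @param config the same [sim_config()] used to generate `cohort`.
#' @param .check internal; skip config revalidation.
#' @return data.frame with `subject_id` and one column per
#'   [metric_columns()] entry.
#' @export
simulate_metric_table <- function(cohort, config, .check = TRUE) {
  stopifnot(inherits(config, "sim_config"))
  if (.check) validate_sim_config(config)
  with_seed(substream_seed(config$seed, "metrics"), {
    n <- nrow(cohort)
    scales <- metric_scales()
    mult <- config$center_sigma_multipliers[cohort$center_id]
    age_c <- cohort$age_at_mri - mean(cohort$age_at_mri[cohort$group == "HC"] %||%
                                        cohort$age_at_mri)
    if (!any(cohort$group == "HC")) age_c <- cohort$age_at_mri - mean(cohort$age_at_mri)
    male <- as.numeric(cohort$sex == "M")
    # deterministic center intercept offsets, in SD units
    ctr_off <- (seq_len(config$n_centers) - (config$n_centers + 1) / 2) * 0.25
    out <- data.frame(subject_id = cohort$subject_id, stringsAsFactors = FALSE)
    for (k in seq_len(nrow(scales))) {
      m <- scales$metric[k]
      shift <- rep(0, n)
      prof <- config$metric_effect_profile[[m]]
      if (!is.null(prof)) {
        shift[cohort$group == "AOMS"] <- prof[["aoms"]]
        shift[cohort$group == "LOMS"] <- prof[["loms"]]
      }
      sd_c <- scales$sd[k] * mult
      y <- scales$mean[k] +
        scales$sd[k] * (ctr_off[cohort$center_id] +
                          config$sex_effect * male +
                          config$age_effect * age_c +
                          config$interaction_effect * male * age_c) +
        shift * sd_c + rnorm(n, 0, sd_c)
      out[[m]] <- y
    }
    lv <- rep(0, n)
    for (g in c("AOMS", "LOMS")) {
      i <- cohort$group == g
      lv[i] <- rlnorm(sum(i), config$lv_meanlog[[tolower(g)]], config$lv_sdlog)
    }
    out$lv_ml <- lv
    for (row in c("inter", "intra")) {
      mu <- config$disc_means[row, c(HC = "hc", AOMS = "aoms",
                                     LOMS = "loms")[cohort$group]]
      p <- ifelse(mu <= 0, 0,
                  plogis(rnorm(n, qlogis(pmin(pmax(mu / 100, 1e-6), 1 - 1e-6)), 0.3)))
      out[[paste0(row, "_disc_pct")]] <- 100 * p
    }
    out[c("subject_id", metric_columns())]
  })
}
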