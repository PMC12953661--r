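# End-to-end orchestration: simulate -> (optional geometry demo) -> zscore ->
# compare -> associate -> select, with tab-separated reports shaped like the
# study's Tables 1-4 and a JSON run manifest sufficient to re-run
# bit-identically.

#' Predictor roster for the association and selection analyses
#'
#' Demographics, lesion volume, normative z-scored MRI measures and the two
#' disconnection percentages, matching the study's univariable and
#' multivariable variable set.
#'
#' @return character vector of predictor names.
#' @export
predictor_roster <- function() {
  c("age_at_mri", "sex_male", "disease_duration", "lv_ml",
    zscored_metrics(), "inter_disc_pct", "intra_disc_pct")
}

build_predictor_table <- function(cohort, metrics, zres) {
  pat <- cohort[cohort$group != "HC", ]
  m <- metrics[match(pat$subject_id, metrics$subject_id), ]
  z <- zres$z[match(pat$subject_id, zres$z$subject_id), ]
  d <- data.frame(subject_id = pat$subject_id, group = pat$group,
                  center_id = pat$center_id,
                  sdmt_impaired = pat$sdmt_impaired,
                  age_at_mri = pat$age_at_mri,
                  sex_male = as.numeric(pat$sex == "M"),
                  disease_duration = pat$disease_duration,
                  lv_ml = m$lv_ml,
                  inter_disc_pct = m$inter_disc_pct,
                  intra_disc_pct = m$intra_disc_pct,
                  stringsAsFactors = FALSE)
  for (mm in zscored_metrics()) d[[mm]] <- z[[mm]]
  d
}

predictor_unit <- function(p) {
  if (p == "lv_ml") "per_10pct_lv" else "per_unit"
}

predictor_covariates <- function(p, d) {
  # the study adjusts only LV and disconnection models for center
  if (p %in% c("lv_ml", "inter_disc_pct", "intra_disc_pct"))
    data.frame(center = as.factor(d$center_id)) else NULL
}

stage_table1 <- function(cohort) {
  pat <- cohort$group != "HC"
  rows <- list()
  add <- function(variable, comparison, res)
    rows[[length(rows) + 1]] <<- data.frame(
      variable = variable, comparison = comparison,
      statistic = res$statistic %||% NA_real_, p = res$p,
      stringsAsFactors = FALSE)
  tab_sex <- function(g1, g2) {
    t(vapply(c(g1, g2), function(g)
      c(sum(cohort$group == g & cohort$sex == "M"),
        sum(cohort$group == g & cohort$sex == "F")), numeric(2)))
  }
  add("sex", "AOMS_vs_HC", contingency_test(tab_sex("HC", "AOMS"), "chisq"))
  add("sex", "LOMS_vs_HC", contingency_test(tab_sex("HC", "LOMS"), "chisq"))
  add("sex", "LOMS_vs_AOMS", contingency_test(tab_sex("AOMS", "LOMS"), "chisq"))
  tab_edu <- t(vapply(c("AOMS", "LOMS"), function(g)
    c(sum(cohort$group == g & cohort$education_ge13),
      sum(cohort$group == g & !cohort$education_ge13)), numeric(2)))
  add("education_ge13", "LOMS_vs_AOMS", contingency_test(tab_edu, "chisq"))
  tab_imp <- t(vapply(c("AOMS", "LOMS"), function(g)
    c(sum(cohort$group == g & cohort$sdmt_impaired, na.rm = TRUE),
      sum(cohort$group == g & !cohort$sdmt_impaired, na.rm = TRUE)),
    numeric(2)))
  add("sdmt_impaired", "LOMS_vs_AOMS", contingency_test(tab_imp, "chisq"))
  tab_ph <- t(vapply(c("AOMS", "LOMS"), function(g)
    c(sum(cohort$group == g & cohort$phenotype == "RRMS", na.rm = TRUE),
      sum(cohort$group == g & cohort$phenotype == "PMS", na.rm = TRUE)),
    numeric(2)))
  add("phenotype", "LOMS_vs_AOMS", contingency_test(tab_ph, "fisher"))
  for (v in c("age_at_mri", "disease_duration", "edss")) {
    x <- cohort[[v]][cohort$group == "AOMS"]
    y <- cohort[[v]][cohort$group == "LOMS"]
    x <- x[!is.na(x)]; y <- y[!is.na(y)]
    mw <- mann_whitney(x, y)
    add(v, "LOMS_vs_AOMS", list(statistic = mw$U, p = mw$p))
  }
  do.call(rbind, rows)
}

stage_table2 <- function(cohort, metrics, zres) {
  pat <- cohort[cohort$group != "HC", ]
  m <- metrics[match(pat$subject_id, metrics$subject_id), ]
  rows <- list()
  add <- function(variable, term, estimate, se, p)
    rows[[length(rows) + 1]] <<- data.frame(
      variable = variable, term = term, estimate = estimate, se = se, p = p,
      stringsAsFactors = FALSE)
  lvr <- compare_lesion_volume(m$lv_ml, pat$group, pat$sex, pat$center_id)
  for (i in seq_len(nrow(lvr$by_group)))
    add("lv_ml", lvr$by_group$group[i], lvr$by_group$mean_ml[i],
        lvr$by_group$se_ml[i], NA_real_)
  add("lv_ml", "difference", lvr$between$estimate_log, lvr$between$se,
      lvr$between$p)
  for (v in zscored_metrics()) {
    rz <- robust_z_comparison(zres$z[[v]], zres$z$group)
    for (i in seq_len(nrow(rz)))
      add(v, rz$term[i], rz$estimate[i], rz$se[i], rz$p[i])
  }
  for (v in c("inter_disc_pct", "intra_disc_pct")) {
    dc <- compare_disconnection(m[[v]] / 100, pat$group, pat$sex,
                                pat$center_id)
    for (i in seq_len(nrow(dc$by_group)))
      add(v, dc$by_group$group[i], dc$by_group$mean_pct[i],
          dc$by_group$se_pct[i], NA_real_)
    add(v, "difference", dc$between$estimate, dc$between$se, dc$between$p)
  }
  out <- do.call(rbind, rows)
  out$q <- NA_real_
  out$q[!is.na(out$p)] <- fdr_adjust(out$p[!is.na(out$p)])
  out
}

boot_table3 <- function(d, predictor, unit, n_per_group, reps, seed) {
  # one resampling stream yields the AOMS, LOMS and interaction statistics
  idx <- split(seq_len(nrow(d)), d$group)
  fit_one <- function(dd, grp) {
    di <- dd[dd$group == grp, ]
    univariable_or(di$sdmt_impaired, di[[predictor]],
                   covariates = predictor_covariates(predictor, di),
                   unit = unit, label = predictor)$beta
  }
  stats <- matrix(NA_real_, reps, 3,
                  dimnames = list(NULL, c("AOMS", "LOMS", "interaction")))
  with_seed(seed, {
    for (r in seq_len(reps)) {
      take <- unlist(lapply(idx, function(i)
        i[sample.int(length(i), n_per_group, replace = TRUE)]))
      dd <- d[take, , drop = FALSE]
      stats[r, ] <- tryCatch({
        it <- interaction_test(dd$sdmt_impaired, dd[[predictor]],
                               dd$group,
                               covariates = predictor_covariates(predictor, dd),
                               unit = unit, label = predictor)
        c(fit_one(dd, "AOMS"), fit_one(dd, "LOMS"), it$beta)
      }, error = function(e) rep(NA_real_, 3))
    }
  })
  stats
}

boot_summary <- function(b, reps) {
  ok <- b[!is.na(b)]
  if (!length(ok)) return(c(lo = NA, hi = NA, p = NA))
  ci <- quantile(exp(ok), c(0.025, 0.975), names = FALSE, type = 6)
  p <- if (all(ok == ok[1])) 1 else
    min(1, max(2 * min(mean(ok <= 0), mean(ok >= 0)), 1 / reps))
  c(lo = ci[1], hi = ci[2], p = p)
}

stage_table3 <- function(cohort, metrics, zres, n_per_group = 80L,
                         reps = 500L, seed = 1L) {
  d <- build_predictor_table(cohort, metrics, zres)
  rows <- list()
  for (p in predictor_roster()) {
    unit <- predictor_unit(p)
    res <- lapply(c("AOMS", "LOMS"), function(g) {
      dg <- d[d$group == g, ]
      univariable_or(dg$sdmt_impaired, dg[[p]],
                     covariates = predictor_covariates(p, dg),
                     unit = unit, label = p)
    })
    it <- interaction_test(d$sdmt_impaired, d[[p]], d$group,
                           covariates = predictor_covariates(p, d),
                           unit = unit, label = p)
    b <- boot_table3(d, p, unit, n_per_group, reps,
                     substream_seed(seed, paste0("boot_", p)))
    scale <- if (unit == "per_10pct_lv") log(1.1) else 1
    bs <- apply(b * scale, 2, boot_summary, reps = reps)
    for (i in 1:2) {
      g <- c("AOMS", "LOMS")[i]
      rows[[length(rows) + 1]] <- data.frame(
        predictor = p, group = g, unit = unit,
        or = res[[i]]$or, ci_lo = res[[i]]$ci_lo, ci_hi = res[[i]]$ci_hi,
        p = res[[i]]$p,
        boot_ci_lo = bs["lo", g], boot_ci_hi = bs["hi", g],
        boot_p = bs["p", g], interaction_p = it$p,
        boot_interaction_p = bs["p", "interaction"],
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

stage_table4 <- function(cohort, metrics, zres, alpha = 0.5, reps = 200L,
                         n = 80L, seed = 1L) {
  d <- build_predictor_table(cohort, metrics, zres)
  d$lv_ml <- log(pmax(d$lv_ml, min(d$lv_ml[d$lv_ml > 0]) / 2))
  out <- list()
  aucs <- c()
  for (g in c("AOMS", "LOMS")) {
    dg <- d[d$group == g, ]
    X <- dg[predictor_roster()]
    names(X)[names(X) == "lv_ml"] <- "log_lv"
    fit <- elastic_net_select(X, dg$sdmt_impaired, center = dg$center_id,
                              alpha = alpha,
                              seed = substream_seed(seed, paste0("en_", g)))
    fr <- selection_frequencies(X, dg$sdmt_impaired, center = dg$center_id,
                                alpha = alpha, n = n, reps = reps,
                                seed = substream_seed(seed, paste0("fr_", g)))
    tab <- merge(fit$coefficients, fr, by = "predictor", sort = FALSE)
    tab <- cbind(group = g, tab)
    out[[g]] <- tab
    aucs[g] <- fit$auc_insample
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "auc") <- aucs
  res
}

#' Run the full analysis pipeline on a synthetic cohort
#'
#' Executes simulate -> zscore -> compare -> associate -> select (plus an
#' optional small connectome-geometry demonstration), writes Table-1/2/3/4
#' shaped tab-separated reports into `out_dir`, and returns a run manifest
#' (config snapshot, seeds, file checksums, per-stage timings) sufficient to
#' re-run bit-identically. A stage failure halts with the stage name; the
#' manifest of completed stages is written first.
#'
#' @param config a [sim_config()].
#' @param out_dir output directory (created if needed).
#' @param assoc_reps,select_reps bootstrap replicates for the association
#'   and selection stages (study default 5000; defaults here are scaled
#'   down for runtime).
#' @param n_per_group balanced-bootstrap downsampling size.
#' @param alpha elastic-net mixing parameter.
#' @param geometry_subjects if > 0, additionally runs the streamline ->
#'   connectome -> metrics path for this many synthetic subjects as a
#'   demonstration (writes matrices under `geometry/`).
#' @return the manifest, invisibly (also written as `manifest.json`).
#' @export
run_all <- function(config, out_dir, assoc_reps = 500L, select_reps = 200L,
                    n_per_group = 80L, alpha = 0.5, geometry_subjects = 0L) {
  stopifnot(inherits(config, "sim_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(package_version = as.character(utils::packageVersion("mscognet")),
                   config = unclass(config), seed = config$seed,
                   stages = list(), files = list())
  flush_manifest <- function()
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  run_stage <- function(name, fn) {
    t0 <- Sys.time()
    warns <- character(0)
    res <- withCallingHandlers(
      tryCatch(fn(), error = function(e) {
        manifest$stages[[name]] <<- list(status = "failed",
                                         error = conditionMessage(e))
        flush_manifest()
        stop_data("stage '", name, "' failed: ", conditionMessage(e))
      }),
      warning = function(w) {
        warns <<- c(warns, conditionMessage(w))
        invokeRestart("muffleWarning")
      })
    manifest$stages[[name]] <<- list(
      status = "ok",
      elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs")),
      warnings = warns)
    res
  }
  emit <- function(obj, fname) {
    path <- file.path(out_dir, fname)
    write_table_tsv(obj, path)
    manifest$files[[fname]] <<- unname(tools::md5sum(path))
    path
  }

  sim <- run_stage("simulate", function() {
    cohort <- simulate_cohort(config)
    metrics <- simulate_metric_table(cohort, config)
    list(cohort = cohort, metrics = metrics)
  })
  emit(sim$cohort, "cohort.tsv")
  emit(sim$metrics, "metrics.tsv")

  if (geometry_subjects > 0) {
    run_stage("geometry", function() {
      gdir <- file.path(out_dir, "geometry")
      dir.create(gdir, showWarnings = FALSE)
      parc <- simulate_parcellation(20L, c(24L, 24L, 24L), 1)
      write_nifti(parc$label_grid, file.path(gdir, "parcellation.nii"), 1)
      ids <- head(sim$cohort$subject_id[sim$cohort$group != "HC"],
                  geometry_subjects)
      for (sid in ids) {
        srow <- sim$cohort[sim$cohort$subject_id == sid, ]
        sseed <- substream_seed(config$seed, paste0("geom_", sid))
        tr <- simulate_tractogram(parc, 400L, 0.15, seed = sseed)
        lv <- sim$metrics$lv_ml[sim$metrics$subject_id == sid]
        les <- simulate_lesions(c(24L, 24L, 24L), 1,
                                min(lv, 2), seed = sseed + 1L)
        asg <- assign_endpoints(tr, parc)
        cn <- build_connectome(asg, tr, parc$nodes)
        dx <- disconnection_indices(asg, intersect_lesions(tr, les),
                                    parc$nodes)
        write_matrix_tsv(cn$count, file.path(gdir, paste0(sid, "_count.tsv")))
        write_matrix_tsv(cn$fa, file.path(gdir, paste0(sid, "_fa.tsv")))
        gm <- graph_metric_set(cn, dx, n_repetitions = 10L, seed = sseed)
        write_table_tsv(cbind(subject_id = sid, gm),
                        file.path(gdir, paste0(sid, "_metrics.tsv")))
      }
      invisible(NULL)
    })
  }

  zres <- run_stage("zscore", function()
    zscore_table(sim$cohort, sim$metrics))
  emit(zres$z, "zscores.tsv")

  t1 <- run_stage("compare_table1", function() stage_table1(sim$cohort))
  emit(t1, "table1.tsv")
  t2 <- run_stage("compare_table2", function()
    stage_table2(sim$cohort, sim$metrics, zres))
  emit(t2, "table2.tsv")

  t3 <- run_stage("associate", function()
    stage_table3(sim$cohort, sim$metrics, zres, n_per_group = n_per_group,
                 reps = assoc_reps, seed = substream_seed(config$seed, "table3")))
  emit(t3, "table3.tsv")

  t4 <- run_stage("select", function()
    stage_table4(sim$cohort, sim$metrics, zres, alpha = alpha,
                 reps = select_reps, n = n_per_group,
                 seed = substream_seed(config$seed, "table4")))
  emit(cbind(t4, auc_insample = attr(t4, "auc")[t4$group]), "table4.tsv")

  flush_manifest()
  manifest$files[["manifest.json"]] <-
    unname(tools::md5sum(file.path(out_dir, "manifest.json")))
  invisible(manifest)
}

cli_help <- "usage: mscognet <command> [--config FILE] [--seed S] [--out-dir DIR]
commands:
  simulate     write cohort.tsv and metrics.tsv
  zscore       --cohort TSV --metrics TSV --out TSV
  metrics      --connectome TSV --nodes TSV [--reps N] [--seed S]
  compare      --cohort TSV --metrics TSV --out-dir DIR
  associate    --cohort TSV --metrics TSV --out-dir DIR [--reps N] [--n-per-group N]
  select       --cohort TSV --metrics TSV --out-dir DIR [--alpha A] [--reps N]
  run-all      full pipeline into --out-dir
exit codes: 0 ok, 2 config error, 3 data error, 4 convergence error"

parse_cli_args <- function(args) {
  opts <- list()
  i <- 1
  while (i <= length(args)) {
    a <- args[i]
    if (startsWith(a, "--")) {
      key <- sub("^--", "", a)
      opts[[gsub("-", "_", key)]] <- if (i < length(args)) args[i + 1] else ""
      i <- i + 2
    } else i <- i + 1
  }
  opts
}

#' Command-line entry point
#'
#' Dispatches the pipeline subcommands; see `inst/cli/mscognet`. Returns an
#' exit code: 0 success, 2 configuration error, 3 data error, 4 convergence
#' error.
#'
#' @param args character vector of command-line arguments.
#' @return integer exit code, invisibly.
#' @export
mscognet_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (!length(args) || args[1] %in% c("-h", "--help", "help")) {
    message(cli_help)
    return(invisible(0L))
  }
  cmd <- args[1]
  opts <- parse_cli_args(args[-1])
  code <- tryCatch({
    cfg <- if (!is.null(opts[["config"]])) read_config_json(opts[["config"]])
           else sim_config()
    if (!is.null(opts[["seed"]])) cfg$seed <- as.integer(opts[["seed"]])
    out_dir <- opts[["out_dir"]] %||% "."
    load_inputs <- function() {
      cohort <- read_table_tsv(opts[["cohort"]] %||% file.path(out_dir, "cohort.tsv"))
      metrics <- read_table_tsv(opts[["metrics"]] %||% file.path(out_dir, "metrics.tsv"))
      list(cohort = cohort, metrics = metrics)
    }
    switch(cmd,
      "simulate" = {
        cohort <- simulate_cohort(cfg)
        metrics <- simulate_metric_table(cohort, cfg)
        dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
        write_table_tsv(cohort, file.path(out_dir, "cohort.tsv"))
        write_table_tsv(metrics, file.path(out_dir, "metrics.tsv"))
      },
      "zscore" = {
        io <- load_inputs()
        zres <- zscore_table(io$cohort, io$metrics)
        write_table_tsv(zres$z, opts[["out"]] %||% file.path(out_dir, "zscores.tsv"))
      },
      "metrics" = {
        w <- read_matrix_tsv(opts[["connectome"]])
        nodes <- read_table_tsv(opts[["nodes"]])
        cn <- structure(list(count = (w > 0) * 1, fa = w, nodes = nodes),
                        class = "connectome")
        gm <- graph_metric_set(cn, NULL,
                               n_repetitions = as.integer(opts[["reps"]] %||% 100),
                               seed = as.integer(opts[["seed"]] %||% 1))
        write_table_tsv(gm, opts[["out"]] %||% file.path(out_dir, "metrics_row.tsv"))
      },
      "compare" = {
        io <- load_inputs()
        zres <- zscore_table(io$cohort, io$metrics)
        write_table_tsv(stage_table1(io$cohort), file.path(out_dir, "table1.tsv"))
        write_table_tsv(stage_table2(io$cohort, io$metrics, zres),
                        file.path(out_dir, "table2.tsv"))
      },
      "associate" = {
        io <- load_inputs()
        zres <- zscore_table(io$cohort, io$metrics)
        t3 <- stage_table3(io$cohort, io$metrics, zres,
                           n_per_group = as.integer(opts[["n_per_group"]] %||% 80),
                           reps = as.integer(opts[["reps"]] %||% 500),
                           seed = substream_seed(cfg$seed, "table3"))
        write_table_tsv(t3, file.path(out_dir, "table3.tsv"))
      },
      "select" = {
        io <- load_inputs()
        zres <- zscore_table(io$cohort, io$metrics)
        t4 <- stage_table4(io$cohort, io$metrics, zres,
                           alpha = as.numeric(opts[["alpha"]] %||% 0.5),
                           reps = as.integer(opts[["reps"]] %||% 200),
                           seed = substream_seed(cfg$seed, "table4"))
        write_table_tsv(t4, file.path(out_dir, "table4.tsv"))
      },
      "run-all" = {
        run_all(cfg, out_dir,
                assoc_reps = as.integer(opts[["reps"]] %||% 500),
                select_reps = as.integer(opts[["select_reps"]] %||% 200))
      },
      stop_config("unknown command '", cmd, "'; run with --help"))
    0L
  },
  mscognet_config_error = function(e) { message("config error: ", conditionMessage(e)); 2L },
  mscognet_convergence_error = function(e) { message("convergence error: ", conditionMessage(e)); 4L },
  error = function(e) { message("data error: ", conditionMessage(e)); 3L })
  invisible(code)
}
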