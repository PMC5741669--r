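#' Configuration for a full synthetic study run
#'
#' @param seed Master integer seed; every stage derives its own stream from
#'   it, so a fixed seed makes [run_study()] bit-reproducible.
#' @param specs Group specification, default [default_group_specs()].
#' @param baseline_end_cor Within-animal BASELINE-END correlation.
#' @param full_pipeline Route tabulated E/R through the signal simulator
#'   and estimator (slower; default `FALSE`).
#' @param n_breaths_pipeline Breaths per simulated recording in
#'   full-pipeline mode.
#' @param noise_sd Pressure noise (cmH2O) in full-pipeline mode.
#' @param sampling_hz Signal sampling rate (Hz).
#' @param cv_grid Nominal CVs (%) for the tidal-volume generator stage.
#' @param n_breaths_cv Breaths per generated sequence in that stage.
#' @param stages Which stages to run, a subset of
#'   `c("vtgen", "cohort", "morphometry", "qpcr", "stats")`. `"stats"`
#'   needs the data stages it summarises.
#' @return A list of class `study_config`.
#' @export
study_config <- function(seed = 1, specs = default_group_specs(),
                         baseline_end_cor = 0.7, full_pipeline = FALSE,
                         n_breaths_pipeline = 50, noise_sd = 0.2,
                         sampling_hz = 1000,
                         cv_grid = c(0, 15, 22.5, 30), n_breaths_cv = 1200,
                         stages = c("vtgen", "cohort", "morphometry",
                                    "qpcr", "stats")) {
  stopifnot(inherits(specs, "group_specs"))
  ok <- c("vtgen", "cohort", "morphometry", "qpcr", "stats")
  if (!all(stages %in% ok)) {
    stop("unknown stage(s): ", paste(setdiff(stages, ok), collapse = ", "),
         call. = FALSE)
  }
  assert_scalar(seed, "seed")
  structure(
    list(seed = as.integer(seed), specs = specs,
         baseline_end_cor = baseline_end_cor,
         full_pipeline = isTRUE(full_pipeline),
         n_breaths_pipeline = n_breaths_pipeline, noise_sd = noise_sd,
         sampling_hz = sampling_hz, cv_grid = cv_grid,
         n_breaths_cv = n_breaths_cv, stages = stages),
    class = "study_config"
  )
}

derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 1009 + k * 9973) %% 2147483629 + 1)
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE)
  })
}

# mean/SD summary of a long cohort table, one row per variable x timepoint,
# one mean/sd column pair per group
summarize_cohort <- function(df) {
  ag <- stats::aggregate(value ~ variable + timepoint + group, data = df,
                         FUN = function(z) c(mean = mean(z),
                                             sd = stats::sd(z)))
  out <- data.frame(variable = ag$variable, timepoint = ag$timepoint,
                    group = ag$group, mean = ag$value[, "mean"],
                    sd = ag$value[, "sd"], stringsAsFactors = FALSE)
  wide <- stats::reshape(out, direction = "wide",
                         idvar = c("variable", "timepoint"),
                         timevar = "group")
  rownames(wide) <- NULL
  wide[order(wide$variable, wide$timepoint), ]
}

#' Run the full synthetic study pipeline
#'
#' Executes the selected stages — tidal-volume sequence generation over the
#' CV grid, synthetic-cohort generation (optionally routing E/R through the
#' signal simulator and estimator), airspace morphometry, delta-delta-Ct
#' expression fold changes, and the statistical battery (paired t,
#' repeated-measures ANOVA with Holm-Sidak post hoc, one-way ANOVA for
#' morphometry, Kruskal-Wallis with Dunn for expression, Spearman
#' correlations of elastance with surfactant-protein expression, and the
#' BASELINE-to-END percent-change table). Any stage failure aborts with a
#' stage-named diagnostic. A fixed seed makes the whole report bundle
#' bit-reproducible.
#'
#' @param config A [study_config()].
#' @return A list of class `study_report`: `config_summary`, `vtgen`,
#'   `cohort`, `table_cardio`, `morphometry`, `table_morpho`, `qpcr_folds`,
#'   `stats` (list of test results), `table_pct_change`.
#' @export
run_study <- function(config = study_config()) {
  stopifnot(inherits(config, "study_config"))
  st <- config$stages
  specs <- config$specs
  rep_ <- list(config_summary = list(
    seed = config$seed, stages = st, n_animals = specs$n_animals,
    full_pipeline = config$full_pipeline,
    baseline_end_cor = config$baseline_end_cor))

  if ("vtgen" %in% st) {
    rep_$vtgen <- run_stage("vtgen", {
      rows <- lapply(seq_along(config$cv_grid), function(i) {
        cv <- config$cv_grid[i]
        plan <- ventilation_plan(cv_pct = cv,
                                 n_breaths = config$n_breaths_cv,
                                 seed = derive_seed(config$seed, i))
        s <- generate_vt_sequence(plan)
        data.frame(cv_nominal = cv, realized_cv_pct = s$realized_cv_pct,
                   realized_mean_ml_kg = s$realized_mean_ml_kg,
                   n_breaths = length(s$values))
      })
      do.call(rbind, rows)
    })
  }

  if ("cohort" %in% st) {
    rep_$cohort <- run_stage("cohort", generate_cohort(
      specs, seed = derive_seed(config$seed, 101),
      baseline_end_cor = config$baseline_end_cor,
      full_pipeline = config$full_pipeline,
      n_breaths_pipeline = config$n_breaths_pipeline,
      noise_sd = config$noise_sd, sampling_hz = config$sampling_hz))
    rep_$table_cardio <- summarize_cohort(rep_$cohort)
  }

  if ("morphometry" %in% st) {
    rep_$morphometry <- run_stage("morphometry", {
      diam <- generate_morphometry_data(specs,
                                        seed = derive_seed(config$seed, 202))
      morphometry_table(diam)
    })
    mt <- rep_$morphometry
    ag <- stats::aggregate(cbind(lm, d2, beta_inv) ~ group, data = mt,
                           FUN = function(z) c(mean = mean(z),
                                               sd = stats::sd(z)))
    rep_$table_morpho <- data.frame(
      group = ag$group,
      lm_mean = ag$lm[, "mean"], lm_sd = ag$lm[, "sd"],
      d2_mean = ag$d2[, "mean"], d2_sd = ag$d2[, "sd"],
      beta_inv_mean = ag$beta_inv[, "mean"],
      beta_inv_sd = ag$beta_inv[, "sd"], stringsAsFactors = FALSE)
  }

  if ("qpcr" %in% st) {
    rep_$qpcr_folds <- run_stage("qpcr", {
      ct <- generate_ct_table(specs, seed = derive_seed(config$seed, 303))
      fold_change_table(ct)
    })
  }

  if ("stats" %in% st) {
    rep_$stats <- run_stage("stats", run_stats_battery(rep_))
    if (!is.null(rep_$cohort)) {
      rep_$table_pct_change <- percent_change_table(
        rep_$cohort,
        variables = c("E", "PAT", "PET", "PAT_PET", "RV_area", "PaO2"))
    }
  }
  structure(rep_, class = "study_report")
}

# The statistical battery over whichever data stages ran.
run_stats_battery <- function(rep_) {
  out <- list()
  if (!is.null(rep_$cohort)) {
    df <- rep_$cohort
    vars <- c("E", "R", "PaO2", "PAT", "PET", "PAT_PET", "RV_area")
    paired <- list()
    for (v in vars) {
      for (grp in unique(df$group)) {
        b <- df$value[df$variable == v & df$group == grp &
                        df$timepoint == "BASELINE"]
        e <- df$value[df$variable == v & df$group == grp &
                        df$timepoint == "END"]
        res <- tryCatch(paired_t(b, e), error = function(err) {
          list(t = NA_real_, df = length(b) - 1, p = NA_real_,
               mean_diff = mean(e - b))
        })
        paired[[length(paired) + 1L]] <- data.frame(
          variable = v, group = grp, t = res$t, df = res$df, p = res$p,
          mean_diff = res$mean_diff, stringsAsFactors = FALSE)
      }
    }
    out$paired_t <- do.call(rbind, paired)
    out$rm_anova <- lapply(stats::setNames(vars, vars), function(v) {
      rm_anova_two_way(df, dv = v)
    })
  }
  if (!is.null(rep_$morphometry)) {
    mt <- rep_$morphometry
    out$morpho_anova <- lapply(
      stats::setNames(c("lm", "d2", "beta_inv"), c("lm", "d2", "beta_inv")),
      function(v) anova_one_way(mt[[v]], mt$group))
  }
  if (!is.null(rep_$qpcr_folds)) {
    folds <- rep_$qpcr_folds
    out$kruskal_dunn <- lapply(
      stats::setNames(unique(folds$gene), unique(folds$gene)),
      function(gn) {
        sub <- folds[folds$gene == gn, ]
        kruskal_dunn(sub$fold, g = sub$group)
      })
  }
  if (!is.null(rep_$cohort) && !is.null(rep_$qpcr_folds)) {
    e_end <- rep_$cohort[rep_$cohort$variable == "E" &
                           rep_$cohort$timepoint == "END",
                         c("animal_id", "value")]
    out$spearman <- lapply(
      stats::setNames(c("SP-D", "SP-C"), c("SP-D", "SP-C")), function(gn) {
        sub <- merge(e_end,
                     rep_$qpcr_folds[rep_$qpcr_folds$gene == gn,
                                     c("animal_id", "fold")],
                     by = "animal_id")
        spearman_cor(sub$value, sub$fold)
      })
  }
  out
}

#' @export
print.study_report <- function(x, ...) {
  cat("<study_report> stages:",
      paste(x$config_summary$stages, collapse = ", "),
      sprintf("(seed %d)\n", x$config_summary$seed))
  if (!is.null(x$vtgen)) {
    cat("  realized CV by nominal CV:\n")
    print(x$vtgen, row.names = FALSE)
  }
  if (!is.null(x$table_morpho)) {
    cat("  morphometry group means:\n")
    print(x$table_morpho, row.names = FALSE, digits = 3)
  }
  invisible(x)
}

#' Write a study report bundle to disk
#'
#' CSV tables (cohort, cardiorespiratory summary, morphometry, percent
#' change, qPCR folds, realized CVs) and one JSON with every statistical
#' comparison.
#'
#' @param report A [run_study()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "study_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wcsv <- function(obj, name) {
    if (!is.null(obj)) {
      utils::write.csv(obj, file.path(dir, name), row.names = FALSE)
    }
  }
  wcsv(report$vtgen, "vt_cv_grid.csv")
  wcsv(report$cohort, "cohort.csv")
  wcsv(report$table_cardio, "table_cardiorespiratory.csv")
  wcsv(report$morphometry, "morphometry.csv")
  wcsv(report$table_morpho, "table_morphometry.csv")
  wcsv(report$qpcr_folds, "qpcr_folds.csv")
  wcsv(report$table_pct_change, "table_percent_change.csv")
  if (!is.null(report$stats)) {
    jsonlite::write_json(report$stats, file.path(dir, "comparisons.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
  }
  jsonlite::write_json(report$config_summary, file.path(dir, "config.json"),
                       auto_unbox = TRUE)
  invisible(dir)
}
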