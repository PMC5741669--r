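# Synthetic cohort generation and the end-to-end study driver.

test_that("PAT/PET ratio matches hand-divided values", {
  expect_equal(pat_pet_ratio(20.7, 65.1), 0.318, tolerance = 1e-3)
  expect_equal(pat_pet_ratio(17.3, 58.1), 0.298, tolerance = 1e-3)
  expect_equal(pat_pet_ratio(30, 30), 1)
  expect_error(pat_pet_ratio(20, 0), "PET")
  expect_error(pat_pet_ratio(-1, 50), "PAT")
})

test_that("cohort draws reproduce the specified group means across cohorts", {
  specs <- default_group_specs()
  specs$timepoint <- specs$timepoint[specs$timepoint$variable == "E", ]
  means <- vapply(1:1000, function(i) {
    co <- generate_cohort(specs, seed = i)
    mean(co$value[co$group == "VV_0" & co$variable == "E" &
                    co$timepoint == "BASELINE"])
  }, numeric(1))
  expect_lt(abs(mean(means) - 3.2) / 3.2, 0.01)
})

test_that("zero SDs give every animal exactly the group mean", {
  specs <- default_group_specs()
  specs$timepoint$sd <- 0
  co <- generate_cohort(specs, seed = 1)
  e_base <- co$value[co$group == "VV_30" & co$variable == "E" &
                       co$timepoint == "BASELINE"]
  expect_true(all(e_base == 3.0))
})

test_that("same seed gives bit-identical cohorts; negative SDs are rejected", {
  specs <- default_group_specs()
  expect_identical(generate_cohort(specs, seed = 12),
                   generate_cohort(specs, seed = 12))
  bad <- specs
  bad$timepoint$sd[1] <- -1
  expect_error(generate_cohort(bad, seed = 1), "negative SD")
})

test_that("cohort table is complete: one value per animal/timepoint/variable", {
  co <- generate_cohort(default_group_specs(), seed = 2)
  counts <- table(co$animal_id, co$timepoint, co$variable)
  expect_true(all(counts == 1))
  expect_setequal(unique(co$group), c("VV_0", "VV_15", "VV_22.5", "VV_30"))
  pats <- co[co$variable == "PAT", ]
  pets <- co[co$variable == "PET", ]
  ratio <- co[co$variable == "PAT_PET", ]
  m <- merge(merge(pats, pets, by = c("animal_id", "timepoint")),
             ratio, by = c("animal_id", "timepoint"))
  expect_equal(m$value.x / m$value.y, m$value, tolerance = 1e-12)
})

test_that("morphometry generator tracks the group anchors", {
  # Lm near 70 and homogeneity near 0.85 for the intermediate-CV group;
  # averaged over animals and a few cohorts to tame 7-animal noise
  mts <- lapply(1:5, function(i) {
    morphometry_table(generate_morphometry_data(default_group_specs(),
                                                seed = 400 + i))
  })
  mt <- do.call(rbind, mts)
  g <- mt[mt$group == "VV_22.5", ]
  expect_lt(abs(mean(g$lm) - 70), 4)
  expect_lt(abs(mean(g$beta_inv) - 0.85), 0.04)
  expect_lt(abs(mean(g$d2) - 82), 9)
  nv <- mt[mt$group == "NV", ]
  expect_lt(abs(mean(nv$beta_inv) - 0.66), 0.08)
})

test_that("full-pipeline mode recovers the direction of elastance change", {
  # with E falling from BASELINE to END (high-variability groups), the
  # estimated group trajectory must reproduce the sign of the change
  specs <- default_group_specs()
  specs$timepoint <- specs$timepoint[specs$timepoint$variable %in%
                                       c("E", "R", "PAT", "PET"), ]
  hits <- vapply(1:8, function(i) {
    co <- generate_cohort(specs, seed = 500 + i, full_pipeline = TRUE,
                          n_breaths_pipeline = 15)
    e <- co[co$variable == "E" & co$group == "VV_30", ]
    mean(e$value[e$timepoint == "END"]) <
      mean(e$value[e$timepoint == "BASELINE"])
  }, logical(1))
  expect_gte(mean(hits), 7 / 8)
})

test_that("run_study orders realized CVs along the nominal grid", {
  rep_ <- run_study(study_config(seed = 6, stages = "vtgen"))
  cvs <- rep_$vtgen$realized_cv_pct
  expect_equal(rep_$vtgen$cv_nominal, c(0, 15, 22.5, 30))
  expect_true(all(diff(cvs) > 0))
  expect_equal(cvs[1], 0)
  expect_lt(abs(cvs[3] - 22.5), 2)
})

test_that("fixed-seed run_study is bit-identical and schema-stable", {
  cfg <- study_config(seed = 9)
  r1 <- run_study(cfg)
  r2 <- run_study(cfg)
  expect_identical(r1, r2)
  expect_named(
    r1,
    c("config_summary", "vtgen", "cohort", "table_cardio", "morphometry",
      "table_morpho", "qpcr_folds", "stats", "table_pct_change"))
  expect_identical(names(r1$cohort),
                   c("animal_id", "group", "timepoint", "variable", "value"))
  expect_identical(
    names(r1$table_pct_change),
    c("variable", "group", "mean_pct_change", "sd_pct_change"))
  expect_setequal(unique(r1$table_pct_change$variable),
                  c("E", "PAT", "PET", "PAT_PET", "RV_area", "PaO2"))
})

test_that("stage gating restricts the report and bad stages abort by name", {
  r <- run_study(study_config(seed = 3, stages = c("morphometry", "qpcr")))
  expect_null(r$cohort)
  expect_null(r$vtgen)
  expect_false(is.null(r$table_morpho))
  expect_error(study_config(stages = "echo"), "unknown stage")
})

test_that("write_report emits the expected files", {
  dir <- withr::local_tempdir()
  r <- run_study(study_config(seed = 4))
  write_report(r, dir)
  expect_true(all(file.exists(file.path(dir, c(
    "vt_cv_grid.csv", "cohort.csv", "table_cardiorespiratory.csv",
    "morphometry.csv", "table_morphometry.csv", "qpcr_folds.csv",
    "table_percent_change.csv", "comparisons.json", "config.json")))))
  folds <- utils::read.csv(file.path(dir, "qpcr_folds.csv"))
  expect_identical(names(folds), c("animal_id", "group", "gene", "delta_ct",
                                   "delta_delta_ct", "fold"))
})
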