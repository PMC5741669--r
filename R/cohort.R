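#' PAT/PET ratio
#'
#' Pulmonary artery flow acceleration time over ejection time, the
#' echocardiographic index of pulmonary arterial pressure (lower values
#' indicate higher pressure).
#'
#' @param pat Pulmonary acceleration time (ms, > 0).
#' @param pet Pulmonary ejection time (ms, > 0).
#' @return Dimensionless PAT/PET.
#' @examples
#' pat_pet_ratio(20.7, 65.1)
#' @export
pat_pet_ratio <- function(pat, pet) {
  if (any(!is.finite(pet)) || any(pet <= 0)) {
    stop("PET must be > 0", call. = FALSE)
  }
  if (any(!is.finite(pat)) || any(pat <= 0)) {
    stop("PAT must be > 0", call. = FALSE)
  }
  pat / pet
}

# Correlated BASELINE/END pairs, truncated at lb by rejection. sd = 0 gives
# the mean exactly.
draw_paired <- function(n, m1, s1, m2, s2, rho, lb = 0) {
  b <- numeric(n); e <- numeric(n)
  for (i in seq_len(n)) {
    repeat {
      z1 <- stats::rnorm(1)
      z2 <- rho * z1 + sqrt(1 - rho^2) * stats::rnorm(1)
      bi <- m1 + s1 * z1
      ei <- m2 + s2 * z2
      if ((bi > lb || s1 == 0) && (ei > lb || s2 == 0)) break
    }
    b[i] <- if (s1 == 0) m1 else bi
    e[i] <- if (s2 == 0) m2 else ei
  }
  list(baseline = b, end = e)
}

#' Generate a synthetic cohort table
#'
#' Draws per-animal values for every (variable, timepoint) cell of the
#' ventilated groups from Gaussians with the group means and SDs of the
#' specification, with a configurable within-animal BASELINE-END
#' correlation (default 0.7) and truncation at zero for these
#' positive-valued physiological quantities. A derived `PAT_PET` variable
#' is added per animal and timepoint. Non-ventilated (NV) animals carry no
#' ventilation or echo variables; they enter only morphometry and qPCR.
#'
#' With `full_pipeline = TRUE`, each ventilated animal's tabulated E and R
#' become the ground truth of a signal simulation: a tidal-volume sequence
#' is generated (CV 0 at BASELINE, the group CV at END), pressure is
#' simulated under the equation of motion with additive noise, and the
#' tabulated E and R are replaced by the least-squares estimates.
#'
#' @param specs A [default_group_specs()] object.
#' @param seed Integer seed; the whole table is reproducible from it.
#' @param baseline_end_cor Within-animal correlation between BASELINE and
#'   END draws (default 0.7).
#' @param full_pipeline Replace tabulated E/R with estimator output from
#'   simulated signals (default `FALSE`).
#' @param n_breaths_pipeline Breaths simulated per animal and timepoint in
#'   full-pipeline mode (default 50; scaled down from the 1200-breath
#'   protocol for runtime).
#' @param noise_sd Pressure noise (cmH2O) in full-pipeline mode.
#' @param sampling_hz Sampling rate in full-pipeline mode.
#' @return A long-format data frame (`animal_id`, `group`, `timepoint`,
#'   `variable`, `value`) with attribute `provenance` recording the seed.
#' @export
generate_cohort <- function(specs = default_group_specs(), seed = NULL,
                            baseline_end_cor = 0.7, full_pipeline = FALSE,
                            n_breaths_pipeline = 50, noise_sd = 0.2,
                            sampling_hz = 1000) {
  stopifnot(inherits(specs, "group_specs"))
  assert_scalar(baseline_end_cor, "baseline_end_cor", lower = -1, upper = 1)
  if (any(specs$timepoint$sd < 0)) {
    stop("negative SD requested in group specification", call. = FALSE)
  }
  n <- specs$n_animals
  tp <- specs$timepoint
  with_seed(seed, {
    rows <- list()
    for (grp in specs$vent_groups) {
      ids <- sprintf("%s_%d", grp, seq_len(n))
      for (v in unique(tp$variable)) {
        cell_b <- tp[tp$variable == v & tp$group == grp &
                       tp$timepoint == "BASELINE", ]
        cell_e <- tp[tp$variable == v & tp$group == grp &
                       tp$timepoint == "END", ]
        d <- draw_paired(n, cell_b$mean, cell_b$sd, cell_e$mean, cell_e$sd,
                         baseline_end_cor)
        rows[[length(rows) + 1L]] <- data.frame(
          animal_id = rep(ids, 2L), group = grp,
          timepoint = rep(c("BASELINE", "END"), each = n),
          variable = v, value = c(d$baseline, d$end),
          stringsAsFactors = FALSE)
      }
    }
    df <- do.call(rbind, rows)

    # derived PAT/PET per animal and timepoint (when both were drawn)
    if (all(c("PAT", "PET") %in% tp$variable)) {
      pat <- df[df$variable == "PAT", ]
      pet <- df[df$variable == "PET", ]
      m <- merge(pat, pet, by = c("animal_id", "group", "timepoint"),
                 suffixes = c("_pat", "_pet"))
      df <- rbind(df, data.frame(
        animal_id = m$animal_id, group = m$group, timepoint = m$timepoint,
        variable = "PAT_PET",
        value = pat_pet_ratio(m$value_pat, m$value_pet),
        stringsAsFactors = FALSE))
    }

    if (full_pipeline) {
      df <- replace_mechanics_with_estimates(
        df, specs, n_breaths_pipeline, noise_sd, sampling_hz)
    }
    df <- df[order(df$variable, df$group, df$timepoint, df$animal_id), ]
    rownames(df) <- NULL
    attr(df, "provenance") <- list(source = "synthetic", seed = seed)
    df
  })
}

# Full-pipeline mode: per ventilated animal and timepoint, simulate signals
# under the animal's true (E, R) and replace the tabulated E/R values with
# equation-of-motion least-squares estimates.
replace_mechanics_with_estimates <- function(df, specs, n_breaths, noise_sd,
                                             sampling_hz) {
  cv_of <- function(grp) switch(grp, VV_0 = 0, VV_15 = 15,
                                `VV_22.5` = 22.5, VV_30 = 30)
  for (grp in specs$vent_groups) {
    ids <- unique(df$animal_id[df$group == grp])
    for (id in ids) {
      for (tpt in c("BASELINE", "END")) {
        sel_e <- df$variable == "E" & df$animal_id == id & df$timepoint == tpt
        sel_r <- df$variable == "R" & df$animal_id == id & df$timepoint == tpt
        e_true <- df$value[sel_e]
        r_true <- df$value[sel_r]
        cv <- if (tpt == "BASELINE") 0 else cv_of(grp)
        plan <- ventilation_plan(cv_pct = cv, n_breaths = n_breaths)
        vts <- generate_vt_sequence(plan)
        model <- lung_model(E = e_true, R = r_true, p0 = plan$peep,
                            noise_sd = noise_sd)
        sig <- simulate_breaths(vts, model, plan, sampling_hz = sampling_hz)
        fit <- fit_equation_of_motion(sig)
        df$value[sel_e] <- fit$E_hat
        df$value[sel_r] <- fit$R_hat
      }
    }
  }
  df
}

#' Generate synthetic airspace-diameter data for a cohort
#'
#' Each animal's mean diameter is drawn from the group's Lm distribution
#' (Gaussian, truncated positive); its 20 within-animal diameters come from
#' a pure gamma with coefficient of variation solved in closed form from
#' the group homogeneity index (`1/beta = 1 / (1 + 2 cv^2)` in expectation
#' for the gamma family).
#'
#' @param specs A [default_group_specs()].
#' @param seed Integer seed.
#' @param n_diameters Diameters per animal (default 20).
#' @return Long data frame `animal_id`, `group`, `diameter_um`.
#' @export
generate_morphometry_data <- function(specs = default_group_specs(),
                                      seed = NULL, n_diameters = 20) {
  stopifnot(inherits(specs, "group_specs"))
  md <- specs$morphometry
  n <- specs$n_animals
  with_seed(seed, {
    rows <- list()
    for (k in seq_len(nrow(md))) {
      grp <- md$group[k]
      cv <- sqrt((1 / md$beta_inv[k] - 1) / 2)
      for (i in seq_len(n)) {
        repeat {
          mu_i <- stats::rnorm(1, md$lm_mean[k], md$lm_sd[k])
          if (mu_i > 0) break
        }
        s <- generate_airspace_sample(mu_i, cv, n = n_diameters,
                                      family = "gamma")
        rows[[length(rows) + 1L]] <- data.frame(
          animal_id = sprintf("%s_%d", grp, i), group = grp,
          diameter_um = s$diameters, stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, rows)
  })
}

#' Generate a synthetic qPCR Ct table for a cohort
#'
#' Housekeeping (36B4) Ct per animal is Gaussian; each target gene's
#' delta-Ct adds the group's delta-delta-Ct shift (NV = 0) plus
#' animal-level noise, and wells add replicate noise. Triplicates by
#' default.
#'
#' @param specs A [default_group_specs()].
#' @param seed Integer seed.
#' @return Long data frame `animal_id`, `group`, `gene`, `well`, `ct`.
#' @export
generate_ct_table <- function(specs = default_group_specs(), seed = NULL) {
  stopifnot(inherits(specs, "group_specs"))
  q <- specs$qpcr
  n <- specs$n_animals
  with_seed(seed, {
    rows <- list()
    for (grp in specs$groups) {
      for (i in seq_len(n)) {
        id <- sprintf("%s_%d", grp, i)
        ref_ct <- stats::rnorm(1, q$ref_ct_mean, q$ref_ct_sd)
        rows[[length(rows) + 1L]] <- data.frame(
          animal_id = id, group = grp, gene = q$reference_gene,
          well = seq_len(q$n_replicates),
          ct = ref_ct + stats::rnorm(q$n_replicates, 0, q$replicate_sd),
          stringsAsFactors = FALSE)
        for (gene in q$genes) {
          shift <- if (grp == "NV") 0 else q$ddct_shift[gene, grp]
          dct <- q$base_delta_ct + shift + stats::rnorm(1, 0, q$animal_sd)
          rows[[length(rows) + 1L]] <- data.frame(
            animal_id = id, group = grp, gene = gene,
            well = seq_len(q$n_replicates),
            ct = ref_ct + dct + stats::rnorm(q$n_replicates, 0,
                                             q$replicate_sd),
            stringsAsFactors = FALSE)
        }
      }
    }
    do.call(rbind, rows)
  })
}
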