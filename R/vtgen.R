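#' Describe a variable-ventilation plan
#'
#' A ventilation plan captures the ventilator settings of a
#' volume-controlled, variable tidal-volume (VV) protocol: the nominal mean
#' tidal volume per body mass, the coefficient of variation (CV) of the
#' breath-to-breath Gaussian tidal-volume distribution, and the timing
#' parameters needed to build flow waveforms.
#'
#' Defaults follow a small-animal emphysema protocol: mean V_T 6 mL/kg,
#' PEEP 3 cmH2O, 1200 breaths, body mass 0.437 kg, and a respiratory rate
#' of 57 breaths/min chosen so that minute ventilation is close to
#' 150 mL/min at the default mass.
#'
#' @param mean_vt Nominal mean tidal volume (mL/kg body mass), > 0.
#' @param cv_pct Coefficient of variation of tidal volume, in percent
#'   (>= 0). The study grid is 0, 15, 22.5 and 30.
#' @param n_breaths Number of breaths in the generated sequence (>= 1).
#' @param body_mass Body mass in kg used to convert mL/kg to absolute mL.
#' @param peep Positive end-expiratory pressure (cmH2O, >= 0).
#' @param resp_rate Respiratory rate (breaths/min, > 0).
#' @param ie_ratio Inspiratory-to-expiratory time ratio I/E (> 0); 0.5
#'   encodes the conventional 1:2.
#' @param seed Optional integer seed; the same plan and seed always produce
#'   the same tidal-volume sequence.
#' @param truncation_sd Number of SDs at which Gaussian draws are clipped
#'   (default 3; use `Inf` to disable clipping).
#' @param vt_floor_frac Strictly positive floor for generated volumes,
#'   expressed as a fraction of the mean (default 0.1).
#' @return An object of class `ventilation_plan`.
#' @export
ventilation_plan <- function(mean_vt = 6, cv_pct = 22.5, n_breaths = 1200,
                             body_mass = 0.437, peep = 3, resp_rate = 57,
                             ie_ratio = 0.5, seed = NULL, truncation_sd = 3,
                             vt_floor_frac = 0.1) {
  assert_scalar(mean_vt, "mean_vt", lower = 0, strict_lower = TRUE)
  assert_scalar(cv_pct, "cv_pct", lower = 0)
  assert_scalar(n_breaths, "n_breaths", lower = 1)
  assert_scalar(body_mass, "body_mass", lower = 0, strict_lower = TRUE)
  assert_scalar(peep, "peep", lower = 0)
  assert_scalar(resp_rate, "resp_rate", lower = 0, strict_lower = TRUE)
  assert_scalar(ie_ratio, "ie_ratio", lower = 0, strict_lower = TRUE)
  assert_scalar(truncation_sd, "truncation_sd", lower = 0,
                strict_lower = TRUE, allow_inf = TRUE)
  assert_scalar(vt_floor_frac, "vt_floor_frac", lower = 0, upper = 1)
  structure(
    list(mean_vt = mean_vt, cv_pct = cv_pct,
         n_breaths = as.integer(n_breaths), body_mass = body_mass,
         peep = peep, resp_rate = resp_rate, ie_ratio = ie_ratio,
         seed = seed, truncation_sd = truncation_sd,
         vt_floor_frac = vt_floor_frac),
    class = "ventilation_plan"
  )
}

#' @export
print.ventilation_plan <- function(x, ...) {
  cat(sprintf(
    "<ventilation_plan> mean V_T %.3g mL/kg, CV %.4g%%, %d breaths, mass %.3g kg, PEEP %.3g cmH2O, RR %.3g/min, I:E %.3g\n",
    x$mean_vt, x$cv_pct, x$n_breaths, x$body_mass, x$peep, x$resp_rate,
    x$ie_ratio))
  invisible(x)
}

#' Generate a breath-to-breath Gaussian tidal-volume sequence
#'
#' Draws `n_breaths` tidal volumes from a Gaussian with mean
#' `mean_vt * body_mass` (mL) and SD `mean * cv_pct / 100`, clips at
#' `mean +/- truncation_sd * SD`, and floors values at
#' `vt_floor_frac * mean` so every delivered volume is strictly positive.
#' With `cv_pct = 0` every value equals the mean exactly.
#'
#' If the positivity floor censors more than 1% of draws the result carries
#' a warning flag (`floor_warning`) rather than failing: the sequence is
#' still deliverable, but its distribution is visibly distorted.
#'
#' @param plan A [ventilation_plan()].
#' @return An object of class `vt_sequence` with elements `values` (mL),
#'   `realized_mean` (mL), `realized_mean_ml_kg`, `realized_cv_pct`
#'   (100 * sample SD / sample mean), `seed_used`, `n_clipped`,
#'   `n_floored`, and `floor_warning`.
#' @examples
#' seq <- generate_vt_sequence(ventilation_plan(cv_pct = 22.5, seed = 1))
#' seq$realized_cv_pct
#' @export
generate_vt_sequence <- function(plan) {
  stopifnot(inherits(plan, "ventilation_plan"))
  mu <- plan$mean_vt * plan$body_mass
  n <- plan$n_breaths
  if (plan$cv_pct == 0) {
    values <- rep(mu, n)
    n_clipped <- n_floored <- 0L
  } else {
    sd <- mu * plan$cv_pct / 100
    values <- with_seed(plan$seed, stats::rnorm(n, mu, sd))
    if (is.finite(plan$truncation_sd)) {
      lo <- mu - plan$truncation_sd * sd
      hi <- mu + plan$truncation_sd * sd
      n_clipped <- sum(values < lo | values > hi)
      values <- pmin(pmax(values, lo), hi)
    } else {
      n_clipped <- 0L
    }
    floor <- plan$vt_floor_frac * mu
    n_floored <- sum(values < floor)
    values <- pmax(values, floor)
  }
  realized_mean <- mean(values)
  realized_cv <- if (n > 1L) 100 * stats::sd(values) / realized_mean else 0
  structure(
    list(values = values,
         realized_mean = realized_mean,
         realized_mean_ml_kg = realized_mean / plan$body_mass,
         realized_cv_pct = realized_cv,
         seed_used = plan$seed,
         n_clipped = as.integer(n_clipped),
         n_floored = as.integer(n_floored),
         floor_warning = n_floored > 0.01 * n),
    class = "vt_sequence"
  )
}

#' @export
print.vt_sequence <- function(x, ...) {
  cat(sprintf(
    "<vt_sequence> %d breaths, mean %.4g mL (%.4g mL/kg-equivalent given plan), CV %.3f%%%s\n",
    length(x$values), x$realized_mean, x$realized_mean_ml_kg,
    x$realized_cv_pct,
    if (isTRUE(x$floor_warning)) " [floor censored > 1% of draws]" else ""))
  invisible(x)
}

#' Write a tidal-volume sequence to CSV
#'
#' Single column `vt_ml` with `#`-prefixed metadata comment lines
#' (seed, realized CV).
#'
#' @param x A `vt_sequence`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_vt_sequence <- function(x, path) {
  stopifnot(inherits(x, "vt_sequence"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# seed: %s", if (is.null(x$seed_used)) "NA" else x$seed_used),
    sprintf("# realized_cv_pct: %.6f", x$realized_cv_pct),
    "vt_ml"), con)
  writeLines(format(x$values, digits = 10, trim = TRUE, scientific = FALSE),
             con)
  invisible(path)
}

#' Read a tidal-volume sequence written by [write_vt_sequence()]
#'
#' @param path CSV path.
#' @return Numeric vector of tidal volumes (mL).
#' @export
read_vt_sequence <- function(path) {
  df <- utils::read.csv(path, comment.char = "#")
  df$vt_ml
}

#' Build a volume-controlled breath waveform
#'
#' Constructs one breath of flow and volume on a uniform sampling grid:
#' constant inspiratory flow (with a short linear rise, `rise_frac` of the
#' inspiratory time, so the flow regressor is not degenerate within
#' inspiration), an optional end-inspiratory pause, and a passive
#' expiration modelled either as an exponential decay or a linear return.
#' Flow samples are normalised so that the trapezoid-integrated volume
#' peaks at exactly `vt` and returns to 0 at end-expiration to within 0.1%
#' of `vt`.
#'
#' @param vt Tidal volume for this breath (mL, > 0).
#' @param plan A [ventilation_plan()] supplying rate and I:E ratio.
#' @param sampling_hz Sampling frequency (Hz, default 1000).
#' @param expiration `"exponential"` (default) or `"linear"` expiratory
#'   flow profile.
#' @param tau Expiratory time constant in seconds for the exponential
#'   profile; default `t_exp / 8`, which leaves a residual volume
#'   `vt * exp(-8)` (< 0.04% of vt).
#' @param rise_frac Fraction of inspiratory time spent ramping flow from 0
#'   to its plateau (default 0.05).
#' @param pause_s End-inspiratory pause (s, default 0).
#' @return A `breath_signal` with `time` (s), `flow` (mL/s, inspiration
#'   positive), `volume` (mL, 0 at start), `paw = NULL` (no pressure until
#'   simulated), `breath_boundaries = 1L` and `sampling_hz`.
#' @export
build_breath_waveform <- function(vt, plan, sampling_hz = 1000,
                                  expiration = c("exponential", "linear"),
                                  tau = NULL, rise_frac = 0.05, pause_s = 0) {
  stopifnot(inherits(plan, "ventilation_plan"))
  assert_scalar(vt, "vt", lower = 0, strict_lower = TRUE)
  assert_scalar(sampling_hz, "sampling_hz", lower = 0, strict_lower = TRUE)
  expiration <- match.arg(expiration)
  period <- 60 / plan$resp_rate
  n <- floor(period * sampling_hz)
  if (n < 2L) stop("breath period shorter than 2 samples", call. = FALSE)
  t_insp <- period * plan$ie_ratio / (1 + plan$ie_ratio)
  t_exp <- period - t_insp - pause_s
  if (t_exp <= 0) stop("pause leaves no expiratory time", call. = FALSE)
  tm <- (seq_len(n) - 1L) / sampling_hz
  flow <- numeric(n)
  t_rise <- rise_frac * t_insp

  insp <- tm < t_insp
  if (t_rise > 0) {
    ramp <- insp & tm < t_rise
    flow[ramp] <- tm[ramp] / t_rise
  }
  flow[insp & tm >= t_rise] <- 1
  # trapezoid volume at the last inspiratory sample depends only on
  # inspiratory flow samples; scale so it equals vt exactly
  k_star <- max(which(insp))
  vi <- cumtrapz(tm, flow)[k_star]
  flow[insp] <- flow[insp] * vt / vi

  exp_start <- t_insp + pause_s
  is_exp <- tm >= exp_start
  if (expiration == "exponential") {
    if (is.null(tau)) tau <- t_exp / 8
    assert_scalar(tau, "tau", lower = 0, strict_lower = TRUE)
    shape <- -exp(-(tm[is_exp] - exp_start) / tau)
    residual <- vt * exp(-t_exp / tau)
  } else {
    shape <- rep(-1, sum(is_exp))
    residual <- 0
  }
  # total integral is linear in the expiratory scale: solve it exactly so
  # end-expiratory volume equals the analytic residual
  tmp <- numeric(n)
  tmp[is_exp] <- shape
  t_exp_raw <- trapz(tm, tmp)
  t_insp_total <- trapz(tm, replace(flow, is_exp, 0))
  flow[is_exp] <- shape * (residual - t_insp_total) / t_exp_raw
  volume <- cumtrapz(tm, flow)
  structure(
    list(time = tm, paw = NULL, flow = flow, volume = volume,
         breath_boundaries = 1L, sampling_hz = sampling_hz),
    class = "breath_signal"
  )
}

#' @export
print.breath_signal <- function(x, ...) {
  cat(sprintf(
    "<breath_signal> %d samples at %g Hz, %d breath(s)%s\n",
    length(x$time), x$sampling_hz, length(x$breath_boundaries),
    if (is.null(x$paw)) " (no pressure channel)" else ""))
  invisible(x)
}
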