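#' Define a linear lung model
#'
#' Single-compartment linear respiratory mechanics: airway pressure obeys
#' the equation of motion `Paw(t) = E * V(t) + R * V'(t) + P0`. An optional
#' second parallel compartment `(E2, R2)` introduces time-constant
#' inhomogeneity (as seen in obstructive disease) and is used only to probe
#' estimator robustness; the estimator itself always fits the
#' single-compartment form.
#'
#' @param E Elastance of (the first) compartment, cmH2O/mL, > 0.
#' @param R Resistance of (the first) compartment, cmH2O/mL/s, > 0.
#' @param p0 End-expiratory pressure offset (cmH2O); equals total PEEP.
#' @param E2,R2 Optional second-compartment elastance and resistance. Both
#'   or neither must be supplied.
#' @param noise_sd SD of additive Gaussian pressure noise (cmH2O, >= 0).
#' @param seed Optional integer seed for the noise stream.
#' @return An object of class `lung_model`. For a two-compartment model the
#'   steady-state volume fractions (`frac1`, `frac2`, summing to 1) are
#'   derived from the elastances: compartment volumes split inversely to E.
#' @export
lung_model <- function(E = 3.2, R = 0.21, p0 = 3, E2 = NULL, R2 = NULL,
                       noise_sd = 0, seed = NULL) {
  assert_scalar(E, "E", lower = 0, strict_lower = TRUE)
  assert_scalar(R, "R", lower = 0, strict_lower = TRUE)
  assert_scalar(p0, "p0")
  assert_scalar(noise_sd, "noise_sd", lower = 0)
  two <- !is.null(E2) || !is.null(R2)
  if (two) {
    if (is.null(E2) || is.null(R2)) {
      stop("both `E2` and `R2` are required for a two-compartment model",
           call. = FALSE)
    }
    assert_scalar(E2, "E2", lower = 0, strict_lower = TRUE)
    assert_scalar(R2, "R2", lower = 0, strict_lower = TRUE)
  }
  frac2 <- if (two) E / (E + E2) else 0
  structure(
    list(E = E, R = R, p0 = p0, E2 = E2, R2 = R2,
         two_compartment = two, frac1 = 1 - frac2, frac2 = frac2,
         noise_sd = noise_sd, seed = seed),
    class = "lung_model"
  )
}

#' @export
print.lung_model <- function(x, ...) {
  cat(sprintf("<lung_model> E %.3g cmH2O/mL, R %.3g cmH2O/mL/s, P0 %.3g%s%s\n",
              x$E, x$R, x$p0,
              if (x$two_compartment)
                sprintf(", 2nd compartment E2 %.3g R2 %.3g", x$E2, x$R2)
              else "",
              if (x$noise_sd > 0)
                sprintf(", noise SD %.3g cmH2O", x$noise_sd) else ""))
  invisible(x)
}

#' Forward-simulate pressure/flow/volume signals for a tidal-volume sequence
#'
#' Builds one volume-controlled breath per tidal volume (constant
#' inspiratory flow with a short rise, optional end-inspiratory pause) and
#' computes airway pressure from the equation of motion. Expiration is
#' passive: for the single-compartment model volume decays with time
#' constant `tau = R/E` and airway pressure sits at `p0` (the resistive
#' drop exactly cancels the elastic recoil at the airway opening). The
#' two-compartment variant integrates each compartment's first-order
#' dynamics (shared airway node) with fourth-order Runge-Kutta steps and
#' sums the compartment flows; during an end-inspiratory pause gas
#' redistributes between compartments (pendelluft) so the measured pressure
#' relaxes from its peak toward a plateau.
#'
#' @param vt_seq A [generate_vt_sequence()] result, or a bare numeric
#'   vector of tidal volumes in mL.
#' @param model A [lung_model()].
#' @param plan A [ventilation_plan()] for breath timing and PEEP.
#' @param sampling_hz Sampling frequency, default 1000 Hz.
#' @param pause_s End-inspiratory pause per breath (s), default 0.
#' @param rise_frac Inspiratory flow rise fraction, as in
#'   [build_breath_waveform()].
#' @param quantize_bits Optional ADC emulation: number of bits used to
#'   quantize `paw` over `quantize_range`. `NULL` (default) disables it.
#' @param quantize_range Pressure range (cmH2O) mapped onto the ADC.
#' @return A `breath_signal` with `time`, `paw`, `flow`, `volume`,
#'   `breath_boundaries` (1-based start index of each breath) and
#'   `sampling_hz`. Volume is referenced to end-expiration (0 at each
#'   breath start).
#' @export
simulate_breaths <- function(vt_seq, model, plan, sampling_hz = 1000,
                             pause_s = 0, rise_frac = 0.05,
                             quantize_bits = NULL,
                             quantize_range = c(-10, 60)) {
  stopifnot(inherits(model, "lung_model"), inherits(plan, "ventilation_plan"))
  vts <- if (inherits(vt_seq, "vt_sequence")) vt_seq$values else as.numeric(vt_seq)
  if (length(vts) == 0L) stop("empty tidal-volume sequence", call. = FALSE)
  if (any(vts <= 0)) stop("tidal volumes must be > 0", call. = FALSE)

  period <- 60 / plan$resp_rate
  t_insp <- period * plan$ie_ratio / (1 + plan$ie_ratio)
  t_exp <- period - t_insp - pause_s
  if (t_exp <= 0) stop("pause leaves no expiratory time", call. = FALSE)

  one_breath <- function(vt) {
    if (model$two_compartment) {
      sim_breath_two_comp(vt, model, plan, sampling_hz, pause_s, rise_frac)
    } else {
      tau <- model$R / model$E
      w <- build_breath_waveform(vt, plan, sampling_hz,
                                 expiration = "exponential", tau = tau,
                                 rise_frac = rise_frac, pause_s = pause_s)
      paw <- model$E * w$volume + model$R * w$flow + model$p0
      list(flow = w$flow, volume = w$volume, paw = paw, n = length(w$flow))
    }
  }

  breaths <- lapply(vts, one_breath)
  ns <- vapply(breaths, function(b) as.integer(b$n), integer(1))
  flow <- unlist(lapply(breaths, `[[`, "flow"), use.names = FALSE)
  volume <- unlist(lapply(breaths, `[[`, "volume"), use.names = FALSE)
  paw <- unlist(lapply(breaths, `[[`, "paw"), use.names = FALSE)
  if (model$noise_sd > 0) {
    paw <- paw + with_seed(model$seed,
                           stats::rnorm(length(paw), 0, model$noise_sd))
  }
  if (!is.null(quantize_bits)) {
    lo <- quantize_range[1]; hi <- quantize_range[2]
    step <- (hi - lo) / (2^quantize_bits - 1)
    paw <- lo + step * round((pmin(pmax(paw, lo), hi) - lo) / step)
  }
  n_tot <- sum(ns)
  structure(
    list(time = (seq_len(n_tot) - 1L) / sampling_hz,
         paw = paw, flow = flow, volume = volume,
         breath_boundaries = as.integer(cumsum(c(1L, ns[-length(ns)]))),
         sampling_hz = sampling_hz),
    class = "breath_signal"
  )
}

# One breath of the two-parallel-compartment model. Inspiration and pause
# are integrated with RK4 on the sampling grid (sub-stepped x4); passive
# expiration is the exact two-exponential decay.
sim_breath_two_comp <- function(vt, model, plan, sampling_hz, pause_s,
                                rise_frac) {
  E1 <- model$E; R1 <- model$R; E2 <- model$E2; R2 <- model$R2
  period <- 60 / plan$resp_rate
  n <- floor(period * sampling_hz)
  if (n < 2L) stop("breath period shorter than 2 samples", call. = FALSE)
  t_insp <- period * plan$ie_ratio / (1 + plan$ie_ratio)
  t_exp <- period - t_insp - pause_s
  tm <- (seq_len(n) - 1L) / sampling_hz
  t_rise <- rise_frac * t_insp
  f_plateau <- vt / (t_insp - t_rise / 2)
  total_flow_fn <- function(t) {
    ifelse(t < t_rise, f_plateau * t / t_rise,
           ifelse(t < t_insp, f_plateau, 0))
  }
  exp_start <- t_insp + pause_s

  # dV1/dt given total volume V(t) and prescribed total flow F(t)
  dv1 <- function(t, v1, v) (E2 * (v - v1) - E1 * v1 + R2 * total_flow_fn(t)) /
    (R1 + R2)

  flow <- total_flow_fn(tm)
  volume <- cumtrapz(tm, flow)
  v1 <- numeric(n)
  drive <- tm < exp_start
  idx_drive <- which(drive)
  sub <- 4L
  h <- 1 / sampling_hz / sub
  v_fn <- stats::approxfun(tm, volume, rule = 2)
  cur <- 0
  for (k in idx_drive[-1L]) {
    t0 <- tm[k - 1L]
    for (s in seq_len(sub)) {
      ts <- t0 + (s - 1L) * h
      k1 <- dv1(ts, cur, v_fn(ts))
      k2 <- dv1(ts + h / 2, cur + h / 2 * k1, v_fn(ts + h / 2))
      k3 <- dv1(ts + h / 2, cur + h / 2 * k2, v_fn(ts + h / 2))
      k4 <- dv1(ts + h, cur + h * k3, v_fn(ts + h))
      cur <- cur + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    }
    v1[k] <- cur
  }
  v1dot_drive <- dv1(tm[drive], v1[drive], volume[drive])
  paw <- numeric(n)
  paw[drive] <- E1 * v1[drive] + R1 * v1dot_drive + model$p0

  # passive expiration: each compartment decays against the airway node at
  # p0 with its own time constant; airway pressure equals p0
  is_exp <- !drive
  te <- tm[is_exp] - exp_start
  v1_0 <- v1[max(idx_drive)]
  v2_0 <- volume[max(idx_drive)] - v1_0
  tau1 <- R1 / E1; tau2 <- R2 / E2
  v1e <- v1_0 * exp(-te / tau1)
  v2e <- v2_0 * exp(-te / tau2)
  flow[is_exp] <- -v1e / tau1 - v2e / tau2
  volume[is_exp] <- v1e + v2e
  paw[is_exp] <- model$p0
  list(flow = flow, volume = volume, paw = paw, n = n)
}

#' Write a breath signal to CSV (plus sidecar JSON of breath boundaries)
#'
#' Columns `time_s, paw_cmH2O, flow_mL_s, vol_mL`. Breath start indices and
#' the sampling rate go to `<path>.breaths.json`.
#'
#' @param x A `breath_signal`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_breath_signal <- function(x, path) {
  stopifnot(inherits(x, "breath_signal"))
  df <- data.frame(time_s = x$time,
                   paw_cmH2O = if (is.null(x$paw)) NA_real_ else x$paw,
                   flow_mL_s = x$flow, vol_mL = x$volume)
  utils::write.csv(df, path, row.names = FALSE)
  jsonlite::write_json(
    list(breath_boundaries = x$breath_boundaries,
         sampling_hz = x$sampling_hz),
    paste0(path, ".breaths.json"), auto_unbox = TRUE)
  invisible(path)
}

#' Read a breath signal written by [write_breath_signal()]
#'
#' If the sidecar JSON is absent the whole record is treated as one breath.
#'
#' @param path CSV path.
#' @return A `breath_signal`.
#' @export
read_breath_signal <- function(path) {
  df <- utils::read.csv(path)
  sidecar <- paste0(path, ".breaths.json")
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    bb <- as.integer(meta$breath_boundaries)
    hz <- meta$sampling_hz
  } else {
    bb <- 1L
    hz <- 1 / stats::median(diff(df$time_s))
  }
  structure(
    list(time = df$time_s, paw = df$paw_cmH2O, flow = df$flow_mL_s,
         volume = df$vol_mL, breath_boundaries = bb, sampling_hz = hz),
    class = "breath_signal"
  )
}
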