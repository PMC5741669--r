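#' Estimate respiratory mechanics by least squares on the equation of motion
#'
#' Ordinary least squares of airway pressure on volume, flow and an
#' intercept, `Paw = E*V + R*V' + P0`, fitted per breath (default) or over
#' the whole record. Per-breath estimates are aggregated by the median
#' (default, robust to occasional corrupted breaths) or the mean. Volume is
#' re-referenced to 0 at each breath start so `P0` is interpretable as
#' total PEEP.
#'
#' @param signal A `breath_signal` containing a pressure channel.
#' @param per_breath Fit each breath separately (default `TRUE`); otherwise
#'   one global fit.
#' @param agg Aggregation across per-breath estimates: `"median"`
#'   (default) or `"mean"`.
#' @param window `"breath"` (default, all samples) or `"inspiration"`
#'   (samples with positive flow only).
#' @return An object of class `mechanics_fit` with `E_hat`, `R_hat`,
#'   `p0_hat`, a `per_breath` data frame (`breath`, `E`, `R`, `p0`,
#'   `r_squared`) and the aggregation label.
#' @examples
#' plan <- ventilation_plan(cv_pct = 0, n_breaths = 3)
#' sig <- simulate_breaths(generate_vt_sequence(plan), lung_model(3, 0.2), plan)
#' fit_equation_of_motion(sig)
#' @export
fit_equation_of_motion <- function(signal, per_breath = TRUE,
                                   agg = c("median", "mean"),
                                   window = c("breath", "inspiration")) {
  stopifnot(inherits(signal, "breath_signal"))
  if (is.null(signal$paw) || all(is.na(signal$paw))) {
    stop("signal has no pressure channel to fit", call. = FALSE)
  }
  agg <- match.arg(agg)
  window <- match.arg(window)
  bb <- signal$breath_boundaries
  n <- length(signal$paw)
  starts <- bb
  ends <- c(bb[-1L] - 1L, n)

  # reference volume to 0 at each breath start so p0 estimates total PEEP
  for (i in seq_along(starts)) {
    idx <- seq.int(starts[i], ends[i])
    signal$volume[idx] <- signal$volume[idx] - signal$volume[idx[1L]]
  }

  fit_one <- function(idx, label) {
    if (window == "inspiration") idx <- idx[signal$flow[idx] > 0]
    v <- signal$volume[idx]
    f <- signal$flow[idx]
    p <- signal$paw[idx]
    X <- cbind(V = v, Vdot = f, `(Intercept)` = 1)
    qx <- qr(X)
    if (qx$rank < 3L) {
      stop(sprintf("degenerate fit in breath %s: regressor matrix is rank-deficient (constant flow and volume colinear over the fit window?)",
                   label), call. = FALSE)
    }
    beta <- qr.coef(qx, p)
    res <- p - X %*% beta
    tss <- sum((p - mean(p))^2)
    r2 <- if (tss > 0) 1 - sum(res^2) / tss else 1
    c(E = beta[[1L]], R = beta[[2L]], p0 = beta[[3L]],
      r_squared = max(0, min(1, r2)))
  }

  if (per_breath) {
    per <- t(vapply(seq_along(starts), function(i) {
      fit_one(seq.int(starts[i], ends[i]), as.character(i))
    }, numeric(4)))
    per <- data.frame(breath = seq_along(starts), per)
    aggfun <- if (agg == "median") stats::median else mean
    out <- list(E_hat = aggfun(per$E), R_hat = aggfun(per$R),
                p0_hat = aggfun(per$p0), per_breath = per,
                aggregation = agg)
  } else {
    est <- fit_one(seq_len(n), "global")
    out <- list(E_hat = est[["E"]], R_hat = est[["R"]],
                p0_hat = est[["p0"]],
                per_breath = data.frame(breath = NA_integer_, E = est[["E"]],
                                        R = est[["R"]], p0 = est[["p0"]],
                                        r_squared = est[["r_squared"]]),
                aggregation = "global")
  }
  structure(out, class = "mechanics_fit")
}

#' @export
print.mechanics_fit <- function(x, ...) {
  cat(sprintf(
    "<mechanics_fit> E %.4g cmH2O/mL, R %.4g cmH2O/mL/s, P0 %.4g cmH2O (%s over %d breath fits, median R^2 %.4f)\n",
    x$E_hat, x$R_hat, x$p0_hat, x$aggregation, nrow(x$per_breath),
    stats::median(x$per_breath$r_squared)))
  invisible(x)
}
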