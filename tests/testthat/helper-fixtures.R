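# Shared fixtures: everything is generated in code at test time.

quick_plan <- function(cv = 0, n = 3, seed = NULL, ...) {
  ventilation_plan(cv_pct = cv, n_breaths = n, seed = seed, ...)
}

# A balanced long-format null cohort: `ng` groups x `n` subjects x 2
# timepoints of pure noise (split-plot null for type-I checks).
null_rm_data <- function(n = 7, ng = 4) {
  df <- expand.grid(animal_id = paste0("a", seq_len(n * ng)),
                    timepoint = c("BASELINE", "END"),
                    stringsAsFactors = FALSE)
  df$group <- rep(rep(paste0("g", seq_len(ng)), each = n), 2L)
  df$y <- stats::rnorm(nrow(df))
  df
}

# Hand-built breath_signal (bypasses the simulator) for degenerate cases.
manual_signal <- function(time, paw, flow, volume, bb = 1L, hz = NULL) {
  if (is.null(hz)) hz <- 1 / stats::median(diff(time))
  structure(list(time = time, paw = paw, flow = flow, volume = volume,
                 breath_boundaries = as.integer(bb), sampling_hz = hz),
            class = "breath_signal")
}
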