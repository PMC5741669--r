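#' A qPCR cycle-threshold record
#'
#' One animal x gene combination with its replicate Ct values (the protocol
#' runs triplicates). Ct must lie in (0, 45).
#'
#' @param animal_id Animal identifier.
#' @param group Group label.
#' @param gene Gene name (e.g. `"IL-6"`, `"SP-D"`, reference `"36B4"`).
#' @param ct_values Numeric vector of replicate Ct values (cycles).
#' @return An object of class `ct_record`.
#' @export
ct_record <- function(animal_id, group, gene, ct_values) {
  ct_values <- as.numeric(ct_values)
  if (length(ct_values) == 0L) stop("ct_values must be non-empty", call. = FALSE)
  if (any(!is.finite(ct_values)) || any(ct_values <= 0) ||
      any(ct_values >= 45)) {
    stop("all Ct values must lie in (0, 45) cycles", call. = FALSE)
  }
  structure(list(animal_id = animal_id, group = group, gene = gene,
                 ct_values = ct_values),
            class = "ct_record")
}

# Mean Ct after optional outlier rejection: replicates more than
# `tol` cycles from the replicate median are dropped (never all of them).
aggregate_ct <- function(ct_values, outlier_reject = FALSE, tol = 0.5) {
  if (outlier_reject && length(ct_values) > 1L) {
    keep <- abs(ct_values - stats::median(ct_values)) <= tol
    if (any(keep)) ct_values <- ct_values[keep]
  }
  mean(ct_values)
}

#' Delta-Ct: target minus reference gene
#'
#' `dCt = mean Ct(target) - mean Ct(reference)` for the same animal;
#' replicates are averaged before subtraction.
#'
#' @param record Target-gene [ct_record()].
#' @param reference Reference-gene (housekeeping, e.g. 36B4) [ct_record()]
#'   of the same animal.
#' @param outlier_reject Drop replicates > 0.5 cycles from the replicate
#'   median before averaging (default `FALSE`).
#' @return Delta-Ct in cycles.
#' @export
delta_ct <- function(record, reference, outlier_reject = FALSE) {
  stopifnot(inherits(record, "ct_record"), inherits(reference, "ct_record"))
  if (!identical(record$animal_id, reference$animal_id)) {
    stop(sprintf("mismatched animal ids: target '%s' vs reference '%s'",
                 record$animal_id, reference$animal_id), call. = FALSE)
  }
  aggregate_ct(record$ct_values, outlier_reject) -
    aggregate_ct(reference$ct_values, outlier_reject)
}

#' Fold change by the 2^-ddCt method
#'
#' `fold = 2^-(dCt_sample - dCt_calibrator)`. With the calibrator taken as
#' the arithmetic mean dCt of the control group (per gene), the control
#' group's geometric-mean fold is exactly 1.
#'
#' @param dct_sample Sample delta-Ct (cycles).
#' @param dct_calibrator Calibrator delta-Ct (cycles), e.g. the mean dCt of
#'   the non-ventilated group for that gene.
#' @return Fold change (dimensionless, > 0).
#' @examples
#' fold_change(3, 4)  # ddCt = -1 -> 2
#' @export
fold_change <- function(dct_sample, dct_calibrator) {
  assert_scalar(dct_sample, "dct_sample")
  assert_scalar(dct_calibrator, "dct_calibrator")
  2^(-(dct_sample - dct_calibrator))
}

#' Per-animal fold changes from a long-format Ct table
#'
#' Computes, for every animal and target gene, the delta-Ct against the
#' housekeeping gene, references it to the mean delta-Ct of the calibrator
#' group, and returns `2^-ddCt` fold changes.
#'
#' @param df Data frame with columns `animal_id`, `group`, `gene`, `ct`
#'   (one row per replicate well; a `well` column is allowed and ignored).
#' @param reference_gene Housekeeping gene name (default `"36B4"`).
#' @param calibrator_group Group whose mean delta-Ct is the calibrator
#'   (default `"NV"`).
#' @param outlier_reject Passed to [delta_ct()].
#' @return Data frame `animal_id`, `group`, `gene`, `delta_ct`,
#'   `delta_delta_ct`, `fold`.
#' @export
fold_change_table <- function(df, reference_gene = "36B4",
                              calibrator_group = "NV",
                              outlier_reject = FALSE) {
  need <- c("animal_id", "group", "gene", "ct")
  stopifnot(all(need %in% names(df)))
  if (!reference_gene %in% df$gene) {
    stop(sprintf("reference gene '%s' absent from table", reference_gene),
         call. = FALSE)
  }
  if (!calibrator_group %in% df$group) {
    stop(sprintf("calibrator group '%s' absent from table", calibrator_group),
         call. = FALSE)
  }
  # mean Ct per animal x gene
  agg <- stats::aggregate(ct ~ animal_id + group + gene, data = df,
                          FUN = aggregate_ct, outlier_reject = outlier_reject)
  ref <- agg[agg$gene == reference_gene, c("animal_id", "ct")]
  names(ref)[2L] <- "ct_ref"
  tgt <- agg[agg$gene != reference_gene, , drop = FALSE]
  tgt <- merge(tgt, ref, by = "animal_id")
  tgt$delta_ct <- tgt$ct - tgt$ct_ref
  cal <- stats::aggregate(delta_ct ~ gene,
                          data = tgt[tgt$group == calibrator_group, ],
                          FUN = mean)
  names(cal)[2L] <- "dct_cal"
  tgt <- merge(tgt, cal, by = "gene")
  tgt$delta_delta_ct <- tgt$delta_ct - tgt$dct_cal
  tgt$fold <- 2^(-tgt$delta_delta_ct)
  out <- tgt[order(tgt$gene, tgt$group, tgt$animal_id),
             c("animal_id", "group", "gene", "delta_ct", "delta_delta_ct",
               "fold")]
  rownames(out) <- NULL
  out
}
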