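# Default group-level parameters for the synthetic cohort. Means and SDs
# are the published group summaries of a five-group (NV + four ventilated)
# rat emphysema variable-ventilation study: respiratory/blood-gas
# variables and echocardiography at BASELINE and after 2 h (END), and
# post-mortem morphometry. They define the stated world the generator
# emulates; they are parameters, not fitted quantities.

vent_groups <- c("VV_0", "VV_15", "VV_22.5", "VV_30")
all_groups <- c("NV", vent_groups)

# variable, group, timepoint, mean, sd (ventilated groups only)
timepoint_defaults <- function() {
  rows <- list(
    # variable      VV_0 base      VV_0 end       VV_15 base     VV_15 end      VV_22.5 base   VV_22.5 end    VV_30 base     VV_30 end
    VT      = list(c(6.0, 0.0),   c(6.0, 0.1),   c(6.0, 0.0),   c(6.0, 0.0),   c(6.0, 0.1),   c(6.0, 0.1),   c(6.0, 0.1),   c(6.1, 0.1)),
    CV_VT   = list(c(2.5, 1.9),   c(1.6, 0.3),   c(1.2, 0.5),   c(15.4, 0.9),  c(1.6, 0.7),   c(23.4, 1.3),  c(1.4, 0.6),   c(28.8, 2.1)),
    VE      = list(c(149.5, 2.9), c(149.7, 2.1), c(150.4, 1.9), c(153.1, 7.6), c(149.8, 2.3), c(150.9, 3.6), c(149.9, 2.3), c(151.8, 4.9)),
    E       = list(c(3.2, 0.5),   c(3.6, 0.3),   c(3.3, 0.4),   c(3.2, 0.3),   c(3.2, 0.6),   c(2.8, 0.2),   c(3.0, 0.6),   c(2.4, 0.2)),
    R       = list(c(0.21, 0.04), c(0.18, 0.01), c(0.20, 0.03), c(0.18, 0.04), c(0.18, 0.02), c(0.16, 0.01), c(0.19, 0.02), c(0.17, 0.02)),
    PEEP    = list(c(3.2, 0.3),   c(3.2, 0.3),   c(3.2, 0.2),   c(3.2, 0.1),   c(3.2, 0.2),   c(3.3, 0.3),   c(3.0, 0.4),   c(3.1, 0.3)),
    pHa     = list(c(7.40, 0.02), c(7.35, 0.04), c(7.38, 0.03), c(7.36, 0.04), c(7.40, 0.05), c(7.36, 0.06), c(7.41, 0.02), c(7.37, 0.07)),
    PaO2    = list(c(139, 37),    c(176, 21),    c(134, 38),    c(191, 18),    c(133, 34),    c(179, 26),    c(134, 37),    c(173, 20)),
    PaCO2   = list(c(37.7, 1.5),  c(43.3, 5.3),  c(37.3, 3.1),  c(36.6, 5.6),  c(38.4, 6.9),  c(36.9, 8.0),  c(34.1, 3.0),  c(38.3, 5.1)),
    HCO3    = list(c(23.6, 1.2),  c(23.3, 3.4),  c(21.7, 1.6),  c(20.4, 2.7),  c(23.4, 3.0),  c(19.8, 2.7),  c(21.4, 2.3),  c(21.8, 2.7)),
    HR      = list(c(367, 75),    c(351, 67),    c(351, 60),    c(357, 52),    c(411, 66),    c(371, 60),    c(348, 46),    c(319, 89)),
    MAP     = list(c(116, 43),    c(129, 17),    c(132, 17),    c(105, 24),    c(133, 39),    c(106, 36),    c(115, 26),    c(118, 22)),
    IVC     = list(c(0.19, 0.07), c(0.20, 0.10), c(0.23, 0.09), c(0.21, 0.08), c(0.14, 0.03), c(0.12, 0.03), c(0.20, 0.06), c(0.21, 0.11)),
    RA      = list(c(0.38, 0.05), c(0.36, 0.05), c(0.43, 0.04), c(0.40, 0.03), c(0.36, 0.05), c(0.30, 0.03), c(0.40, 0.07), c(0.39, 0.05)),
    RV_area = list(c(0.34, 0.06), c(0.28, 0.05), c(0.38, 0.07), c(0.39, 0.11), c(0.34, 0.07), c(0.33, 0.05), c(0.37, 0.07), c(0.46, 0.12)),
    PAT     = list(c(20.7, 8.6),  c(28.9, 9.8),  c(22.3, 7.5),  c(33.3, 12.1), c(19.2, 5.4),  c(25.2, 5.5),  c(22.6, 7.8),  c(17.3, 8.3)),
    PET     = list(c(65.1, 18.9), c(65.0, 16.7), c(69.0, 14.5), c(61.6, 13.4), c(62.0, 8.5),  c(56.9, 9.3),  c(68.8, 9.6),  c(58.1, 13.6)),
    LV_area = list(c(0.14, 0.04), c(0.20, 0.05), c(0.12, 0.03), c(0.13, 0.04), c(0.16, 0.08), c(0.19, 0.10), c(0.13, 0.04), c(0.16, 0.08)),
    EF      = list(c(95.2, 3.9),  c(92.1, 5.4),  c(95.1, 2.3),  c(89.5, 7.3),  c(95.7, 3.4),  c(95.3, 1.9),  c(93.2, 6.6),  c(87.9, 9.2)),
    FS      = list(c(67.8, 9.2),  c(61.7, 12.3), c(66.4, 6.3),  c(54.4, 12.8), c(68.7, 9.2),  c(66.1, 5.2),  c(64.4, 13.2), c(55.9, 14.3))
  )
  out <- do.call(rbind, lapply(names(rows), function(v) {
    vals <- rows[[v]]
    data.frame(
      variable = v,
      group = rep(vent_groups, each = 2L),
      timepoint = rep(c("BASELINE", "END"), times = 4L),
      mean = vapply(vals, `[`, numeric(1), 1L),
      sd = vapply(vals, `[`, numeric(1), 2L),
      stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

# group-level morphometry summaries: Lm mean/SD (between animals) and the
# group homogeneity index, from which the within-animal diameter CV is
# derived in closed form for the pure-gamma generator (1/beta = 1/(1+2cv^2))
morphometry_defaults <- function() {
  data.frame(
    group = all_groups,
    lm_mean = c(96, 89, 89, 70, 88),
    lm_sd = c(10, 13, 13, 6, 15),
    beta_inv = c(0.66, 0.70, 0.78, 0.85, 0.76),
    stringsAsFactors = FALSE
  )
}

# Per-gene, per-group delta-delta-Ct shifts relative to NV (NV = 0 by
# construction). The study reports fold changes only graphically, so these
# magnitudes are synthetic; signs and contrasts follow the reported group
# differences (e.g. IL-6 and SP-D up in VV_30, CINC-1 up everywhere except
# VV_22.5, IL-1beta down in VV_22.5/VV_30 relative to VV_0).
qpcr_defaults <- function() {
  genes <- c("IL-6", "IL-1b", "IL-10", "CINC-1", "amphiregulin",
             "SP-D", "SP-C", "CC16", "PCIII")
  shift <- rbind(
    `IL-6`         = c(-0.5, -0.5, -0.5, -1.6),
    `IL-1b`        = c(-0.8, -0.3,  0.6,  0.6),
    `IL-10`        = c(-0.2, -0.2, -1.2, -0.2),
    `CINC-1`       = c(-1.3, -1.3, -0.2, -1.3),
    `amphiregulin` = c(0, 0, 0, 0),
    `SP-D`         = c(-0.3, -0.3, -0.3, -1.3),
    `SP-C`         = c(0.5, 0.0, -0.8, -1.0),
    `CC16`         = c(0.5, 0.0, -0.8, 0.0),
    `PCIII`        = c(0, 0, 0, 0)
  )
  colnames(shift) <- vent_groups
  list(genes = genes, reference_gene = "36B4", ddct_shift = shift,
       base_delta_ct = 5, ref_ct_mean = 20, ref_ct_sd = 0.5,
       animal_sd = 0.4, replicate_sd = 0.15, n_replicates = 3L)
}

#' Default synthetic-cohort group specifications
#'
#' Bundles the published group summaries (cardiorespiratory and
#' echocardiographic variables at BASELINE and END, morphometry, and
#' synthetic gene-expression shifts) into the specification consumed by
#' [generate_cohort()] and [run_study()].
#'
#' @param n_animals Animals per group (default 7).
#' @return A list of class `group_specs` with elements `groups`,
#'   `n_animals`, `timepoint` (per-variable mean/SD data frame),
#'   `morphometry`, and `qpcr`.
#' @export
default_group_specs <- function(n_animals = 7) {
  assert_scalar(n_animals, "n_animals", lower = 2)
  structure(
    list(groups = all_groups, vent_groups = vent_groups,
         n_animals = as.integer(n_animals),
         timepoint = timepoint_defaults(),
         morphometry = morphometry_defaults(),
         qpcr = qpcr_defaults()),
    class = "group_specs"
  )
}
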