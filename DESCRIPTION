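Package: varivent
Title: Variable-Ventilation Respiratory Mechanics, Airspace Morphometry and
    Study Statistics
Version: 0.1.0
Authors@R:
    person("Pulmonary", "Toolkits", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for designing and analysing variable mechanical
    ventilation experiments in small animals. Generates breath-to-breath
    Gaussian tidal-volume sequences at a set coefficient of variation,
    forward-simulates airway pressure under the single-compartment
    equation of motion, estimates respiratory-system elastance and
    resistance by least squares, computes airspace-heterogeneity
    morphometry (mean linear intercept, the D2 moment statistic and the
    homogeneity index 1/beta), quantifies gene expression by the
    2^-ddCt method, and provides the accompanying statistical battery
    (noncentral-t power analysis, Holm-Sidak step-down adjustment,
    repeated-measures ANOVA, Kruskal-Wallis with Dunn post hoc, Spearman
    correlation). A synthetic-cohort generator emulates a five-group
    emphysema ventilation study end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
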