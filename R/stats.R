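#' Bonferroni-adjusted significance level
#'
#' @param alpha Family-wise level in (0, 1).
#' @param m Number of comparisons (>= 1).
#' @return `alpha / m`. With the study design (0.05 over 6 pairwise
#'   comparisons) this is 0.00833, conventionally rounded to 0.008.
#' @export
bonferroni_alpha <- function(alpha, m) {
  assert_scalar(alpha, "alpha", lower = 0, upper = 1, strict_lower = TRUE)
  if (!is.numeric(m) || length(m) != 1L || is.na(m) || m < 1) {
    stop("`m` must be a count >= 1", call. = FALSE)
  }
  alpha / m
}

#' Exact power of a two-sided two-sample t-test
#'
#' Equal group sizes n, pooled-variance t-test, Cohen's d effect size:
#' df = 2n - 2, noncentrality `d * sqrt(n / 2)`. The exact noncentral-t
#' distribution is used rather than a normal approximation, which
#' misorders small n.
#'
#' @param n Per-group sample size (>= 2).
#' @param d Cohen's d (> 0).
#' @param alpha Two-sided significance level.
#' @return Power in (0, 1).
#' @export
power_two_sample_t <- function(n, d, alpha) {
  assert_scalar(n, "n", lower = 2)
  assert_scalar(d, "d", lower = 0, strict_lower = TRUE)
  assert_scalar(alpha, "alpha", lower = 0, upper = 1, strict_lower = TRUE)
  df <- 2 * n - 2
  ncp <- d * sqrt(n / 2)
  tc <- stats::qt(1 - alpha / 2, df)
  1 - stats::pt(tc, df, ncp) + stats::pt(-tc, df, ncp)
}

#' Smallest per-group n reaching target power (two-sample t-test)
#'
#' @param d Cohen's d (> 0).
#' @param alpha Two-sided level for the individual test; pass the
#'   Bonferroni-adjusted level (e.g. 0.008 for 0.05 over 6 comparisons)
#'   to size a multiple-comparison design.
#' @param power Target power (default 0.8).
#' @param n_max Search cap (default 10^4).
#' @return Smallest integer n >= 2 whose exact noncentral-t power reaches
#'   `power`.
#' @examples
#' required_n_two_sample_t(d = 2.21, alpha = 0.008)  # 7
#' @export
required_n_two_sample_t <- function(d, alpha, power = 0.8, n_max = 1e4) {
  assert_scalar(power, "power", lower = 0, upper = 1, strict_lower = TRUE)
  for (n in 2:n_max) {
    if (power_two_sample_t(n, d, alpha) >= power) return(as.integer(n))
  }
  stop("no n <= n_max reaches the target power", call. = FALSE)
}

#' Holm-Sidak step-down multiple-comparison adjustment
#'
#' P-values are sorted ascending; the i-th smallest is adjusted to
#' `max over j <= i of 1 - (1 - p_(j))^(m - j + 1)`, clipped at 1. The
#' running maximum makes rejection decisions monotone: once one ordered
#' hypothesis is retained, all later ones are too.
#'
#' @param pvalues Numeric vector of raw p-values in \[0, 1\].
#' @param alpha Family-wise level used for the `reject` column.
#' @param labels Optional contrast labels.
#' @return Data frame `contrast`, `raw_p`, `adjusted_p`, `reject`,
#'   `method`, in the input order.
#' @export
holm_sidak <- function(pvalues, alpha = 0.05, labels = NULL) {
  if (any(!is.finite(pvalues)) || any(pvalues < 0) || any(pvalues > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  m <- length(pvalues)
  if (is.null(labels)) labels <- paste0("c", seq_len(m))
  o <- order(pvalues)
  adj_sorted <- cummax(pmin(1, 1 - (1 - pvalues[o])^(m - seq_len(m) + 1)))
  adjusted <- numeric(m)
  adjusted[o] <- adj_sorted
  data.frame(contrast = labels, raw_p = pvalues, adjusted_p = adjusted,
             reject = adjusted < alpha, method = "holm-sidak",
             stringsAsFactors = FALSE)
}

#' Two-way repeated-measures (split-plot) ANOVA
#'
#' One between-subject factor (group) and one within-subject factor
#' (timepoint), balanced design. Sums of squares are computed directly from
#' cell and marginal means (Type III, which coincides with Type I on a
#' balanced design); the group effect is tested against subjects-within-
#' groups, the time and interaction effects against the within-subject
#' residual. Unbalanced or incomplete data are rejected.
#'
#' Post hoc, pairwise group contrasts within each timepoint are tested with
#' two-sample t-statistics on the cell data and Holm-Sidak adjusted as one
#' family.
#'
#' @param table Long-format data frame (a cohort table) with the columns
#'   named by `dv`, `within`, `between` and `subject`.
#' @param dv Name of the response variable column, or the value of the
#'   `variable` column if the table is in variable/value long format.
#' @param within Within-subject factor column (default `"timepoint"`).
#' @param between Between-subject factor column (default `"group"`).
#' @param subject Subject identifier column (default `"animal_id"`).
#' @param alpha Family-wise level for the post hoc tests.
#' @param posthoc Compute the pairwise contrasts (default `TRUE`); turn off
#'   for speed in simulation loops that only need the omnibus F tests.
#' @return List with `anova` (data frame of F tests for group, time and
#'   interaction) and `posthoc` (Holm-Sidak adjusted pairwise group
#'   contrasts per timepoint, or `NULL`).
#' @export
rm_anova_two_way <- function(table, dv, within = "timepoint",
                             between = "group", subject = "animal_id",
                             alpha = 0.05, posthoc = TRUE) {
  df <- as.data.frame(table)
  if (!dv %in% names(df) && all(c("variable", "value") %in% names(df))) {
    df <- df[df$variable == dv, , drop = FALSE]
    df$.y <- df$value
  } else {
    stopifnot(dv %in% names(df))
    df$.y <- df[[dv]]
  }
  g <- factor(df[[between]])
  w <- factor(df[[within]])
  s <- factor(df[[subject]])
  y <- df$.y
  if (anyNA(y)) stop("missing response values", call. = FALSE)
  a <- nlevels(g); b <- nlevels(w)
  tab <- table(g, w)
  if (length(unique(as.vector(tab))) != 1L) {
    stop("unbalanced design: unequal cell counts", call. = FALSE)
  }
  counts <- table(s, w)
  if (any(counts != 1L)) {
    bad <- rownames(counts)[rowSums(counts != 1L) > 0][1L]
    stop(sprintf("subject '%s' lacks exactly one value per timepoint", bad),
         call. = FALSE)
  }
  n <- tab[1L, 1L]  # subjects per group
  N <- length(y)
  grand <- mean(y)

  subj_mean <- tapply(y, s, mean)
  subj_group <- tapply(as.character(g), s, `[`, 1L)
  group_mean <- tapply(y, g, mean)
  time_mean <- tapply(y, w, mean)
  cell_mean <- tapply(y, list(g, w), mean)

  ss_total <- sum((y - grand)^2)
  ss_between_subj <- b * sum((subj_mean - grand)^2)
  ss_group <- n * b * sum((group_mean - grand)^2)
  ss_subj_within <- ss_between_subj - ss_group
  ss_time <- n * a * sum((time_mean - grand)^2)
  ss_cells <- n * sum((cell_mean - grand)^2)
  ss_inter <- ss_cells - ss_group - ss_time
  ss_error2 <- ss_total - ss_between_subj - ss_time - ss_inter

  df_group <- a - 1
  df_err1 <- a * (n - 1)
  df_time <- b - 1
  df_inter <- (a - 1) * (b - 1)
  df_err2 <- a * (n - 1) * (b - 1)
  if (ss_total == 0) {
    stop("zero variance: identical values for all subjects", call. = FALSE)
  }
  ms <- function(ss, df) ss / df
  f_group <- ms(ss_group, df_group) / ms(ss_subj_within, df_err1)
  f_time <- ms(ss_time, df_time) / ms(ss_error2, df_err2)
  f_inter <- ms(ss_inter, df_inter) / ms(ss_error2, df_err2)
  if (!is.finite(f_group) || !is.finite(f_time) || !is.finite(f_inter)) {
    stop("zero variance in an error stratum: F undefined", call. = FALSE)
  }
  an <- data.frame(
    effect = c(between, within, paste0(between, ":", within)),
    df1 = c(df_group, df_time, df_inter),
    df2 = c(df_err1, df_err2, df_err2),
    F = c(f_group, f_time, f_inter),
    p = c(stats::pf(f_group, df_group, df_err1, lower.tail = FALSE),
          stats::pf(f_time, df_time, df_err2, lower.tail = FALSE),
          stats::pf(f_inter, df_inter, df_err2, lower.tail = FALSE)),
    stringsAsFactors = FALSE
  )

  if (!posthoc) return(list(anova = an, posthoc = NULL))

  # post hoc: pairwise group t-tests within each timepoint, one
  # Holm-Sidak family across all of them
  labs <- character(0); praw <- numeric(0); stat <- numeric(0)
  for (wl in levels(w)) {
    for (i in seq_len(a - 1)) for (j in seq.int(i + 1, a)) {
      yi <- y[g == levels(g)[i] & w == wl]
      yj <- y[g == levels(g)[j] & w == wl]
      tt <- stats::t.test(yi, yj, var.equal = TRUE)
      labs <- c(labs, sprintf("%s vs %s @ %s", levels(g)[i], levels(g)[j], wl))
      praw <- c(praw, tt$p.value)
      stat <- c(stat, unname(tt$statistic))
    }
  }
  ph <- holm_sidak(praw, alpha = alpha, labels = labs)
  ph$statistic <- stat
  list(anova = an, posthoc = ph)
}

#' One-way ANOVA with Holm-Sidak pairwise contrasts
#'
#' @param values Numeric response vector.
#' @param groups Group labels (same length).
#' @param alpha Family-wise level for the post hoc family.
#' @return List with `anova` (F, df, p) and `posthoc` (all pairwise
#'   two-sample t contrasts using the pooled residual SE, Holm-Sidak
#'   adjusted).
#' @export
anova_one_way <- function(values, groups, alpha = 0.05) {
  g <- factor(groups)
  stopifnot(length(values) == length(g), nlevels(g) >= 2)
  fit <- stats::lm(values ~ g)
  an <- stats::anova(fit)
  mse <- an["Residuals", "Mean Sq"]
  dfr <- an["Residuals", "Df"]
  lv <- levels(g)
  ns <- table(g)
  means <- tapply(values, g, mean)
  labs <- character(0); praw <- numeric(0); stat <- numeric(0)
  for (i in seq_len(length(lv) - 1)) for (j in seq.int(i + 1, length(lv))) {
    se <- sqrt(mse * (1 / ns[i] + 1 / ns[j]))
    tv <- (means[i] - means[j]) / se
    labs <- c(labs, sprintf("%s vs %s", lv[i], lv[j]))
    stat <- c(stat, tv)
    praw <- c(praw, 2 * stats::pt(abs(tv), dfr, lower.tail = FALSE))
  }
  ph <- holm_sidak(praw, alpha = alpha, labels = labs)
  ph$statistic <- unname(stat)
  list(anova = data.frame(effect = "group", df1 = an[1, "Df"], df2 = dfr,
                          F = an[1, "F value"], p = an[1, "Pr(>F)"]),
       posthoc = ph)
}

#' Kruskal-Wallis test with Dunn's post hoc comparisons
#'
#' Kruskal-Wallis H with tie correction, followed by Dunn z-statistics on
#' mean ranks. Pairwise p-values are adjusted with Holm-Sidak by default
#' (or Bonferroni).
#'
#' @param groups A named list of numeric samples, or a numeric vector
#'   accompanied by `g`.
#' @param g Group labels when `groups` is a vector.
#' @param alpha Family-wise level.
#' @param adjust `"holm-sidak"` (default) or `"bonferroni"`.
#' @return List with `kruskal` (H, df, p) and `dunn` (pairwise z, raw and
#'   adjusted p). When every observation is identical, H = 0 and p = 1.
#' @export
kruskal_dunn <- function(groups, g = NULL, alpha = 0.05,
                         adjust = c("holm-sidak", "bonferroni")) {
  adjust <- match.arg(adjust)
  if (is.list(groups)) {
    if (is.null(names(groups))) names(groups) <- paste0("g", seq_along(groups))
    x <- unlist(groups, use.names = FALSE)
    g <- factor(rep(names(groups), lengths(groups)), levels = names(groups))
  } else {
    stopifnot(!is.null(g), length(g) == length(groups))
    x <- as.numeric(groups)
    g <- factor(g)
  }
  if (nlevels(g) < 2L) stop("need >= 2 groups", call. = FALSE)
  N <- length(x)
  r <- rank(x)
  ns <- tapply(r, g, length)
  rbar <- tapply(r, g, mean)
  ties <- table(x)
  tie_sum <- sum(ties^3 - ties)
  C <- 1 - tie_sum / (N^3 - N)
  if (C <= 0) {
    # all observations identical
    kw <- data.frame(H = 0, df = nlevels(g) - 1, p = 1)
    dn <- NULL
  } else {
    H <- (12 / (N * (N + 1)) * sum(ns * (rbar - (N + 1) / 2)^2)) / C
    kw <- data.frame(H = H, df = nlevels(g) - 1,
                     p = stats::pchisq(H, nlevels(g) - 1, lower.tail = FALSE))
    lv <- levels(g)
    var0 <- (N * (N + 1) / 12 - tie_sum / (12 * (N - 1)))
    labs <- character(0); zs <- numeric(0); praw <- numeric(0)
    for (i in seq_len(length(lv) - 1)) for (j in seq.int(i + 1, length(lv))) {
      se <- sqrt(var0 * (1 / ns[i] + 1 / ns[j]))
      z <- (rbar[i] - rbar[j]) / se
      labs <- c(labs, sprintf("%s vs %s", lv[i], lv[j]))
      zs <- c(zs, z)
      praw <- c(praw, 2 * stats::pnorm(abs(z), lower.tail = FALSE))
    }
    if (adjust == "holm-sidak") {
      dn <- holm_sidak(praw, alpha = alpha, labels = labs)
    } else {
      dn <- data.frame(contrast = labs, raw_p = praw,
                       adjusted_p = pmin(1, praw * length(praw)),
                       reject = pmin(1, praw * length(praw)) < alpha,
                       method = "bonferroni", stringsAsFactors = FALSE)
    }
    dn$statistic <- unname(zs)
    dn$mean_rank_diff <- NULL
  }
  list(kruskal = kw, dunn = dn,
       mean_ranks = stats::setNames(as.numeric(rbar), levels(g)))
}

#' Spearman rank correlation with t-approximation p-value
#'
#' Pearson correlation of (midranked) ranks; the two-sided p-value uses the
#' t approximation `t = rho * sqrt((n - 2) / (1 - rho^2))` on n - 2 df.
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return List with `rho`, `statistic`, `df`, `p`.
#' @export
spearman_cor <- function(x, y) {
  stopifnot(length(x) == length(y))
  n <- length(x)
  if (n < 3L) stop("need at least 3 pairs", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("constant input: Spearman correlation undefined", call. = FALSE)
  }
  rho <- stats::cor(rank(x), rank(y))
  if (abs(rho) >= 1) {
    p <- 0
    tv <- sign(rho) * Inf
  } else {
    tv <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(abs(tv), n - 2, lower.tail = FALSE)
  }
  list(rho = rho, statistic = tv, df = n - 2, p = p)
}

#' Paired t-test on before/after samples
#'
#' @param before,after Numeric vectors of equal length >= 2 (same
#'   subjects, same order).
#' @return List with `t`, `df`, `p`, `mean_diff`.
#' @export
paired_t <- function(before, after) {
  stopifnot(length(before) == length(after), length(before) >= 2)
  d <- after - before
  sd_d <- stats::sd(d)
  if (sd_d == 0) {
    stop("zero-variance differences: paired t undefined", call. = FALSE)
  }
  n <- length(d)
  tv <- mean(d) / (sd_d / sqrt(n))
  list(t = tv, df = n - 1,
       p = 2 * stats::pt(abs(tv), n - 1, lower.tail = FALSE),
       mean_diff = mean(d))
}

#' Per-group mean percent change from BASELINE to END
#'
#' Percent change is computed per animal, `100 * (END - BASELINE) /
#' BASELINE`, and then averaged within group. This is deliberately NOT the
#' percent change of the group means: the mean of per-animal ratios
#' differs from the ratio of means whenever baselines are heterogeneous.
#'
#' @param table Long-format cohort data frame with columns `animal_id`,
#'   `group`, `timepoint` (levels `BASELINE`, `END`), `variable`, `value`.
#' @param variables Which variables to tabulate (default: all present).
#' @return Data frame `variable` x `group` with `mean_pct_change` and
#'   `sd_pct_change`.
#' @export
percent_change_table <- function(table, variables = NULL) {
  df <- as.data.frame(table)
  need <- c("animal_id", "group", "timepoint", "variable", "value")
  stopifnot(all(need %in% names(df)))
  if (is.null(variables)) variables <- unique(df$variable)
  df <- df[df$variable %in% variables, , drop = FALSE]
  wide <- merge(
    df[df$timepoint == "BASELINE",
       c("animal_id", "group", "variable", "value")],
    df[df$timepoint == "END", c("animal_id", "variable", "value")],
    by = c("animal_id", "variable"), suffixes = c("_base", "_end"))
  if (any(wide$value_base == 0)) {
    bad <- wide$animal_id[wide$value_base == 0][1L]
    stop(sprintf("BASELINE value is 0 for animal '%s': percent change undefined",
                 bad), call. = FALSE)
  }
  wide$pct <- 100 * (wide$value_end - wide$value_base) / wide$value_base
  out <- stats::aggregate(pct ~ variable + group, data = wide,
                          FUN = function(z) c(mean = mean(z), sd = stats::sd(z)))
  data.frame(variable = out$variable, group = out$group,
             mean_pct_change = out$pct[, "mean"],
             sd_pct_change = out$pct[, "sd"],
             stringsAsFactors = FALSE)
}
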