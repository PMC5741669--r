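# The statistical battery.

test_that("Bonferroni level divides alpha by the comparison count", {
  expect_equal(bonferroni_alpha(0.05, 6), 0.05 / 6)
  expect_equal(round(bonferroni_alpha(0.05, 6), 3), 0.008)
  expect_equal(bonferroni_alpha(0.05, 1), 0.05)
  expect_equal(bonferroni_alpha(0.01, 4), 0.0025)
  expect_error(bonferroni_alpha(0.05, 0), "count")
})

test_that("exact noncentral-t power analysis reproduces the design n", {
  expect_identical(required_n_two_sample_t(d = 2.21, alpha = 0.008), 7L)
  expect_gte(power_two_sample_t(7, 2.21, 0.008), 0.8)
  expect_lt(power_two_sample_t(6, 2.21, 0.008), 0.8)
  # saturation at the minimum feasible df
  expect_identical(required_n_two_sample_t(d = 50, alpha = 0.008), 2L)
  # monotone: smaller effect or stricter alpha never reduces n
  expect_gte(required_n_two_sample_t(1.5, 0.008),
             required_n_two_sample_t(2.21, 0.008))
  expect_gte(required_n_two_sample_t(2.21, 0.001),
             required_n_two_sample_t(2.21, 0.008))
})

test_that("exact power agrees with a Monte-Carlo two-sample t oracle", {
  mc_power <- function(n, d, alpha, nsim = 1e5) {
    set.seed(99)
    x <- matrix(stats::rnorm(n * nsim, mean = d), n)
    y <- matrix(stats::rnorm(n * nsim), n)
    mx <- colMeans(x); my <- colMeans(y)
    vx <- (colSums(x^2) - n * mx^2) / (n - 1)
    vy <- (colSums(y^2) - n * my^2) / (n - 1)
    tv <- (mx - my) / sqrt((vx + vy) / n)
    mean(abs(tv) > stats::qt(1 - alpha / 2, 2 * n - 2))
  }
  for (n in c(6, 7)) {
    exact <- power_two_sample_t(n, 2.21, 0.008)
    mc <- mc_power(n, 2.21, 0.008)
    se <- sqrt(exact * (1 - exact) / 1e5)
    expect_lt(abs(mc - exact), 4 * se)
  }
})

test_that("Holm-Sidak adjustment matches closed-form hand computations", {
  out <- holm_sidak(c(0.01, 0.04))
  expect_equal(out$adjusted_p, c(1 - 0.99^2, 0.04), tolerance = 1e-12)
  expect_equal(holm_sidak(0.03)$adjusted_p, 0.03)
  expect_equal(holm_sidak(c(0, 0, 0))$adjusted_p, c(0, 0, 0))
  expect_error(holm_sidak(c(0.2, 1.3)), "\\[0, 1\\]")
})

test_that("Holm-Sidak adjusted p-values are monotone and never below raw", {
  set.seed(5)
  for (i in 1:20) {
    p <- stats::runif(sample(2:12, 1))
    out <- holm_sidak(p)
    expect_true(all(out$adjusted_p >= out$raw_p - 1e-15))
    expect_true(all(out$adjusted_p <= 1))
    o <- order(p)
    expect_true(all(diff(out$adjusted_p[o]) >= -1e-15))
  }
})

test_that("split-plot RM-ANOVA matches the aov() oracle on a balanced design", {
  set.seed(31)
  df <- null_rm_data(n = 7, ng = 4)
  df$y <- df$y + rep(c(0, 0.4, 0.8, 0), each = 7) +
    ifelse(df$timepoint == "END", 0.5, 0)
  mine <- rm_anova_two_way(df, dv = "y")
  oracle <- summary(stats::aov(
    y ~ group * timepoint + Error(animal_id / timepoint), data = df))
  between <- oracle[["Error: animal_id"]][[1]]
  within <- oracle[["Error: animal_id:timepoint"]][[1]]
  expect_equal(mine$anova$F,
               c(between["group", "F value"], within["timepoint", "F value"],
                 within["group:timepoint", "F value"]), tolerance = 1e-10)
  expect_equal(mine$anova$p,
               c(between["group", "Pr(>F)"], within["timepoint", "Pr(>F)"],
                 within["group:timepoint", "Pr(>F)"]), tolerance = 1e-10)
  expect_true(all(mine$posthoc$adjusted_p >= mine$posthoc$raw_p - 1e-15))
})

test_that("a purely additive time shift leaves the interaction F near 1", {
  set.seed(32)
  fints <- replicate(400, {
    df <- null_rm_data(n = 7, ng = 4)
    df$y <- df$y + ifelse(df$timepoint == "END", 1, 0)
    rm_anova_two_way(df, "y", posthoc = FALSE)$anova$F[3]
  })
  # E[F(3, 24)] = 24/22 under the null
  expect_equal(mean(fints), 24 / 22, tolerance = 0.12)
})

test_that("RM-ANOVA rejects degenerate and malformed designs", {
  df <- null_rm_data(n = 4, ng = 2)
  df$y <- 1
  expect_error(rm_anova_two_way(df, "y"), "zero variance")
  expect_error(rm_anova_two_way(df[-1, ], "y"), "subject|unbalanced")
  df2 <- null_rm_data(n = 4, ng = 2)
  df2 <- df2[!(df2$animal_id == "a1" & df2$timepoint == "END"), ]
  expect_error(rm_anova_two_way(df2, "y"), "a1|unbalanced")
})

test_that("one-way ANOVA with Holm-Sidak matches the lm/aov oracle", {
  set.seed(33)
  x <- stats::rnorm(21) + rep(c(0, 1, 2), each = 7)
  g <- rep(c("a", "b", "c"), each = 7)
  mine <- anova_one_way(x, g)
  oracle <- stats::anova(stats::lm(x ~ g))
  expect_equal(mine$anova$F, oracle[1, "F value"], tolerance = 1e-12)
  expect_equal(mine$anova$p, oracle[1, "Pr(>F)"], tolerance = 1e-12)
  # pairwise raw p equals pooled-SD pairwise t-test
  pt_oracle <- stats::pairwise.t.test(x, g, p.adjust.method = "none")
  expect_equal(mine$posthoc$raw_p[1], pt_oracle$p.value["b", "a"],
               tolerance = 1e-12)
})

test_that("Kruskal-Wallis H matches kruskal.test, including ties", {
  set.seed(34)
  x <- round(stats::rnorm(21), 1)  # rounding forces ties
  g <- rep(c("a", "b", "c"), each = 7)
  mine <- kruskal_dunn(x, g = g)
  oracle <- stats::kruskal.test(x, factor(g))
  expect_equal(mine$kruskal$H, unname(oracle$statistic), tolerance = 1e-12)
  expect_equal(mine$kruskal$p, oracle$p.value, tolerance = 1e-12)
  expect_true(all(mine$dunn$adjusted_p >= mine$dunn$raw_p - 1e-15))
})

test_that("identical observations give H = 0, p = 1 rather than an error", {
  out <- kruskal_dunn(list(g1 = rep(2, 5), g2 = rep(2, 5)))
  expect_equal(out$kruskal$H, 0)
  expect_equal(out$kruskal$p, 1)
})

test_that("Dunn mean ranks order with stochastically ordered groups", {
  out <- kruskal_dunn(list(lo = c(1, 2, 3), mid = c(10, 20, 30),
                           hi = c(100, 200, 300)))
  expect_true(all(diff(out$mean_ranks) > 0))
  expect_true(all(out$dunn$statistic < 0))  # lo - mid, lo - hi, mid - hi
})

test_that("Spearman correlation matches the cor.test oracle", {
  expect_equal(spearman_cor(1:6, (1:6)^2)$rho, 1)
  expect_equal(spearman_cor(1:6, -(1:6)^3)$rho, -1)
  x <- c(1, 2, 3, 4, 5); y <- c(2, 1, 4, 3, 5)
  mine <- spearman_cor(x, y)
  expect_equal(mine$rho, 0.8)  # 1 - 6*4/(5*24)
  oracle <- stats::cor.test(x, y, method = "spearman", exact = FALSE)
  expect_equal(mine$rho, unname(oracle$estimate), tolerance = 1e-12)
  expect_equal(mine$p, oracle$p.value, tolerance = 1e-12)
  expect_error(spearman_cor(rep(1, 5), 1:5), "constant")
})

test_that("paired t matches t.test and flags zero-variance differences", {
  set.seed(35)
  b <- stats::rnorm(7); a <- b + stats::rnorm(7, 0.5)
  mine <- paired_t(b, a)
  oracle <- stats::t.test(a, b, paired = TRUE)
  expect_equal(mine$t, unname(oracle$statistic), tolerance = 1e-12)
  expect_equal(mine$p, oracle$p.value, tolerance = 1e-12)
  expect_error(paired_t(b, b), "zero-variance")
  near <- paired_t(rep(0, 4), c(1, 1, 1, 1) + c(1, -1, 1, -1) * 1e-9)
  expect_gt(abs(near$t), 1e6)
  expect_lt(near$p, 1e-10)
})

test_that("percent change is per-animal-then-mean, not ratio of means", {
  tab <- data.frame(
    animal_id = rep(c("a1", "a2"), each = 2),
    group = "VV_0",
    timepoint = rep(c("BASELINE", "END"), 2),
    variable = "E",
    value = c(1, 2, 2, 2.4))
  out <- percent_change_table(tab)
  expect_equal(out$mean_pct_change, mean(c(100, 20)))  # 60, not 46.7
  ratio_of_means <- 100 * (mean(c(2, 2.4)) - mean(c(1, 2))) / mean(c(1, 2))
  expect_false(isTRUE(all.equal(out$mean_pct_change, ratio_of_means)))
  # simple anchors
  tab$value <- c(2, 3, 2, 3)
  expect_equal(percent_change_table(tab)$mean_pct_change, 50)
  tab$value <- c(2, 2, 5, 5)
  expect_equal(percent_change_table(tab)$mean_pct_change, 0)
  tab$value[1] <- 0
  expect_error(percent_change_table(tab), "a1")
})
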