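# Forward simulation under the equation of motion.

test_that("noise-free single-compartment signals satisfy the equation of motion exactly", {
  plan <- quick_plan(cv = 22.5, n = 5, seed = 2)
  vts <- generate_vt_sequence(plan)
  model <- lung_model(E = 3.0, R = 0.2, p0 = 3)
  sig <- simulate_breaths(vts, model, plan)
  resid <- sig$paw - (3.0 * sig$volume + 0.2 * sig$flow + 3)
  expect_lt(max(abs(resid)), 1e-9)
})

test_that("peak pressure matches the closed-form equation-of-motion value", {
  plan <- quick_plan(cv = 0, n = 1)
  sig <- simulate_breaths(2.622, lung_model(E = 3.0, R = 0.2, p0 = 3), plan)
  # at end-inspiration V = vt exactly and flow is at its plateau
  expect_equal(max(sig$paw), 3 + 3.0 * 2.622 + 0.2 * max(sig$flow),
               tolerance = 1e-12)
})

test_that("airway pressure relaxes to p0 during passive expiration", {
  plan <- quick_plan(cv = 0, n = 1)
  sig <- simulate_breaths(2.622, lung_model(E = 3.0, R = 0.2, p0 = 3), plan)
  n <- length(sig$paw)
  late_exp <- seq.int(floor(0.8 * n), n)
  expect_lt(max(abs(sig$paw[late_exp] - 3)), 0.05)
})

test_that("pressure noise is reproducible from the model seed", {
  plan <- quick_plan(cv = 0, n = 2)
  m <- lung_model(E = 3, R = 0.2, p0 = 3, noise_sd = 0.2, seed = 11)
  s1 <- simulate_breaths(2.622, m, plan)
  s2 <- simulate_breaths(2.622, m, plan)
  expect_identical(s1$paw, s2$paw)
  m2 <- lung_model(E = 3, R = 0.2, p0 = 3, noise_sd = 0.2, seed = 12)
  expect_false(identical(s1$paw, simulate_breaths(2.622, m2, plan)$paw))
})

test_that("inspiratory work is at least the elastic work E*vt^2/2", {
  plan <- quick_plan(cv = 22.5, n = 4, seed = 9)
  vts <- generate_vt_sequence(plan)
  model <- lung_model(E = 3.2, R = 0.21, p0 = 3)
  sig <- simulate_breaths(vts, model, plan)
  bb <- c(sig$breath_boundaries, length(sig$paw) + 1L)
  for (b in seq_along(vts$values)) {
    idx <- seq.int(bb[b], bb[b + 1L] - 1L)
    insp <- idx[sig$flow[idx] > 0]
    dv <- diff(sig$volume[insp])
    pmid <- (sig$paw[insp][-1] + sig$paw[insp][-length(insp)]) / 2 - 3
    work <- sum(pmid * dv)
    vt <- max(sig$volume[idx])
    expect_gte(work, 3.2 * vt^2 / 2 * 0.999)
  }
})

test_that("two-compartment pause pressure decays as the analytic pendelluft solution", {
  # tau1 = 0.2/3 s, tau2 = 0.8/6 s; shared-node relaxation time during an
  # end-inspiratory pause is (R1+R2)/(E1+E2) = 1/9 s
  plan <- quick_plan(cv = 0, n = 1, resp_rate = 50)
  model <- lung_model(E = 3, R = 0.2, E2 = 6, R2 = 0.8, p0 = 3)
  sig <- simulate_breaths(2.622, model, plan, pause_s = 0.45)
  t_insp <- (60 / 50) / 3
  pause_idx <- which(sig$time > t_insp + 0.005 & sig$time < t_insp + 0.44)
  p <- sig$paw[pause_idx]
  # monotone decay from peak toward plateau
  expect_true(all(diff(p) <= 1e-9))
  # plateau: equilibrated elastic pressure of the paralleled compartments
  # (residual decay after 4 relaxation times plus discretization ~ 0.05)
  e_eq <- 3 * 6 / (3 + 6)
  expect_equal(p[length(p)], 3 + e_eq * 2.622, tolerance = 0.05)
  # decay rate via successive differences, which cancel the plateau:
  # d_k = p(t_k) - p(t_k + h) is proportional to exp(-t_k (E1+E2)/(R1+R2))
  lag <- 50L
  m <- length(p) - lag
  d <- p[seq_len(m)] - p[seq_len(m) + lag]
  tt <- sig$time[pause_idx][seq_len(m)]
  keep <- d > 1e-3
  fit <- stats::lm(log(d[keep]) ~ tt[keep])
  expect_equal(unname(stats::coef(fit)[2]), -9, tolerance = 0.01)
})

test_that("ADC quantization snaps pressure onto the grid", {
  plan <- quick_plan(cv = 0, n = 1)
  sigq <- simulate_breaths(2.622, lung_model(3, 0.2, 3), plan,
                           quantize_bits = 12, quantize_range = c(-10, 60))
  step <- 70 / (2^12 - 1)
  offs <- (sigq$paw + 10) / step
  expect_lt(max(abs(offs - round(offs))), 1e-6)
  sig <- simulate_breaths(2.622, lung_model(3, 0.2, 3), plan)
  expect_lt(max(abs(sig$paw - sigq$paw)), step / 2 + 1e-9)
})

test_that("signals roundtrip through CSV with their breath boundaries", {
  plan <- quick_plan(cv = 15, n = 3, seed = 4)
  sig <- simulate_breaths(generate_vt_sequence(plan), lung_model(3, 0.2, 3),
                          plan)
  path <- withr::local_tempfile(fileext = ".csv")
  write_breath_signal(sig, path)
  back <- read_breath_signal(path)
  expect_equal(back$paw, sig$paw, tolerance = 1e-6)
  expect_identical(back$breath_boundaries, sig$breath_boundaries)
  expect_equal(back$sampling_hz, 1000)
})

test_that("simulator validates its inputs", {
  plan <- quick_plan()
  expect_error(simulate_breaths(numeric(0), lung_model(), plan), "empty")
  expect_error(simulate_breaths(c(2, -1), lung_model(), plan), "> 0")
  expect_error(lung_model(E = 0), "E")
  expect_error(lung_model(E = 3, R = 0.2, E2 = 5), "R2")
  expect_error(lung_model(noise_sd = -1), "noise_sd")
})
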