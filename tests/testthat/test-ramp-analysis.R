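test_that("Arrhenius transform applies the defining coordinates", {
  tr <- temperature_trace("t", 0, 25, -100)
  pr <- to_arrhenius(tr, min_points = 1)
  expect_equal(pr$inv_temp_K, 1 / 298.15, tolerance = 1e-15)
  expect_equal(pr$log_current, log(100), tolerance = 1e-15)
})

test_that("zero-current samples are excluded from the log domain and counted", {
  tr <- temperature_trace("t", 1:5, c(20, 21, 22, 23, 24),
                          c(-10, 0, -12, 0, -14))
  pr <- to_arrhenius(tr)
  expect_length(pr$inv_temp_K, 3)
  expect_identical(pr$n_dropped, 2L)
  expect_error(to_arrhenius(temperature_trace("t", 1:3, 20:22, c(0, 0, -1)),
                            min_points = 2), "insufficient")
})

test_that("a pure-exponential current gives an exactly linear profile", {
  tr <- make_exponential_trace(B = 18041.4)
  pr <- to_arrhenius(tr)
  fit <- lm(pr$log_current ~ pr$inv_temp_K)
  expect_equal(unname(coef(fit)[2]), -18041.4, tolerance = 1e-9)
  expect_lt(max(abs(residuals(fit))), 1e-9)
})

test_that("threshold detection recovers analytic breakpoints exactly", {
  for (t_break in c(26, 31.57, 36.85, 40)) {
    for (m in c(-25000, -18041.4, -9000)) {
      prof <- make_piecewise_profile(t_break, m = m)
      res <- detect_threshold(prof)
      expect_lt(abs(res$threshold_C - t_break), 1e-6)
      expect_equal(res$steep$slope, m, tolerance = 1e-9)
      expect_equal(res$baseline$slope, 0, tolerance = 1e-9)
    }
  }
})

test_that("a single straight line yields a no-intersection error", {
  x <- seq(1 / 320, 1 / 290, length.out = 50)
  prof <- arrhenius_profile(x, -15000 * x + 50)
  expect_error(detect_threshold(prof), "single linear component")
})

test_that("detection is deterministic for identical inputs", {
  tr <- simulate_heat_ramp(gating_params_thalf(34, noise_sd = 0.05), seed = 11)
  a <- detect_threshold(tr)
  b <- detect_threshold(tr)
  expect_identical(a, b)
})

test_that("Q10 follows from the steep slope and matches the ratio definition", {
  expect_warning(q0 <- compute_q10(list(slope = 0), t_ref_C = 30),
                 "no temperature activation")
  expect_equal(q0$q10, 1)
  # Ea = 150 kJ/mol at 30 C reference
  q <- compute_q10(list(slope = -18041.4), t_ref_C = 30)
  expect_equal(q$q10, 6.689015, tolerance = 1e-6)
  expect_equal(q$ea_kJ_mol, 150.0, tolerance = 1e-3)
  # ratio definition I(T+10)/I(T) on a pure-exponential current
  tr <- make_exponential_trace(B = 18041.4)
  pr <- to_arrhenius(tr)
  fit <- lm(pr$log_current ~ pr$inv_temp_K)
  slope <- unname(coef(fit)[2])
  t_ref <- 30
  i_ratio <- exp(-18041.4 / kelvin(t_ref + 10)) / exp(-18041.4 / kelvin(t_ref))
  q_slope <- compute_q10(list(slope = slope), t_ref_C = t_ref)$q10
  expect_equal(q_slope / i_ratio, 1, tolerance = 0.01)
})

test_that("half-max activation temperature interpolates the gated mid-rise", {
  # zero leak, linear rise from 0 at 30 C to max at 40 C
  tC <- seq(25, 40, by = 0.5)
  gated <- pmax(0, (tC - 30)) * 100
  tr <- temperature_trace("lin", seq_along(tC), tC, -gated - 1e-9)
  expect_equal(half_max_activation_temp(tr), 35, tolerance = 1e-6)
  # two-state model with T_half = 35 C and negligible leak
  p <- gating_params(dH = 300, dS = 300 / 308.15, leak_ref = 0, noise_sd = 0)
  tr2 <- simulate_heat_ramp(p, ramp_protocol(10, 45, sample_hz = 1))
  t_half <- half_max_activation_temp(tr2)
  # the ramp tops out at 45 C where P < 1, so the mid-rise sits just below
  # the model midpoint; dense-grid interpolation keeps it within the 0.5 C
  # sample spacing of the analytic value
  p_top <- thermogate::open_probability(kelvin(45), p)
  t_analytic <- 300 / (300 / 308.15 + 8.314e-3 * log(1 / (p_top / 2) - 1)) - 273.15
  expect_lt(abs(t_half - t_analytic), 0.25)
  expect_error(half_max_activation_temp(
    temperature_trace("z", 1:3, 20:22, c(-1, -1, -1)),
    list(slope = 0, intercept = log(2))), "no activation")
})

test_that("capsaicin standardization interpolates at the probe temperature", {
  tr <- temperature_trace("t", 1:3, c(39.8, 40.0, 40.2), c(-900, -1000, -1100),
                          i_capsaicin_nA = 4000)
  expect_equal(current_at_temperature(tr, 40), 0.25)
  tr2 <- temperature_trace("t", 1:2, c(39.8, 40.2), c(-900, -1100),
                           i_capsaicin_nA = 1000)
  expect_equal(current_at_temperature(tr2, 40), 1.0)  # midpoint of 900/1100
  no_ref <- temperature_trace("t", 1:2, c(39, 41), c(-1, -2))
  expect_error(current_at_temperature(no_ref, 40), "missing capsaicin")
  expect_error(current_at_temperature(tr2, 50), "outside")
  expect_error(temperature_trace("t", 1, 20, -1, i_capsaicin_nA = 0), "positive")
})

test_that("detected thresholds are strictly monotone in the generating midpoint", {
  t_halves <- seq(28, 44, by = 2)
  thr <- vapply(t_halves, function(th) {
    tr <- simulate_heat_ramp(gating_params_thalf(th, noise_sd = 0.02),
                             ramp_protocol(10, 47), seed = 21)
    detect_threshold(tr)$threshold_C
  }, numeric(1))
  expect_true(all(diff(thr) > 0))
})

test_that("threshold marks onset: below half-max activation on monotone traces", {
  for (th in c(30, 34, 38)) {
    tr <- simulate_heat_ramp(gating_params_thalf(th, noise_sd = 0), seed = 1)
    res <- analyze_trace(tr)
    expect_lt(res$threshold_C, res$t_half_act_C)
  }
})
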