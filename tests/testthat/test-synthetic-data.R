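test_that("open probability has the van't Hoff midpoint and closed form", {
  # midpoint P = 0.5 at T = dH/dS for a spread of parameter sets
  for (dH in c(100, 200, 300, 500)) {
    for (t_half in c(280, 305, 340)) {
      p <- gating_params(dH = dH, dS = dH / t_half)
      expect_equal(open_probability(t_half, p), 0.5, tolerance = 1e-12)
    }
  }
  # direct evaluation of the closed form
  p <- gating_params(dH = 200, dS = 0.6536)
  expect_equal(open_probability(300, p), 0.1719818, tolerance = 1e-6)
  # large dH at fixed midpoint approaches a step
  steep <- gating_params(dH = 20000, dS = 20000 / 310)
  expect_lt(open_probability(309, steep), 1e-3)
  expect_gt(open_probability(311, steep), 1 - 1e-3)
  expect_error(open_probability(-1, p), "positive")
})

test_that("open probability is monotone in temperature for random parameters", {
  set.seed(101)
  for (i in 1:25) {
    dH <- runif(1, 50, 600)
    t_half <- runif(1, 275, 370)
    p <- gating_params(dH = dH, dS = dH / t_half)
    tt <- sort(runif(50, 270, 380))
    pv <- open_probability(tt, p)
    expect_true(all(diff(pv) >= 0))  # ties only at float saturation
    mid <- pv > 1e-9 & pv < 1 - 1e-9
    expect_true(all(diff(pv[mid]) > 0))
  }
})

test_that("gating parameter invariants are enforced", {
  expect_error(gating_params(dH = -1, dS = 0.5), "dH")
  expect_error(gating_params(dH = 100, dS = 1), "outside")  # T_half = 100 K
  expect_error(gating_params(dH = 200, dS = 200 / 300, q10_leak = 0.8), "q10_leak")
  expect_error(gating_params(dH = 200, dS = 200 / 300, noise_sd = -0.1), "noise_sd")
})

test_that("heat-ramp simulation reduces to leak far below the midpoint", {
  p <- gating_params_thalf(40, noise_sd = 0)
  tr <- simulate_heat_ramp(p, ramp_protocol(10, 20))
  gated_max <- max(abs(tr$current_nA)) -
    p$leak_ref * p$q10_leak^((max(tr$temp_C) - 25) / 10)
  expect_lt(gated_max, 0.01 * p$i_max)
  leak <- p$leak_ref * p$q10_leak^((tr$temp_C - 25) / 10)
  expect_equal(abs(tr$current_nA), leak, tolerance = 0.01)
})

test_that("heat-ramp simulation is a pure function of params and seed", {
  p <- gating_params_thalf(34, noise_sd = 0.05)
  a <- simulate_heat_ramp(p, seed = 7)
  b <- simulate_heat_ramp(p, seed = 7)
  expect_identical(a, b)
  c2 <- simulate_heat_ramp(p, seed = 8)
  expect_false(identical(a$current_nA, c2$current_nA))
  # simulation must not disturb the caller's RNG stream
  set.seed(1); before <- runif(1)
  set.seed(1); invisible(simulate_heat_ramp(p, seed = 3)); after <- runif(1)
  expect_identical(before, after)
})

test_that("noiseless traces are monotone in magnitude and carry the inward sign", {
  tr <- simulate_heat_ramp(gating_params_thalf(32, noise_sd = 0))
  expect_true(all(tr$current_nA < 0))
  expect_true(all(diff(abs(tr$current_nA)) > 0))
})

test_that("low-occupancy Arrhenius slope of the gated component is -dH/R", {
  p <- gating_params_thalf(40, dH = 300, noise_sd = 0)
  tr <- simulate_heat_ramp(p, ramp_protocol(10, 45))
  tK <- kelvin(tr$temp_C)
  gated <- abs(tr$current_nA) - p$leak_ref * p$q10_leak^((tr$temp_C - 25) / 10)
  keep <- open_probability(tK, p) < 0.05 & gated > 0
  fit <- lm(log(gated[keep]) ~ I(1 / tK[keep]))
  slope <- unname(coef(fit)[2])
  expect_equal(slope, -p$dH * 1000 / 8.314, tolerance = 0.02)
})

test_that("dose-response generator matches the Hill closed form", {
  tab <- simulate_dose_response(ec50 = 1, hill_n = 2, r_max = 10,
                                doses = c(0, 1, 3))
  expect_equal(tab$response[tab$dose == 0], 0)
  expect_equal(tab$response[tab$dose == 1], 5)            # C = ec50
  expect_equal(tab$response[tab$dose == 3], 9)            # 9/10 of r_max
  expect_error(simulate_dose_response(1, 2, 10, numeric(0)), "non-empty")
  # acid doses are carried as pH but generated on molar [H+]
  acid <- simulate_dose_response(ec50 = 10^-6, hill_n = 1, r_max = 1,
                                 doses = 6, stimulus_kind = "acid")
  expect_equal(acid$response, 0.5)
})

test_that("melt-curve generator has the van't Hoff midpoint and plateaus", {
  mc <- simulate_melt_curve(tm_C = 32, f_native = 1000, f_unfolded = 5000)
  i <- which(mc$temp_C == 32)
  expect_equal(mc$fluorescence[i], 3000, tolerance = 1e-9)
  expect_equal(mc$fluorescence[1], 1000, tolerance = 1)   # far below Tm
  a <- simulate_melt_curve(32, noise_sd = 50, seed = 3)
  b <- simulate_melt_curve(32, noise_sd = 50, seed = 3)
  expect_identical(a, b)
  expect_error(simulate_melt_curve(32, grid_C = seq(30, 95, 0.5)), "20 C")
})

test_that("mutant panels realize the programmed linear relation", {
  pan <- simulate_mutant_panel(12, t0_C = 34, slope_C_per_kcal = -1.5,
                               noise_sd = 0, seed = 5)
  expect_equal(cor(pan$ddG_kcal_mol, pan$threshold_C), -1, tolerance = 1e-12)
  expect_identical(pan, simulate_mutant_panel(12, t0_C = 34,
                                              slope_C_per_kcal = -1.5,
                                              noise_sd = 0, seed = 5))
  expect_warning(simulate_mutant_panel(5, ddg_range = c(1, 1), seed = 1),
                 "zero width")
  # slope 0 with noise: correlation centered on zero across seeds
  rs <- vapply(1:100, function(s)
    cor(simulate_mutant_panel(16, slope_C_per_kcal = 0, noise_sd = 1,
                              seed = s)[, c("ddG_kcal_mol", "threshold_C")])[1, 2],
    numeric(1))
  expect_lt(abs(mean(rs)), 0.05)
})
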