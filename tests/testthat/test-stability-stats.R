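make_panel <- function(ddg, thr) {
  data.frame(mutant_id = sprintf("m%d", seq_along(ddg)),
             position = "P", ddG_kcal_mol = ddg, threshold_C = thr,
             stringsAsFactors = FALSE)
}

test_that("Pearson correlation matches collinear and hand-computed cases", {
  lin <- make_panel(c(0, 1, 2, 3), 40 - 2 * c(0, 1, 2, 3))
  res <- correlate_ddg_threshold(lin)
  expect_equal(res$r, -1, tolerance = 1e-12)
  expect_lt(res$p, 1e-6)
  hand <- correlate_ddg_threshold(make_panel(c(0, 1, 2, 3), c(0, 1, 0, 1)))
  expect_equal(hand$r, 0.4472136, tolerance = 1e-6)   # 2/sqrt(20)
  expect_identical(hand$n, 4L)
})

test_that("correlation guards degenerate panels and drops NA rows", {
  expect_error(correlate_ddg_threshold(make_panel(c(1, 1, 1), c(2, 3, 4))),
               "constant")
  expect_error(correlate_ddg_threshold(make_panel(c(1, 2), c(2, 3))), ">= 3")
  with_na <- make_panel(c(0, 1, 2, NA), c(5, 4, 3, 2))
  res <- correlate_ddg_threshold(with_na)
  expect_identical(res$n, 3L)
  expect_match(res$flags, "dropped_na_rows:1")
})

test_that("correlation is affine-invariant and sign-flips under negation", {
  set.seed(8)
  pan <- simulate_mutant_panel(16, slope_C_per_kcal = -1.5, noise_sd = 1,
                               seed = 8)
  r0 <- correlate_ddg_threshold(pan)$r
  scaled <- pan
  scaled$ddG_kcal_mol <- 3 * scaled$ddG_kcal_mol + 7
  scaled$threshold_C <- 0.5 * scaled$threshold_C - 2
  expect_equal(correlate_ddg_threshold(scaled)$r, r0, tolerance = 1e-12)
  neg <- pan; neg$ddG_kcal_mol <- -neg$ddG_kcal_mol
  expect_equal(correlate_ddg_threshold(neg)$r, -r0, tolerance = 1e-12)
})

test_that("null panels keep the Fisher-z interval calibrated", {
  cover <- vapply(1:100, function(s) {
    pan <- simulate_mutant_panel(16, slope_C_per_kcal = 0, noise_sd = 1,
                                 seed = s)
    ci <- correlate_ddg_threshold(pan)$ci95
    ci[1] <= 0 && 0 <= ci[2]
  }, logical(1))
  expect_gte(mean(cover), 0.90)
})

test_that("Student's t and ANOVA match hand-computed statistics", {
  same <- compare_groups(list(a = c(1, 2, 3), b = c(1, 2, 3)))
  expect_equal(same$statistic, 0)
  expect_equal(same$p, 1)
  tt <- compare_groups(list(a = c(1, 2, 3), b = c(4, 5, 6)), test = "student_t")
  expect_equal(tt$statistic, -3.674235, tolerance = 1e-6)
  expect_equal(tt$df, 4)
  expect_equal(tt$means, c(a = 2, b = 5))
  expect_equal(tt$sems, c(a = 1, b = 1) / sqrt(3))
  aov3 <- compare_groups(list(a = c(1, 2), b = c(1, 2), c = c(1, 2)),
                         test = "anova_oneway")
  expect_equal(aov3$statistic, 0)
  expect_error(compare_groups(list(a = 1, b = c(1, 2))), "insufficient")
})

test_that("post-hoc contrasts return family-wise adjusted p-values", {
  set.seed(5)
  groups <- list(ctrl = rnorm(8, 0), m1 = rnorm(8, 0.2), m2 = rnorm(8, 3))
  dunn <- compare_groups(groups, test = "anova_oneway", posthoc = "dunnett")
  expect_equal(nrow(dunn$posthoc), 2)          # two contrasts vs control
  expect_true(all(dunn$posthoc$p_adjusted > 0 & dunn$posthoc$p_adjusted <= 1))
  tuk <- compare_groups(groups, test = "anova_oneway", posthoc = "tukey")
  expect_equal(nrow(tuk$posthoc), 3)           # all pairwise
})

test_that("sample correlation is centered on the generating correlation", {
  # noise chosen so the generating (population) correlation is -0.85 with
  # ddG uniform on [-2, 4] and slope -1.5
  sd_ddg <- 6 / sqrt(12)
  rho <- -0.85
  noise <- 1.5 * sd_ddg * sqrt(1 / rho^2 - 1)
  rs <- vapply(1:150, function(s)
    correlate_ddg_threshold(simulate_mutant_panel(
      16, slope_C_per_kcal = -1.5, noise_sd = noise, seed = s))$r,
    numeric(1))
  expect_lt(abs(mean(rs) - rho), 0.05)
})
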