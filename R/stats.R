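#' Correlate mutational stability changes with activation thresholds
#'
#' Pearson correlation between per-mutant folding energy changes (ddG,
#' kcal/mol, supplied as input — computed externally by an energy function)
#' and heat-activation thresholds (degrees C). The two-sided p-value uses the
#' exact t-transform with `n - 2` degrees of freedom and the 95% confidence
#' interval the Fisher z-transform, both via [stats::cor.test]. Rows with
#' missing values are dropped and flagged.
#'
#' @param panel A `data.frame` with columns `ddG_kcal_mol` and `threshold_C`
#'   (as from [simulate_mutant_panel()] or [read_panel()]).
#' @return An object of class `correlation_result`: `r`, `p`, `n`, `ci95`,
#'   `flags`.
#' @examples
#' pan <- simulate_mutant_panel(16, slope_C_per_kcal = -1.5, noise_sd = 0, seed = 1)
#' correlate_ddg_threshold(pan)$r  # -1
#' @export
correlate_ddg_threshold <- function(panel) {
  stopifnot(is.data.frame(panel),
            all(c("ddG_kcal_mol", "threshold_C") %in% names(panel)))
  flags <- character(0)
  ok <- is.finite(panel$ddG_kcal_mol) & is.finite(panel$threshold_C)
  if (any(!ok)) flags <- c(flags, sprintf("dropped_na_rows:%d", sum(!ok)))
  x <- panel$ddG_kcal_mol[ok]; y <- panel$threshold_C[ok]
  n <- length(x)
  if (n < 3) .stopf("need >= 3 complete pairs (have %d)", n)
  if (sd(x) == 0 || sd(y) == 0)
    .stopf("undefined correlation: a variable is constant")
  ct <- suppressWarnings(cor.test(x, y, method = "pearson"))
  ci <- if (!is.null(ct$conf.int)) as.numeric(ct$conf.int) else {
    # Fisher z interval by hand when n is too small for cor.test to report one
    z <- atanh(ct$estimate); sz <- 1 / sqrt(n - 3)
    tanh(z + c(-1, 1) * qnorm(0.975) * sz)
  }
  structure(list(r = unname(ct$estimate), p = ct$p.value, n = n,
                 ci95 = ci, flags = flags),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("Pearson correlation (n = %d): r = %.4f, p = %.4g, 95%% CI [%.4f, %.4f]\n",
              x$n, x$r, x$p, x$ci95[1], x$ci95[2]))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' Group comparison statistics
#'
#' Mean +/- SEM per group with the comparison tests used throughout the
#' analysis: Student's two-sided unpaired t-test (pooled variance) or Welch's
#' t-test for two groups, one-way ANOVA for more, with optional Dunnett
#' (vs. the first group as control) or Tukey-Kramer post-hoc contrasts.
#' Post-hoc family-wise adjusted p-values are delegated to
#' [multcomp::glht].
#'
#' @param values_by_group Named list of numeric vectors, one per group (every
#'   group needs `n >= 2`).
#' @param test `"auto"` (Student's t for 2 groups, ANOVA for more),
#'   `"student_t"`, `"welch_t"` or `"anova_oneway"`.
#' @param posthoc `"none"`, `"dunnett"` (first group is the control) or
#'   `"tukey"`.
#' @return An object of class `group_comparison`: `groups`, `n`, `means`,
#'   `sems`, `test`, `statistic`, `df`, `p`, and `posthoc` (data.frame of
#'   contrasts with adjusted p-values, or `NULL`).
#' @examples
#' compare_groups(list(a = c(1, 2, 3), b = c(4, 5, 6)))$statistic  # -3.674
#' @export
compare_groups <- function(values_by_group,
                           test = c("auto", "student_t", "welch_t",
                                    "anova_oneway"),
                           posthoc = c("none", "dunnett", "tukey")) {
  test <- match.arg(test)
  posthoc <- match.arg(posthoc)
  stopifnot(is.list(values_by_group), length(values_by_group) >= 2)
  if (is.null(names(values_by_group)))
    names(values_by_group) <- paste0("group", seq_along(values_by_group))
  ns <- vapply(values_by_group, length, integer(1))
  if (any(ns < 2))
    .stopf("insufficient replicates: group '%s' has n = %d (need >= 2)",
           names(values_by_group)[which.min(ns)], min(ns))
  means <- vapply(values_by_group, mean, numeric(1))
  sems <- vapply(values_by_group, function(v) sd(v) / sqrt(length(v)), numeric(1))
  k <- length(values_by_group)
  if (test == "auto") test <- if (k == 2) "student_t" else "anova_oneway"
  if (test %in% c("student_t", "welch_t") && k != 2)
    .stopf("%s requires exactly 2 groups (have %d)", test, k)

  ph <- NULL
  if (test %in% c("student_t", "welch_t")) {
    tt <- t.test(values_by_group[[1]], values_by_group[[2]],
                 var.equal = (test == "student_t"))
    statistic <- unname(tt$statistic); df <- unname(tt$parameter); p <- tt$p.value
  } else {
    dat <- data.frame(
      value = unlist(values_by_group, use.names = FALSE),
      group = factor(rep(names(values_by_group), ns),
                     levels = names(values_by_group)))
    fit <- aov(value ~ group, data = dat)
    at <- anova(fit)
    statistic <- at[["F value"]][1]
    df <- c(at[["Df"]][1], at[["Df"]][2])
    p <- at[["Pr(>F)"]][1]
    if (posthoc != "none") {
      type <- if (posthoc == "dunnett") "Dunnett" else "Tukey"
      gl <- multcomp::glht(fit, linfct = multcomp::mcp(group = type))
      sm <- summary(gl)
      ph <- data.frame(contrast = names(sm$test$coefficients),
                       estimate = as.numeric(sm$test$coefficients),
                       p_adjusted = as.numeric(sm$test$pvalues),
                       stringsAsFactors = FALSE)
    }
  }
  structure(list(groups = names(values_by_group), n = unname(ns),
                 means = means, sems = sems, test = test,
                 statistic = statistic, df = df, p = p, posthoc = ph),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("Group comparison [%s]\n", x$test))
  for (i in seq_along(x$groups))
    cat(sprintf("  %s: mean %.4g +/- %.4g SEM (n = %d)\n",
                x$groups[i], x$means[i], x$sems[i], x$n[i]))
  cat(sprintf("  statistic = %.4g, df = %s, p = %.4g\n",
              x$statistic, paste(signif(x$df, 5), collapse = ", "), x$p))
  if (!is.null(x$posthoc)) {
    cat("  post-hoc contrasts (family-wise adjusted):\n")
    for (i in seq_len(nrow(x$posthoc)))
      cat(sprintf("    %s: estimate %.4g, p_adj %.4g\n",
                  x$posthoc$contrast[i], x$posthoc$estimate[i],
                  x$posthoc$p_adjusted[i]))
  }
  invisible(x)
}
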