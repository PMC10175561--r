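#' Detection settings for Arrhenius threshold analysis
#'
#' @param min_points Window length (samples) for the steep-segment scan and
#'   minimum size of each fitted segment. Default 10.
#' @param r2_min Minimum coefficient of determination for a candidate steep
#'   window. Default 0.90.
#' @param guard_gap Samples excluded between the steep window and the
#'   baseline region. Default 2.
#' @param t_cap_C Samples above this temperature are dropped before analysis
#'   (default `Inf`; 40 C mirrors oocyte-style protocols where heat
#'   stimulation stops at 40 C).
#' @param t_guard_C Length-2 guard band, degrees C: an intersection outside
#'   it is flagged `threshold_out_of_range` (default the profile's own
#'   temperature range).
#' @param slope_tol Minimum slope difference (K) below which the two fits are
#'   declared parallel (no intersection). Default 1e-8.
#' @return An object of class `detection_config`.
#' @export
detection_config <- function(min_points = 10, r2_min = 0.90, guard_gap = 2,
                             t_cap_C = Inf, t_guard_C = NULL,
                             slope_tol = 1e-8) {
  if (min_points < 2) .stopf("min_points must be >= 2")
  if (r2_min < 0 || r2_min > 1) .stopf("r2_min must lie in [0, 1]")
  if (guard_gap < 0) .stopf("guard_gap must be >= 0")
  if (slope_tol <= 0) .stopf("slope_tol must be > 0")
  structure(list(min_points = min_points, r2_min = r2_min,
                 guard_gap = guard_gap, t_cap_C = t_cap_C,
                 t_guard_C = t_guard_C, slope_tol = slope_tol),
            class = "detection_config")
}

#' Convert a temperature trace to an Arrhenius profile
#'
#' Plots (in coordinates) the current magnitude on a log scale against the
#' reciprocal of the absolute temperature: `x = 1/(temp_C + 273.15)`,
#' `y = ln |current|`. Samples with zero current magnitude are excluded (ln
#' domain) and counted in the `n_dropped` field. The profile is ordered by
#' ascending `1/T`, i.e. descending temperature.
#'
#' @param trace A [temperature_trace()].
#' @param min_points Minimum number of usable samples. Default 2.
#' @return An object of class `arrhenius_profile` with fields `inv_temp_K`,
#'   `log_current`, `source_index`, `n_dropped`.
#' @examples
#' tr <- temperature_trace("t", 0, 25, -100)
#' pr <- to_arrhenius(tr, min_points = 1)
#' pr$inv_temp_K  # 1/298.15
#' pr$log_current # log(100)
#' @export
to_arrhenius <- function(trace, min_points = 2) {
  stopifnot(inherits(trace, "temperature_trace"))
  mag <- abs(trace$current_nA)
  keep <- which(mag > 0 & is.finite(mag))
  if (length(keep) < min_points)
    .stopf("insufficient data: %d usable samples (need >= %d)",
           length(keep), min_points)
  x <- 1 / kelvin(trace$temp_C[keep])
  y <- log(mag[keep])
  ord <- order(x)
  structure(list(inv_temp_K = x[ord], log_current = y[ord],
                 source_index = keep[ord],
                 n_dropped = length(mag) - length(keep),
                 trace_id = trace$trace_id),
            class = "arrhenius_profile")
}

#' Build an Arrhenius profile directly from coordinate vectors
#'
#' Mainly for constructing exact piecewise-linear profiles in validation.
#'
#' @param inv_temp_K Reciprocal absolute temperature, 1/K.
#' @param log_current Natural log of current magnitude.
#' @param trace_id Identifier.
#' @return An `arrhenius_profile`.
#' @export
arrhenius_profile <- function(inv_temp_K, log_current, trace_id = "profile") {
  if (length(inv_temp_K) != length(log_current))
    .stopf("inv_temp_K and log_current must have equal length")
  if (any(!is.finite(inv_temp_K)) || any(!is.finite(log_current)))
    .stopf("profile values must be finite")
  ord <- order(inv_temp_K)
  structure(list(inv_temp_K = inv_temp_K[ord], log_current = log_current[ord],
                 source_index = ord, n_dropped = 0L, trace_id = trace_id),
            class = "arrhenius_profile")
}

# Segment fit record in 1/T coordinates. index_range is [start, end) over the
# ascending-1/T profile ordering.
.segment_fit <- function(profile, idx) {
  f <- .ols(profile$inv_temp_K[idx], profile$log_current[idx])
  tk <- 1 / profile$inv_temp_K[idx]
  list(slope = f$slope, intercept = f$intercept, r2 = f$r2,
       index_range = c(min(idx), max(idx) + 1L),
       t_range_C = celsius(range(tk)), t_mid_C = celsius(mean(range(tk))),
       n = length(idx))
}

#' Detect the heat-activation threshold on an Arrhenius profile
#'
#' Locates the threshold temperature as the point of intersection between a
#' linear fit to the baseline and a linear fit to the steepest component of
#' the profile. The steepest component is the contiguous window of
#' `min_points` samples with the largest slope magnitude among windows whose
#' fit reaches `r2 >= r2_min` (ties resolved toward higher temperature); the
#' baseline is the least-squares line over all samples at lower temperature
#' than the steep window, excluding `guard_gap` samples next to it. The
#' intersection is solved in `1/T` coordinates and converted to degrees C.
#' Deterministic given `(profile, cfg)`.
#'
#' @param profile An [arrhenius_profile()] (or a [temperature_trace()], which
#'   is converted first).
#' @param cfg A [detection_config()].
#' @return An object of class `threshold_result` with fields `threshold_C`,
#'   `baseline`, `steep` (segment fits), `flags`, and placeholders for the
#'   downstream summary statistics (`q10`, `t_half_act_C`,
#'   `i_at_probe_norm`), which [analyze_trace()] populates.
#' @export
detect_threshold <- function(profile, cfg = detection_config()) {
  if (inherits(profile, "temperature_trace"))
    profile <- to_arrhenius(profile, min_points = cfg$min_points)
  stopifnot(inherits(profile, "arrhenius_profile"),
            inherits(cfg, "detection_config"))
  flags <- character(0)
  if (profile$n_dropped > 0)
    flags <- c(flags, sprintf("dropped_nonpositive_samples:%d", profile$n_dropped))

  x <- profile$inv_temp_K; y <- profile$log_current
  if (is.finite(cfg$t_cap_C)) {
    keep <- celsius(1 / x) <= cfg$t_cap_C + 1e-12
    x <- x[keep]; y <- y[keep]
  }
  n <- length(x)
  if (n < 2 * cfg$min_points)
    .stopf("profile has %d samples after capping; need >= %d", n, 2 * cfg$min_points)
  temps_C <- celsius(1 / x)
  if (diff(range(temps_C)) < 2)
    .stopf("profile spans %.2f C; too narrow for two-segment detection",
           diff(range(temps_C)))

  # Steep-window scan. Profile is ascending in 1/T, so low indices are the
  # high-temperature end; ties toward higher temperature = lowest start index.
  w <- cfg$min_points
  slopes <- rep(NA_real_, n - w + 1L)
  r2s <- rep(NA_real_, n - w + 1L)
  for (s in seq_len(n - w + 1L)) {
    idx <- s:(s + w - 1L)
    f <- .ols(x[idx], y[idx])
    slopes[s] <- f$slope; r2s[s] <- f$r2
  }
  ok <- which(r2s >= cfg$r2_min)
  if (!length(ok))
    .stopf("no steep component: no %d-sample window reaches r2 >= %.3g",
           w, cfg$r2_min)
  amax <- max(abs(slopes[ok]))
  best_s <- ok[which(abs(slopes[ok]) >= amax * (1 - 1e-12))][1]
  # Windows whose slope ties the maximum exactly (within relative 1e-12, the
  # noiseless case of one linear steep component sampled by several windows)
  # are merged into a single steep segment, so the baseline region starts
  # below the whole component rather than below one arbitrary tied window.
  tied <- ok[abs(slopes[ok]) >= amax * (1 - 1e-12)]
  run <- best_s
  while ((run[length(run)] + 1L) %in% tied) run <- c(run, run[length(run)] + 1L)
  steep_idx <- best_s:(run[length(run)] + w - 1L)

  base_start <- steep_idx[length(steep_idx)] + 1L + cfg$guard_gap
  if (base_start > n - 1L)
    .stopf(paste("no intersection: profile reduces to a single linear",
                 "component (no baseline below the steep component)"))
  base_idx <- base_start:n
  if (length(base_idx) < cfg$min_points)
    flags <- c(flags, sprintf("short_baseline:%d", length(base_idx)))

  sub <- arrhenius_profile(x, y, profile$trace_id)
  steep <- .segment_fit(sub, steep_idx)
  baseline <- .segment_fit(sub, base_idx)

  dslope <- steep$slope - baseline$slope
  if (abs(dslope) < cfg$slope_tol)
    .stopf("no intersection: baseline and steep fits are parallel (|dslope| = %.3g)",
           abs(dslope))
  x_star <- (baseline$intercept - steep$intercept) / dslope
  if (x_star <= 0) .stopf("no intersection at a physical temperature")
  threshold_C <- celsius(1 / x_star)

  guard <- if (is.null(cfg$t_guard_C)) range(temps_C) else sort(cfg$t_guard_C)
  if (threshold_C < guard[1] || threshold_C > guard[2])
    flags <- c(flags, "threshold_out_of_range")
  if (!(threshold_C > min(baseline$t_mid_C, steep$t_mid_C) &&
        threshold_C < max(baseline$t_mid_C, steep$t_mid_C)))
    flags <- c(flags, "threshold_outside_segment_midpoints")

  structure(list(threshold_C = threshold_C, baseline = baseline, steep = steep,
                 q10 = NA_real_, t_half_act_C = NA_real_,
                 i_at_probe_norm = NA_real_, flags = flags,
                 trace_id = profile$trace_id),
            class = "threshold_result")
}

#' @export
print.threshold_result <- function(x, ...) {
  cat(sprintf("Threshold detection '%s'\n", x$trace_id))
  cat(sprintf("  threshold: %.2f C  (baseline slope %.4g, steep slope %.4g, steep r2 %.3f)\n",
              x$threshold_C, x$baseline$slope, x$steep$slope, x$steep$r2))
  if (is.finite(x$q10)) cat(sprintf("  Q10: %.2f\n", x$q10))
  if (is.finite(x$t_half_act_C))
    cat(sprintf("  half-max activation: %.2f C\n", x$t_half_act_C))
  if (is.finite(x$i_at_probe_norm))
    cat(sprintf("  standardized current at probe: %.3f\n", x$i_at_probe_norm))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' Q10 temperature coefficient from a steep-segment fit
#'
#' The Arrhenius slope in `1/T` coordinates gives the activation energy
#' `Ea = -slope * R`; the fold-change per 10 degrees follows as
#' \deqn{Q_{10} = \exp\left(\frac{E_a \cdot 10}{R\,T_{ref}(T_{ref}+10)}\right)}
#' with temperatures in K. A non-negative slope yields `Q10 <= 1` with a
#' warning (no temperature activation), not an error.
#'
#' @param steep A segment fit (the `steep` field of a
#'   [detect_threshold()] result), or any list with a `slope` field in 1/T
#'   coordinates.
#' @param t_ref_C Reference temperature, degrees C. Defaults to the midpoint
#'   temperature of the steep segment when available.
#' @return A list with `q10`, `ea_kJ_mol`, `t_ref_C`, and `warning` (flag).
#' @examples
#' compute_q10(list(slope = -18041.4), t_ref_C = 30)$q10  # ~6.69
#' @export
compute_q10 <- function(steep, t_ref_C = steep$t_mid_C) {
  if (is.null(t_ref_C) || !is.finite(t_ref_C))
    .stopf("t_ref_C is required when the fit carries no midpoint temperature")
  slope <- steep$slope
  if (!is.finite(slope)) .stopf("steep fit has no finite slope")
  ea <- -slope * .R_GAS                      # J/mol
  t1 <- kelvin(t_ref_C); t2 <- t1 + 10
  q10 <- exp(ea * 10 / (.R_GAS * t1 * t2))   # == exp(-slope * 10 / (t1 t2))
  warn <- NULL
  if (slope >= 0) {
    warn <- "nonnegative_slope"
    warning("steep slope >= 0: Q10 <= 1 (no temperature activation)", call. = FALSE)
  }
  list(q10 = q10, ea_kJ_mol = ea / 1000, t_ref_C = t_ref_C, warning = warn)
}

#' Half-maximal activation temperature
#'
#' Subtracts the extrapolated leak (the baseline Arrhenius fit transformed
#' back to current units) from the measured current magnitude and returns the
#' lowest temperature at which this gated component reaches 50% of its
#' maximum over the ramp, by linear interpolation between the bracketing
#' samples.
#'
#' @param trace A [temperature_trace()].
#' @param baseline Baseline segment fit in 1/T coordinates (from
#'   [detect_threshold()]), or `NULL` to skip leak subtraction.
#' @return Temperature, degrees C.
#' @export
half_max_activation_temp <- function(trace, baseline = NULL) {
  stopifnot(inherits(trace, "temperature_trace"))
  ord <- order(trace$temp_C)
  tC <- trace$temp_C[ord]
  mag <- abs(trace$current_nA)[ord]
  gated <- if (is.null(baseline)) mag else {
    leak <- exp(baseline$intercept + baseline$slope / kelvin(tC))
    mag - leak
  }
  gmax <- max(gated)
  if (!is.finite(gmax) || gmax <= 0)
    .stopf("no activation: leak-subtracted current never exceeds zero")
  half <- gmax / 2
  above <- which(gated >= half)
  i <- above[1]
  if (i == 1L) return(tC[1])
  # linear interpolation between the bracketing samples
  t0 <- tC[i - 1]; t1 <- tC[i]; g0 <- gated[i - 1]; g1 <- gated[i]
  if (g1 == g0) return(t1)
  t0 + (half - g0) * (t1 - t0) / (g1 - g0)
}

#' Capsaicin-standardized current at a probe temperature
#'
#' Interpolates the current magnitude at `probe_C` along the ramp and divides
#' by the trace's capsaicin reference current, giving the dimensionless
#' standardized heat response (e.g. current at 40 C as a fraction of the
#' maximal capsaicin response of the same cell).
#'
#' @param trace A [temperature_trace()] carrying `i_capsaicin_nA`.
#' @param probe_C Probe temperature, degrees C; must lie inside the trace's
#'   temperature range.
#' @return Standardized current, dimensionless.
#' @export
current_at_temperature <- function(trace, probe_C = 40) {
  stopifnot(inherits(trace, "temperature_trace"))
  if (is.null(trace$i_capsaicin_nA))
    .stopf("missing capsaicin reference current on trace '%s'", trace$trace_id)
  rng <- range(trace$temp_C)
  if (probe_C < rng[1] || probe_C > rng[2])
    .stopf("probe temperature %.2f C outside trace range [%.2f, %.2f] C",
           probe_C, rng[1], rng[2])
  i_probe <- approx(trace$temp_C, abs(trace$current_nA), xout = probe_C,
                    ties = mean)$y
  i_probe / trace$i_capsaicin_nA
}

#' Full per-trace ramp analysis
#'
#' Runs [detect_threshold()], [compute_q10()] (reference at the steep-segment
#' midpoint), [half_max_activation_temp()] (leak-subtracted via the baseline
#' fit) and, when a capsaicin reference is present and the probe temperature
#' lies inside the ramp, [current_at_temperature()], returning one populated
#' `threshold_result`.
#'
#' @param trace A [temperature_trace()].
#' @param cfg A [detection_config()].
#' @param probe_C Probe temperature for the standardized current, degrees C.
#' @param subtract_leak Use the baseline fit for leak subtraction in the
#'   half-max computation (default `TRUE`).
#' @return A `threshold_result` with `q10`, `t_half_act_C` and
#'   `i_at_probe_norm` filled in.
#' @export
analyze_trace <- function(trace, cfg = detection_config(), probe_C = 40,
                          subtract_leak = TRUE) {
  res <- detect_threshold(trace, cfg)
  res$q10 <- compute_q10(res$steep)$q10
  res$t_half_act_C <- tryCatch(
    half_max_activation_temp(trace, if (subtract_leak) res$baseline else NULL),
    error = function(e) { res$flags <<- c(res$flags, "no_activation"); NA_real_ })
  if (!is.null(trace$i_capsaicin_nA) &&
      probe_C >= min(trace$temp_C) && probe_C <= max(trace$temp_C)) {
    res$i_at_probe_norm <- current_at_temperature(trace, probe_C)
  }
  res
}
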