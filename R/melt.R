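#' Normalize a thermal-shift melt curve
#'
#' Applies the fractional-unfolding normalization
#' \deqn{\Delta F(t)/\Delta F_{max} = \frac{F(t) - F(20\,°C)}{F_{max} - F(20\,°C)}}
#' where `F(20 C)` is the fluorescence at the 20 C reference sample (the
#' nearest grid sample within `ref_tol_C`) and `Fmax` is the global maximum
#' of the raw curve. The normalized curve is exactly 0 at the reference
#' sample and exactly 1 at the maximum, and is invariant under positive
#' affine transforms of the raw fluorescence. The index of the maximum is
#' recorded as the truncation point for Tm fitting, which makes the
#' downstream estimate robust to the post-peak fluorescence decay of
#' SYPRO-type dyes.
#'
#' @param curve A `data.frame` with columns `temp_C` and `fluorescence`
#'   (single sample), as from [simulate_melt_curve()] or [read_melt()].
#' @param ref_C Reference temperature, degrees C. Default 20.
#' @param ref_tol_C Maximum distance from `ref_C` to the nearest grid sample.
#'   Default 0.25 (half of the standard 0.5 C sampling step).
#' @return An object of class `normalized_melt_curve`: `temp_C`,
#'   `delta_f_norm`, `f_ref_20C`, `f_max`, `truncation_index`, `sample_id`.
#' @examples
#' mc <- simulate_melt_curve(tm_C = 32)
#' nm <- normalize_melt(mc)
#' range(nm$delta_f_norm[seq_len(nm$truncation_index)])  # ~[0 at 20 C, 1]
#' @export
normalize_melt <- function(curve, ref_C = 20, ref_tol_C = 0.25) {
  stopifnot(is.data.frame(curve),
            all(c("temp_C", "fluorescence") %in% names(curve)))
  tC <- curve$temp_C; f <- curve$fluorescence
  if (any(diff(tC) <= 0)) .stopf("temp_C must be strictly increasing")
  if (any(!is.finite(f)) || any(f < 0)) .stopf("fluorescence must be finite and >= 0")
  iref <- which.min(abs(tC - ref_C))
  if (abs(tC[iref] - ref_C) > ref_tol_C)
    .stopf("no %g C reference sample within %.2f C on the grid", ref_C, ref_tol_C)
  f_ref <- f[iref]
  imax <- which.max(f)
  f_max <- f[imax]
  if (f_max <= f_ref)
    .stopf("flat curve: maximum fluorescence does not exceed the %g C reference", ref_C)
  structure(list(temp_C = tC, delta_f_norm = (f - f_ref) / (f_max - f_ref),
                 f_ref_20C = f_ref, f_max = f_max,
                 ref_index = iref, truncation_index = imax,
                 sample_id = if ("sample_id" %in% names(curve))
                   as.character(curve$sample_id[1]) else "curve"),
            class = "normalized_melt_curve")
}

#' Estimate the melting temperature from a normalized melt curve
#'
#' The default method fits a Boltzmann sigmoid with free plateaus,
#' `f(T) = A + (B - A) / (1 + exp((tm - T)/k))`, to the ascending region of
#' the normalized curve truncated at the global fluorescence maximum; `tm` is
#' the fitted midpoint. Alternatives: `half_max_interp` (first upward 0.5
#' crossing on the ascending region, linearly interpolated) and
#' `derivative_max` (temperature of the steepest central-difference slope
#' before truncation). If the sigmoid fit fails to converge the estimator
#' falls back to half-max interpolation and sets the
#' `fallback_half_max` flag.
#'
#' @param norm A [normalize_melt()] result.
#' @param method Estimation method.
#' @param min_points Minimum samples on the ascending region. Default 8.
#' @return An object of class `tm_result`: `tm_C`, `method`, `params`, `se`,
#'   `flags`.
#' @export
estimate_tm <- function(norm,
                        method = c("boltzmann_fit", "half_max_interp",
                                   "derivative_max"),
                        min_points = 8) {
  stopifnot(inherits(norm, "normalized_melt_curve"))
  method <- match.arg(method)
  idx <- seq_len(norm$truncation_index)
  if (length(idx) < min_points)
    .stopf("ascending region has %d samples; need >= %d", length(idx), min_points)
  tC <- norm$temp_C[idx]; yv <- norm$delta_f_norm[idx]
  flags <- character(0)

  half_max <- function() {
    above <- which(yv >= 0.5)
    if (!length(above)) .stopf("normalized curve never reaches 0.5")
    i <- above[1]
    if (i == 1L) return(tC[1])
    t0 <- tC[i - 1]; t1 <- tC[i]; y0 <- yv[i - 1]; y1 <- yv[i]
    if (y1 == y0) t1 else t0 + (0.5 - y0) * (t1 - t0) / (y1 - y0)
  }

  if (method == "half_max_interp") {
    return(structure(list(tm_C = half_max(), method = method, params = NULL,
                          se = NULL, flags = flags, sample_id = norm$sample_id),
                     class = "tm_result"))
  }
  if (method == "derivative_max") {
    dydt <- diff(yv) / diff(tC)
    tmid <- (tC[-1] + tC[-length(tC)]) / 2
    return(structure(list(tm_C = tmid[which.max(dydt)], method = method,
                          params = NULL, se = NULL, flags = flags,
                          sample_id = norm$sample_id),
                     class = "tm_result"))
  }

  dat <- data.frame(tC = tC, yv = yv)
  tm0 <- half_max()
  fit <- tryCatch(
    minpack.lm::nlsLM(
      yv ~ A + (B - A) / (1 + exp((tm - tC) / k)), data = dat,
      start = list(A = min(yv), B = 1, tm = tm0, k = 2),
      lower = c(A = -Inf, B = -Inf, tm = min(tC), k = 1e-3),
      upper = c(A = Inf, B = Inf, tm = max(tC), k = Inf),
      control = nls.control(maxiter = 200, warnOnly = TRUE)),
    error = function(e) NULL)
  if (is.null(fit) || !fit$convInfo$isConv) {
    flags <- c(flags, "fallback_half_max")
    return(structure(list(tm_C = half_max(), method = "half_max_interp",
                          params = NULL, se = NULL, flags = flags,
                          sample_id = norm$sample_id),
                     class = "tm_result"))
  }
  cf <- coef(fit)
  se <- tryCatch(sqrt(diag(vcov(fit))), error = function(e) NULL)
  structure(list(tm_C = unname(cf["tm"]), method = method,
                 params = as.list(cf), se = se, flags = flags,
                 sample_id = norm$sample_id),
            class = "tm_result")
}

#' @export
print.tm_result <- function(x, ...) {
  cat(sprintf("Tm ('%s'): %.2f C  [%s]\n", x$sample_id, x$tm_C, x$method))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' Melt-curve analysis for a multi-sample plate
#'
#' Normalizes and fits each sample independently and summarizes Tm as
#' mean +/- SE per sample group (replicate curves sharing the prefix of
#' `sample_id` before the last underscore, or the whole id).
#'
#' @param plate A `data.frame` with columns `sample_id`, `temp_C`,
#'   `fluorescence`.
#' @param method Passed to [estimate_tm()].
#' @return A list with `per_curve` (data.frame sample_id, tm_C, method,
#'   flags) and `summary` (data.frame group, n, mean_tm_C, sem_tm_C).
#' @export
analyze_melt_plate <- function(plate, method = "boltzmann_fit") {
  stopifnot(is.data.frame(plate),
            all(c("sample_id", "temp_C", "fluorescence") %in% names(plate)))
  ids <- unique(plate$sample_id)
  rows <- lapply(ids, function(id) {
    cur <- plate[plate$sample_id == id, , drop = FALSE]
    tm <- estimate_tm(normalize_melt(cur), method = method)
    data.frame(sample_id = id, tm_C = tm$tm_C, method = tm$method,
               flags = paste(tm$flags, collapse = ";"),
               stringsAsFactors = FALSE)
  })
  per_curve <- do.call(rbind, rows)
  grp <- sub("_[^_]*$", "", per_curve$sample_id)
  summ <- do.call(rbind, lapply(split(per_curve$tm_C, grp), function(v)
    data.frame(n = length(v), mean_tm_C = mean(v),
               sem_tm_C = if (length(v) >= 2) sd(v) / sqrt(length(v)) else NA_real_)))
  summ <- cbind(group = rownames(summ), summ, stringsAsFactors = FALSE)
  rownames(summ) <- NULL
  list(per_curve = per_curve, summary = summ)
}
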