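#' Two-state gating model parameters
#'
#' Parameter container for the van't Hoff two-state channel used by the
#' synthetic heat-ramp generator. The open probability is
#' \deqn{P(T) = 1 / (1 + \exp((\Delta H - T \Delta S) / (R T)))}
#' with \eqn{R = 8.314} J/(mol K), so the channel is half-open at
#' \eqn{T_{1/2} = \Delta H / \Delta S}. The measured current magnitude is the
#' sum of a weakly temperature-dependent leak (Q10 around 1.3, typical of
#' ohmic leak in oocytes) and the gated current \eqn{i_{max} P(T)}, under
#' multiplicative Gaussian noise.
#'
#' @param dH Activation enthalpy, kJ/mol. Must be positive.
#' @param dS Activation entropy, kJ/(mol K). Must be positive; `dH/dS` (the
#'   half-activation temperature in K) must fall in `[273.15, 373.15]`.
#' @param i_max Maximal gated current magnitude at the holding potential, nA.
#' @param leak_ref Leak current magnitude at 25 C, nA.
#' @param q10_leak Dimensionless leak temperature coefficient, `>= 1`.
#' @param noise_sd Multiplicative Gaussian noise SD (dimensionless fraction).
#' @param seed Integer random seed or `NULL`.
#' @return An object of class `gating_params`.
#' @examples
#' p <- gating_params(dH = 200, dS = 200 / 309.15)  # T_half = 36 C
#' open_probability(309.15, p)                      # 0.5
#' @export
gating_params <- function(dH, dS, i_max = 4000, leak_ref = 50,
                          q10_leak = 1.3, noise_sd = 0, seed = NULL) {
  if (!is.numeric(dH) || dH <= 0) .stopf("dH must be > 0 (kJ/mol)")
  if (!is.numeric(dS) || dS <= 0) .stopf("dS must be > 0 (kJ/(mol K))")
  t_half <- dH / dS
  if (t_half < 273.15 || t_half > 373.15)
    .stopf("dH/dS = %.2f K lies outside [273.15, 373.15] K", t_half)
  if (i_max <= 0) .stopf("i_max must be > 0")
  if (leak_ref < 0) .stopf("leak_ref must be >= 0")
  if (q10_leak < 1) .stopf("q10_leak must be >= 1")
  if (noise_sd < 0) .stopf("noise_sd must be >= 0")
  structure(list(dH = dH, dS = dS, i_max = i_max, leak_ref = leak_ref,
                 q10_leak = q10_leak, noise_sd = noise_sd, seed = seed),
            class = "gating_params")
}

#' @export
print.gating_params <- function(x, ...) {
  cat(sprintf(
    "Two-state gating model: dH = %.4g kJ/mol, dS = %.4g kJ/(mol K), T_half = %.2f C\n",
    x$dH, x$dS, celsius(x$dH / x$dS)))
  cat(sprintf("  i_max = %.4g nA, leak_ref = %.4g nA (Q10 %.2f), noise_sd = %.3g\n",
              x$i_max, x$leak_ref, x$q10_leak, x$noise_sd))
  invisible(x)
}

#' Convenience constructor: gating parameters from a target half-activation
#' temperature
#'
#' Keeps `dH` fixed and sets `dS = dH / T_half`, so sweeps over `t_half_C`
#' change the activation midpoint without changing the steepness.
#'
#' @param t_half_C Half-activation temperature, degrees C.
#' @param dH Activation enthalpy, kJ/mol (default 300, giving the steep
#'   thermoTRP-like activation with Q10 well above 10 near threshold).
#' @param ... Passed to [gating_params()].
#' @return A `gating_params` object.
#' @export
gating_params_thalf <- function(t_half_C, dH = 300, ...) {
  gating_params(dH = dH, dS = dH / kelvin(t_half_C), ...)
}

#' Heat-ramp protocol
#'
#' @param t_start_C,t_stop_C Start/stop bath temperature, degrees C.
#' @param rate_C_per_s Heating rate, C/s (default 0.5).
#' @param sample_hz Sampling rate, Hz (default 2).
#' @return An object of class `ramp_protocol`.
#' @export
ramp_protocol <- function(t_start_C = 10, t_stop_C = 45,
                          rate_C_per_s = 0.5, sample_hz = 2) {
  if (t_start_C >= t_stop_C) .stopf("t_start_C must be < t_stop_C")
  if (rate_C_per_s <= 0) .stopf("rate_C_per_s must be > 0")
  if (sample_hz <= 0) .stopf("sample_hz must be > 0")
  structure(list(t_start_C = t_start_C, t_stop_C = t_stop_C,
                 rate_C_per_s = rate_C_per_s, sample_hz = sample_hz),
            class = "ramp_protocol")
}

#' Equilibrium open probability of the two-state channel
#'
#' @param temp_K Absolute temperature(s), K. Must be positive.
#' @param params A [gating_params()] object.
#' @return Open probability in (0, 1), strictly increasing in temperature.
#' @examples
#' p <- gating_params(dH = 200, dS = 0.6536)
#' open_probability(300, p)  # ~0.172
#' @export
open_probability <- function(temp_K, params) {
  stopifnot(inherits(params, "gating_params"))
  if (any(!is.finite(temp_K)) || any(temp_K <= 0))
    .stopf("temp_K must be positive and finite")
  1 / (1 + exp((params$dH - temp_K * params$dS) / (.R_GAS_KJ * temp_K)))
}

#' Construct a temperature trace
#'
#' Validated container for a single heat-ramp recording. Inward currents at
#' -80 mV are carried as negative values; all analyses use magnitudes.
#'
#' @param trace_id Identifier.
#' @param time_s Strictly increasing time grid, s.
#' @param temp_C Bath temperature per sample, degrees C (finite, in [0, 100]).
#' @param current_nA Holding current per sample, nA.
#' @param i_capsaicin_nA Optional scalar capsaicin reference current
#'   magnitude, nA (must be > 0 when present).
#' @return An object of class `temperature_trace`.
#' @export
temperature_trace <- function(trace_id, time_s, temp_C, current_nA,
                              i_capsaicin_nA = NULL) {
  n <- length(time_s)
  if (length(temp_C) != n || length(current_nA) != n)
    .stopf("time_s, temp_C and current_nA must have equal length")
  if (n >= 2 && any(diff(time_s) <= 0)) .stopf("time_s must be strictly increasing")
  if (any(!is.finite(temp_C)) || any(temp_C < 0) || any(temp_C > 100))
    .stopf("temp_C must be finite and within [0, 100] C")
  if (!is.null(i_capsaicin_nA)) {
    if (!is.numeric(i_capsaicin_nA) || length(i_capsaicin_nA) != 1L ||
        !is.finite(i_capsaicin_nA) || i_capsaicin_nA <= 0)
      .stopf("i_capsaicin_nA must be a single positive number")
  }
  structure(list(trace_id = as.character(trace_id), time_s = as.numeric(time_s),
                 temp_C = as.numeric(temp_C), current_nA = as.numeric(current_nA),
                 i_capsaicin_nA = i_capsaicin_nA),
            class = "temperature_trace")
}

#' @export
print.temperature_trace <- function(x, ...) {
  cat(sprintf("Temperature trace '%s': %d samples, %.1f-%.1f C, |I| %.3g-%.3g nA\n",
              x$trace_id, length(x$time_s), min(x$temp_C), max(x$temp_C),
              min(abs(x$current_nA)), max(abs(x$current_nA))))
  if (!is.null(x$i_capsaicin_nA))
    cat(sprintf("  capsaicin reference: %.4g nA\n", x$i_capsaicin_nA))
  invisible(x)
}

#' Simulate a heat-ramp current recording
#'
#' Generates a linear temperature ramp and the corresponding holding-current
#' trace from the two-state model: per-sample current magnitude is
#' `leak_ref * q10_leak^((T - 25)/10) + i_max * P(T)` scaled by multiplicative
#' Gaussian noise `(1 + e)`, `e ~ N(0, noise_sd^2)`. The inward sign
#' convention (negative current at -80 mV) is applied last. Identical
#' `(params, protocol, seed)` give a bit-identical trace.
#'
#' @param params A [gating_params()] object (its `seed` is used unless
#'   overridden by `seed`).
#' @param protocol A [ramp_protocol()] object.
#' @param trace_id Identifier for the trace.
#' @param seed Optional seed overriding `params$seed`.
#' @param i_capsaicin_nA Capsaicin reference current magnitude attached to the
#'   trace; defaults to `2 * i_max` (heat responses in the model system are
#'   typically a fraction of the saturating capsaicin response).
#' @return A [temperature_trace()].
#' @export
simulate_heat_ramp <- function(params, protocol = ramp_protocol(),
                               trace_id = "sim", seed = NULL,
                               i_capsaicin_nA = 2 * params$i_max) {
  stopifnot(inherits(params, "gating_params"), inherits(protocol, "ramp_protocol"))
  seed <- if (is.null(seed)) params$seed else seed
  dur <- (protocol$t_stop_C - protocol$t_start_C) / protocol$rate_C_per_s
  time_s <- seq(0, dur, by = 1 / protocol$sample_hz)
  temp_C <- protocol$t_start_C + protocol$rate_C_per_s * time_s
  temp_K <- kelvin(temp_C)
  leak <- params$leak_ref * params$q10_leak^((temp_C - 25) / 10)
  gated <- params$i_max * open_probability(temp_K, params)
  mag <- leak + gated
  if (params$noise_sd > 0) {
    eps <- .with_seed(seed, rnorm(length(mag), 0, params$noise_sd))
    mag <- mag * (1 + eps)
  }
  temperature_trace(trace_id, time_s, temp_C, -mag, i_capsaicin_nA)
}

#' Simulate a sigmoidal dose-response table
#'
#' Responses follow the Hill equation
#' `r(C) = r_max * C^n / (ec50^n + C^n)` under multiplicative Gaussian noise.
#' For acid stimulation doses are given on the pH scale and converted to molar
#' proton concentration `C = 10^(-pH)` internally (the `dose` column keeps pH
#' units); `ec50` must then be given in molar `[H+]`.
#'
#' @param ec50 Half-maximal dose (uM for capsaicin, molar `[H+]` for acid).
#' @param hill_n Hill coefficient, > 0.
#' @param r_max Maximal response.
#' @param doses Dose vector (uM, or pH units for acid).
#' @param n_replicates Replicates per dose.
#' @param noise_sd Multiplicative noise SD (fraction).
#' @param seed Integer seed or `NULL`.
#' @param construct Construct label.
#' @param stimulus_kind `"capsaicin"` or `"acid"`.
#' @return A `data.frame` with columns construct, stimulus_kind, dose,
#'   replicate, response.
#' @export
simulate_dose_response <- function(ec50, hill_n, r_max, doses,
                                   n_replicates = 1, noise_sd = 0, seed = NULL,
                                   construct = "sim",
                                   stimulus_kind = c("capsaicin", "acid")) {
  stimulus_kind <- match.arg(stimulus_kind)
  if (length(doses) == 0) .stopf("doses must be non-empty")
  if (ec50 <= 0 || hill_n <= 0) .stopf("ec50 and hill_n must be > 0")
  if (stimulus_kind == "capsaicin" && any(doses < 0))
    .stopf("capsaicin doses must be >= 0")
  if (stimulus_kind == "acid" && (any(doses <= 0) || any(doses >= 14)))
    .stopf("pH doses must lie in (0, 14)")
  conc <- if (stimulus_kind == "acid") 10^(-doses) else doses
  tab <- expand.grid(replicate = seq_len(n_replicates), dose = doses,
                     KEEP.OUT.ATTRS = FALSE)
  cc <- if (stimulus_kind == "acid") 10^(-tab$dose) else tab$dose
  mu <- ifelse(cc == 0, 0, r_max * cc^hill_n / (ec50^hill_n + cc^hill_n))
  resp <- if (noise_sd > 0) {
    mu * (1 + .with_seed(seed, rnorm(length(mu), 0, noise_sd)))
  } else mu
  data.frame(construct = construct, stimulus_kind = stimulus_kind,
             dose = tab$dose, replicate = tab$replicate, response = resp,
             stringsAsFactors = FALSE)
}

#' Simulate a two-state thermal-shift melt curve
#'
#' Fluorescence follows a van't Hoff two-state unfolding transition:
#' `F(T) = f_native + (f_unfolded - f_native) * u(T) + e`, with unfolded
#' fraction `u(T) = 1 / (1 + exp(dH_unfold/R * (1/T_K - 1/Tm_K)))` so that
#' `u(Tm) = 0.5`. Optionally a linear post-peak decay emulates the dye
#' aggregation drop seen in SYPRO-type assays past the fluorescence maximum.
#'
#' @param tm_C Melting temperature, degrees C; must lie inside the grid.
#' @param dH_unfold van't Hoff unfolding enthalpy, kJ/mol.
#' @param f_native,f_unfolded Fluorescence plateaus (`f_unfolded > f_native`).
#' @param grid_C Temperature grid, degrees C (default 10-95 in 0.5 steps; must
#'   cover 20 C, the normalization reference).
#' @param noise_sd Additive Gaussian noise SD, fluorescence units.
#' @param seed Integer seed or `NULL`.
#' @param sample_id Sample label.
#' @param post_peak_decay If positive, fluorescence decays linearly at this
#'   rate (units per degree C) above `tm_C + decay_onset_C`.
#' @param decay_onset_C Offset above Tm at which the decay starts.
#' @return A `data.frame` with columns sample_id, temp_C, fluorescence.
#' @export
simulate_melt_curve <- function(tm_C, dH_unfold = 300, f_native = 1000,
                                f_unfolded = 5000,
                                grid_C = seq(10, 95, by = 0.5),
                                noise_sd = 0, seed = NULL, sample_id = "sim",
                                post_peak_decay = 0, decay_onset_C = 10) {
  if (any(diff(grid_C) <= 0)) .stopf("grid_C must be strictly increasing")
  if (min(abs(grid_C - 20)) > 0.25)
    .stopf("grid_C must cover 20 C (the normalization reference)")
  if (tm_C <= min(grid_C) || tm_C >= max(grid_C)) .stopf("tm_C must lie inside grid_C")
  if (f_unfolded <= f_native) .stopf("f_unfolded must exceed f_native")
  u <- 1 / (1 + exp(dH_unfold / .R_GAS_KJ * (1 / kelvin(grid_C) - 1 / kelvin(tm_C))))
  f <- f_native + (f_unfolded - f_native) * u
  if (post_peak_decay > 0) {
    over <- pmax(0, grid_C - (tm_C + decay_onset_C))
    f <- f - post_peak_decay * over
  }
  if (noise_sd > 0)
    f <- f + .with_seed(seed, rnorm(length(f), 0, noise_sd))
  f <- pmax(f, 0)
  data.frame(sample_id = sample_id, temp_C = grid_C, fluorescence = f,
             stringsAsFactors = FALSE)
}

#' Simulate a mutant stability/threshold panel
#'
#' Draws per-mutant folding energy changes `ddG` uniformly over `ddg_range`
#' and sets activation thresholds on a linear relation
#' `threshold = t0_C + slope * ddG + e`, `e ~ N(0, noise_sd^2)`. A negative
#' slope emulates the inverse stability/threshold relation in which
#' destabilizing mutations lower the heat-activation threshold.
#'
#' @param n_mutants Number of mutants (>= 3 for downstream correlation).
#' @param t0_C Threshold at ddG = 0, degrees C.
#' @param slope_C_per_kcal Linear slope, degrees C per kcal/mol (negative for
#'   the inverse relation).
#' @param ddg_range Length-2 range for uniform ddG sampling, kcal/mol.
#' @param noise_sd Threshold noise SD, degrees C.
#' @param seed Integer seed or `NULL`.
#' @return A `data.frame` with columns mutant_id, position, ddG_kcal_mol,
#'   threshold_C. If `ddg_range` has zero width with more than one mutant the
#'   attribute `degenerate_ddg` is set `TRUE` and a warning is raised
#'   (correlation is undefined downstream).
#' @export
simulate_mutant_panel <- function(n_mutants = 16, t0_C = 34,
                                  slope_C_per_kcal = -1.5,
                                  ddg_range = c(-2, 4), noise_sd = 1,
                                  seed = NULL) {
  if (n_mutants < 3) .stopf("n_mutants must be >= 3")
  if (length(ddg_range) != 2) .stopf("ddg_range must have length 2")
  degenerate <- diff(range(ddg_range)) == 0 && n_mutants > 1
  if (degenerate)
    warning("ddg_range has zero width: downstream correlation is undefined",
            call. = FALSE)
  out <- .with_seed(seed, {
    ddg <- runif(n_mutants, min(ddg_range), max(ddg_range))
    thr <- t0_C + slope_C_per_kcal * ddg +
      (if (noise_sd > 0) rnorm(n_mutants, 0, noise_sd) else 0)
    list(ddg = ddg, thr = thr)
  })
  panel <- data.frame(
    mutant_id = sprintf("mut%02d", seq_len(n_mutants)),
    position = sprintf("P%d", seq_len(n_mutants)),
    ddG_kcal_mol = out$ddg, threshold_C = out$thr,
    stringsAsFactors = FALSE)
  attr(panel, "degenerate_ddg") <- degenerate
  panel
}
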