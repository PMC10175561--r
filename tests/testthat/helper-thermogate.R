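# Shared fixtures, built in code.

# Exact two-segment Arrhenius profile: flat baseline at y0, steep line with
# slope m through the breakpoint at inverse temperature x0 = 1/T0_K.
make_piecewise_profile <- function(t_break_C, m = -18041.4, y0 = log(5),
                                   t_lo_C = 16, t_hi_C = max(46, t_break_C + 8),
                                   n = 2 * round(t_hi_C - t_lo_C)) {
  x <- seq(1 / kelvin(t_hi_C), 1 / kelvin(t_lo_C), length.out = n)
  x0 <- 1 / kelvin(t_break_C)
  y <- ifelse(x < x0, m * x + (y0 - m * x0), y0)
  arrhenius_profile(x, y)
}

kelvin <- function(temp_C) temp_C + 273.15

# Noiseless pure-exponential current trace I = A * exp(-B / T_K): its
# Arrhenius profile is an exact line with slope -B.
make_exponential_trace <- function(A = 1e10, B = 18041.4,
                                   t_lo_C = 20, t_hi_C = 45, step_C = 0.25) {
  tC <- seq(t_lo_C, t_hi_C, by = step_C)
  mag <- A * exp(-B / kelvin(tC))
  temperature_trace("exp", seq_along(tC), tC, -mag, i_capsaicin_nA = 1000)
}
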