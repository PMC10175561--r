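---
title: "Methods: threshold detection, Q10, Tm and stability correlation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: threshold detection, Q10, Tm and stability correlation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thermogate)
```

## Scope

thermogate analyzes heat-ramp current recordings from temperature-gated ion
channels (the TRPV1 family being the canonical case) and the companion
assays of a variant-characterization study: dose–response curves,
differential scanning fluorimetry (DSF) melt curves, and mutant
stability/threshold panels. This vignette documents the models, the
estimators, the tunable parameters, and the design choices made where the
conventions of the field leave the procedure under-determined.

## The two-state generative model

No public raw recordings exist for data of this kind, so the package ships
a generator whose ground truth every estimator can be tested against. A
channel population in thermal equilibrium between one closed and one open
state has open probability

$$P(T) = \frac{1}{1 + \exp\!\big((\Delta H - T\,\Delta S)/(RT)\big)},$$

with activation enthalpy $\Delta H$ (kJ/mol), entropy $\Delta S$
(kJ/(mol·K)) and $R = 8.314$ J/(mol·K). $P$ rises monotonically with $T$ and
equals $1/2$ at $T_{1/2} = \Delta H / \Delta S$. A recorded heat-ramp trace
is modelled as

$$|I|(T) = \Big[\,\underbrace{I_{leak}\,Q_{10,leak}^{(T-25)/10}}_{\text{leak}}
 + \underbrace{I_{max}\,P(T)}_{\text{gated}}\Big]\,(1+\varepsilon),
 \qquad \varepsilon \sim N(0, \sigma^2),$$

stored with the inward (negative) sign convention of recordings at −80 mV;
analyses operate on magnitudes throughout. Defaults and why:

| parameter | default | rationale |
|---|---|---|
| $\Delta H$ | 300 kJ/mol | thermoTRP heat activation is extremely steep; this puts the steep-segment Q10 in the 18–25 range typical of heat-gated currents, and separates the gated component cleanly from the leak so the Arrhenius profile shows the baseline-then-steep shape the threshold procedure assumes |
| $I_{max}$ | 4000 nA | whole-oocyte scale currents |
| $I_{leak}$ (25 °C) | 50 nA | small ohmic leak |
| $Q_{10,leak}$ | 1.3 | weak, near-ohmic temperature dependence of leak |
| noise $\sigma$ | 0.03 | multiplicative 3% measurement noise |
| ramp | 10 → 45 °C at 0.5 °C/s, 2 Hz | a plausible bath-heating protocol; heating rates are rarely reported for this assay, so the rate is configurable and its value is not interpreted |
| capsaicin reference | $2 I_{max}$ | heat responses are typically a fraction of the saturating capsaicin response of the same cell |

`gating_params_thalf()` sweeps the activation midpoint at fixed $\Delta H$,
which is how cohorts of "constructs" with different thresholds are built.

What the generator deliberately does **not** emulate: single-channel
stochastic gating, voltage dependence, desensitization during the ramp,
series-resistance and capacitance artifacts, and any rate dependence of
thresholds. Recovery results on this generator therefore demonstrate the
correctness and calibration of the estimators under the stated model — not
robustness to every artifact of real recordings.

Dose–response tables, melt curves and mutant panels come from analogous
closed forms: the Hill equation under multiplicative noise; a two-state
van't Hoff unfolding transition $u(T) = 1/(1+\exp(\Delta H_u/R\,(1/T -
1/T_m)))$ between fluorescence plateaus under additive noise (with an
optional linear post-peak decay mimicking SYPRO dye aggregation); and a
linear threshold–$\Delta\Delta G$ relation with uniform $\Delta\Delta G$
sampling and Gaussian threshold noise. Every generator is a pure function of
its parameters and seed, and restores the caller's RNG state.

## Threshold detection on the Arrhenius profile

`to_arrhenius()` maps a trace to $x = 1/(T_{°C} + 273.15)$, $y = \ln|I|$,
dropping (and counting) samples with zero magnitude, ordered by ascending
$x$. `detect_threshold()` then:

1. **Steep component** — scans contiguous windows of `min_points` samples
   (default 10) and selects, among windows whose linear fit reaches
   $r^2 \ge$ `r2_min` (default 0.90), the one maximizing $|slope|$. Ties are
   broken toward the higher-temperature window. Windows tying the maximum
   slope exactly (relative tolerance $10^{-12}$ — the noiseless case, where
   one linear steep segment is sampled by several windows) are merged into a
   single steep segment, so the baseline region is defined below the whole
   component rather than below one arbitrary tied window; with measurement
   noise exact ties do not occur and the rule reduces to the plain maximum.
2. **Baseline** — least-squares line over all samples at lower temperature
   than the steep segment, excluding a guard gap (default 2 samples) next to
   it.
3. **Intersection** — the two lines are intersected in $1/T$ coordinates and
   converted to °C. Parallel fits (slope difference below `slope_tol`,
   default $10^{-8}$ K) raise a no-intersection error, as does a profile
   whose steep component extends to its low-temperature end (a single linear
   component). An intersection outside the guard band (default: the
   profile's own temperature range) is flagged, not fatal, as is a baseline
   shorter than `min_points`.

The fixed window length keeps the scan deterministic and linear-time; on a
noiseless linear segment any longer window has the same slope, so nothing is
lost relative to a variable-length search. An optional `t_cap_C` drops
samples above a ceiling first (40 °C mirrors oocyte protocols that stop
heating there; the default is no cap so that simulated sweeps with high
midpoints remain analyzable).

Noiseless two-segment profiles are recovered to machine precision
(the suite asserts $\le 10^{-6}$ °C against analytic breakpoints), and
detection is bit-for-bit deterministic in `(profile, cfg)`.

## Q10, half-max activation, capsaicin standardization

The steep slope in $1/T$ coordinates gives $E_a = -R \cdot slope$ and

$$Q_{10} = \exp\!\Big(\frac{10\,E_a}{R\,T_{ref}\,(T_{ref}+10)}\Big),$$

evaluated by default at the steep segment's midpoint temperature — the
reference is not standardized in the field, so it is exposed in the API. The
slope form agrees with the ratio definition $I(T+10)/I(T)$ exactly on
pure-exponential currents; a non-negative slope returns $Q_{10} \le 1$ with
a warning rather than an error.

`half_max_activation_temp()` subtracts the leak — the baseline fit
extrapolated through the ramp and transformed back to current units — and
returns the lowest temperature where the gated component reaches half its
ramp maximum, linearly interpolated between bracketing samples. Leak
subtraction makes the statistic invariant to leak size; a no-subtraction
mode exists (`baseline = NULL`) since published figures do not always state
whether leak was removed. On monotone-activation traces the detected
threshold always lies below the half-max temperature: the intersection marks
onset, the half-max marks mid-rise.

`current_at_temperature()` interpolates $|I|$ at the probe temperature
(default 40 °C) and divides by the trace's capsaicin reference current.
Threshold detection is scale-invariant (a log-domain shift), so whether
currents are standardized before or after detection cannot change the
threshold; standardization matters only for the current summaries.

## Hill fits

`fit_hill()` fits $r(C) = r_{max} C^n/(EC_{50}^n + C^n)$ by
Levenberg–Marquardt with the Hill coefficient bounded in $[0.3, 10]$,
started at $n = 1$, $r_{max} = \max r$, $EC_{50}$ at the geometric median
dose, with 5 starts jittering $\log_{10} EC_{50}$ over $\pm 1$; the best
converged start by RSS wins. The source figures this mirrors plot means ± SE
without naming a fit, so the Hill model is adopted as the community
standard. Acid tables arrive on the pH scale and are converted to molar
[H+] $= 10^{-pH}$ before fitting; `ph50` $= -\log_{10} EC_{50}$ is reported
alongside. The fit is scale-free (scaling responses scales $r_{max}$ only)
and invariant to replicate order; degenerate tables (all responses equal,
fewer than 3 distinct doses, negative responses) are rejected.

## Melt curves and Tm

`normalize_melt()` applies the fractional-unfolding normalization

$$\Delta F(t)/\Delta F_{max} = \frac{F(t) - F(20\,°C)}{F_{max} - F(20\,°C)}$$

with the 20 °C reference taken as the nearest grid sample within 0.25 °C
(half the standard 0.5 °C sampling step) and $F_{max}$ the global maximum of
the raw curve. The normalized curve is exactly 0 at the reference and 1 at
the maximum, invariant under positive affine transforms of raw fluorescence,
and idempotent. The maximum's index becomes the truncation point for Tm
estimation, which excludes the post-peak aggregation decay of SYPRO-type
dyes.

`estimate_tm()` defaults to a Boltzmann sigmoid with free plateaus,
$f(T) = A + (B-A)/(1+\exp((T_m - T)/k))$, fitted to the pre-maximum region;
$T_m$ is the fitted midpoint. Free plateaus make the fit robust to the
normalized curve not spanning exactly [0, 1] on the fitted region. How a
printed Tm was obtained is typically not stated in publications, so two
alternatives are selectable — `half_max_interp` (first upward 0.5 crossing,
interpolated) and `derivative_max` (steepest central difference) — and all
three agree within a grid step on noiseless sigmoids. Non-convergence falls
back to half-max interpolation with a flag. Replicate curves are fitted
independently and summarized as mean ± SE per sample group
(`analyze_melt_plate()`).

## Stability correlation and group statistics

$\Delta\Delta G$ values are consumed as an input table and never computed:
mutational energy calculations belong to external structure-based tools. Per
convention the correlation uses per-mutant mean thresholds, one pair per
mutant. `correlate_ddg_threshold()` reports Pearson's $r$, the exact
t-transform p-value ($n-2$ df) and the Fisher-z 95% CI via `stats::cor.test`
(computed directly when $n < 4$). `compare_groups()` wraps Student's/Welch's
t and one-way ANOVA with Dunnett or Tukey–Kramer contrasts delegated to
`multcomp::glht`; the module's contract is the adjusted-p output shape, not
a re-derivation of the contrast internals.

## Pipeline and reproducibility

`run_pipeline()` concentrates all file I/O and orchestration: simulate (or
read) → analyze each trace → optional dose/melt/panel stages → a run report
with per-trace rows (every input accounted for: analyzed or
skipped-with-reason), cohort means ± SE, the package version, an MD5 hash of
the canonical-JSON configuration, and a registry of every derived seed.
Reports contain no timestamps, so identical configurations produce
byte-identical JSON.

## Validation problem sizes

The test suite validates by parameter recovery at these sizes, chosen to
make Monte-Carlo checks stable while keeping the default run fast: 100 seeds
per activation-midpoint setting (28/32/36/40 °C, 3% noise) for threshold
recovery; 200 seeds for EC50 (4 replicates/dose, 5% noise) and Tm (2%
amplitude noise, 0.5 °C grid) recovery; 500 seeds for correlation
calibration (null coverage of the Fisher-z interval, and bias at a
generating correlation of −0.85 with 16 mutants); 2000 replicates for the
t-test's type-I error; cohorts of 24 traces per construct for the pipeline
summaries.

## Known limitations

* The threshold estimator presumes a monotone baseline-then-steep profile;
  desensitizing or biphasic responses are flagged or rejected rather than
  modelled.
* The window rule (`min_points`, `r2_min`) is a deliberate, documented
  operationalization of "the steepest component"; published analyses rarely
  state theirs, so absolute thresholds can differ between labs even on
  identical data. Within one rule, comparisons across constructs are
  consistent.
* Hill fits assume a shared $r_{max}$ across replicates of a construct; no
  per-cell normalization or global fitting across constructs is attempted.
* Tm estimation targets two-state-like transitions; multi-domain unfolding
  with multiple transitions is out of scope.
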