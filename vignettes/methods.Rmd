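---
title: "Models and methods behind hopperdev"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind hopperdev}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hopperdev)
```

This vignette is the package's own account of its science: the models it
implements, the assumptions they carry, the numerical choices made where
the methodology left them open, and what a green test does and does not
establish.

## 1. Square-wave regimes and the constant temperature equivalent

A rearing regime is an idealised square wave: 12 h at
$\bar T + A$ and 12 h at $\bar T - A$, with the warm phase aligned to the
start of the photophase. Temperature sensitivity is modelled
exponentially,
$$R(T) = R_1 \, Q_{10}^{(T - T_1)/10},$$
with the reference rate $R_1 = 1$ pinned at the mean rearing temperature
$T_1 = 24$ °C. Because both phases last 12 h and the rate model has no
time dependence, phase alignment with the light cycle cannot affect any
computed quantity (asserted by test).

The **constant temperature equivalent** compresses such a regime into one
number. The literature holds more than one definition and published
treatment summaries rarely state which was used, so the package exposes
two:

* **Rate-weighted mean** (default): the development-rate-weighted mean
  of the phase temperatures,
  $\mathrm{CTE} = \frac{T_w r(T_w) + T_c r(T_c)}{r(T_w) + r(T_c)}$ —
  "the median developmental temperature after accounting for development
  speeding up with temperature". Under $Q_{10} = 4$ this yields 26.02 °C
  for the 24 ± 4 regime and 24.54 °C for 24 ± 2, i.e. the familiar
  26 °C / 25 °C pair after integer rounding, with their 1 °C difference.
* **Rate-equivalent temperature**: the $T^*$ whose constant rate equals
  the time-averaged rate over the cycle; in closed form
  $T^* = \bar T + \frac{10}{\ln Q_{10}}
  \ln\cosh\!\big(\frac{A}{10}\ln Q_{10}\big)$, handled as the limit
  $T^* = \bar T$ at $Q_{10} = 1$. It is always the smaller of the two
  for $Q_{10} > 1$ (Jensen-type ordering, verified numerically over a
  $Q_{10} \times A$ grid).

The choice of formulation and of the oracle $Q_{10} = 4$ is **our
reconstruction**, selected because it reproduces the conventional
integer-degree summaries; it is not a claim about how any particular
study computed theirs. Rounding to whole degrees happens only at the
reporting layer.

## 2. Fluctuating-temperature Q10 models

With development units accrued at $Q_{10}$-scaled rates over the two
phases, days to adulthood and adult mass are
$$d = \frac{c}{Q_{10}^{T_{var}/10} + Q_{10}^{-T_{var}/10}},
\qquad
M = c\, d\, \big(Q_{10}^{T_{var}/10} + Q_{10}^{-T_{var}/10}\big),$$
where $T_{var}$ is the half-amplitude of the square wave (4 °C for HV,
2 °C for LV) and $c$ absorbs the fixed developmental requirement (for
$d$) or the growth scale (for $M$). One source text places $T_{var}$
"from $T_1 = 20$ °C", which conflicts with the 24 °C regime mean; since
only $T_{var}$ itself enters the model we read it as the amplitude about
the mean, and nothing downstream depends on the resolution.

Two structural facts are worth noting, both tested:

* The bracket $Q_{10}^{x} + Q_{10}^{-x}$ is symmetric under
  $Q_{10} \mapsto 1/Q_{10}$, so development time **decreases** with
  amplitude for every $Q_{10} \neq 1$ — warm-phase acceleration always
  beats cool-phase slowing in this functional form. There is no
  "increasing for $Q_{10} < 1$" regime.
* Composing the two models with a **shared** $Q_{10}$ cancels the
  brackets exactly: $M = c_{growth} c_{dev}$ independent of $T_{var}$,
  to machine precision. The model family therefore builds in the
  possibility of faster development without a size cost; whether growth
  and development $Q_{10}$s actually coincide is an empirical question
  the fits answer.

**Fitting.** Each site × photoperiod × sex group is fitted
independently by nonlinear least squares (`stats::nls`, `"port"`
algorithm), starts $Q_{10} = 2$ and $c = 2\overline{d}$ (development) or
$c = \overline{M/(2d)}$ (growth), bounds $Q_{10} \in [0.1, 20]$,
$c > 0$, convergence tolerance $10^{-10}$. The `"port"` algorithm is
used because it accepts box bounds and tolerates the zero-residual case
(noiseless round-trip tests recover parameters to better than $10^{-3}$
relative). A group with a single distinct $T_{var}$ is refused — two
parameters cannot be identified from one design point — and an optimiser
failure is returned as a flagged, `NA` fit rather than an exception. An
independent `nlme::gnls` fit of the same model on noisy data agrees with
our estimates to $10^{-4}$ (cross-check test only; it is never the
implementation). Relative $Q_{10}$s divide by the maximum of the set
passed in — all fits together by default, or per group via `within=`
(e.g. per sex), matching the shared-axis convention for comparing
groups.

## 3. Growing degree-days

Daily degree-days above the lower developmental threshold (LDT) use the
single-sine approximation: one symmetric sine between Tmin and Tmax with
a fixed 12 h min-to-max spacing, integrated analytically. The three
cases (threshold below the sine, above it, intercepting it) join
continuously; the intercepted case
$\frac{1}{\pi}\big[(T_m - L)(\frac{\pi}{2} - \theta) + \alpha\cos\theta\big]$,
$\theta = \arcsin((L - T_m)/\alpha)$, agrees with adaptive quadrature of
the clipped sine to $10^{-6}$ °C·day over 1,000 random triples. (A
caution for anyone re-deriving the check: a *naive* call to
`stats::integrate` over the whole day loses ~$10^{-3}$ at the clip
kinks; the test oracle splits the domain at the two crossing times
first.)

Defaults: LDT 0 °C (the rearing-derived threshold for this species;
12 °C, the older pooled field value, is available by argument);
accumulation starts at day-of-year 1 — the choice between Jan 1 and
snowmelt is open in the source methodology, and Jan 1 is the
assumption-free option since sub-threshold winter days contribute
nothing with LDT ≥ 0. Missing weather days are a hard error by default;
`allow_gaps = TRUE` downgrades them to a warning and marks the series
non-contiguous, in which case cumulative values are lower bounds.

## 4. Development index and adult timing

The development index of a survey is the count-weighted mean stage,
$\mathrm{DI} = \sum s\, n_s / \sum n_s \in [1, 6]$ with stages 1–5 the
juvenile instars and 6 adult. Surveys with zero detections are dropped
with a warning rather than failing a site-year. DI is smoothed against
day-of-year or cumulative GDD with a cubic smoothing spline
(`stats::smooth.spline`), smoothing chosen by generalised
cross-validation unless `spar` is given; replicate surveys on one axis
value are first averaged, weighted by individuals counted, and fitted
values are clamped to $[1, 6]$. Fewer than four distinct axis values
yields an `insufficient_data` status that propagates to the timing
estimate.

Adult timing is the **first upward crossing** of DI = 5.5 within the
observed axis range — 5.5 sits just below the all-adult asymptote, near
the curve's inflection — located by bracketing on a 512-point grid and
`uniroot` refinement to $10^{-3}$ axis units. Design choices, made for
near-monotone but noisy curves: no extrapolation beyond the surveyed
range; a fitted maximum below threshold returns `not_reached`; a series
already above threshold at its first survey returns that first axis
value flagged `boundary = TRUE` (the crossing happened before
observation began, so the first observed point is the honest censored
estimate).

## 5. The synthetic study

The generator states one world and keeps it fixed:

* **Rearing** — the full 2 × 2 × 3 × 2 factorial (HV/LV × long/short ×
  three sites at 2,195 / 2,591 / 3,048 m × two sexes), 10 individuals
  per cell (the study-scale average), development noise SD 2 days and
  mass noise SD 0.03 g (a few percent of typical values, matching the
  visible scatter in such experiments), truncated above zero by
  inverse-CDF sampling so determinism is exact. True parameters encode
  the headline biology: development $Q_{10}$ = 3.5 for all long-day
  cells, rising linearly with elevation from 3.5 to 6 under short days;
  growth $Q_{10}$ = 2 everywhere, with a female/male scale difference
  (0.0055 vs 0.0042 g·day⁻¹-scale) giving realistic 0.35–0.6 g adults.
* **Weather** — daily mean = annual mean 8 °C + seasonal cosine of
  amplitude 11 °C peaking at doy 200 + elevation-lapse offsets (0,
  −2.5, −5.5 °C; ~6.5 °C km⁻¹) + N(0, 2 °C) day noise; Tmin/Tmax sit a
  fixed 12 °C diurnal range apart, so `tmax >= tmin` by construction.
  Warm vs cool seasons are explicit ±2 °C offsets, not random draws.
* **Surveys** — a cohort of 100 hatches when cumulative GDD (LDT 0)
  passes N(400, 30) °C·day and advances a stage every further
  150 °C·day (so adults appear ~1,150 °C·day after Jan 1), weekly
  surveys with detection probability 0.5. An optional daylength
  modulation multiplies each day's degree-days by
  $1 + \beta (p_0 - \text{daylength})/p_0$ (default off) — a stand-in
  for the hypothesis that short days accelerate development, not a
  fitted quantity.

Randomness uses one root seed with per-generator derived streams
(R's default Mersenne–Twister), so each table is byte-reproducible and
independent of the order generators are called in.

**What the generator does not emulate** — and hence what a green test
does not establish: real mountain weather (no autocorrelated synoptic
events, radiation, or snow), observation processes beyond binomial
thinning (no sweep-net biases by stage), overlapping generations,
mortality, or any attempt to match the deposited field dataset's values.
Passing tests establish that the *estimators recover the stated world's
parameters*, e.g. that noiseless fits are exact, that noisy
($\sigma$ = 2 days, $n$ = 40) Monte-Carlo fits of a true $Q_{10} = 4$
have |bias| < 0.3, and that a GDD-driven population shows GDD-invariant
adult timing across warm and cool seasons while calendar timing shifts
— not that any field population behaves this way.

## 6. Known limitations

* The CTE reconstruction fixes the rate model's $Q_{10}$ at 4; the fits
  themselves make no use of the CTE, so this affects reporting only.
* Grouped fits share no parameters and carry no maternal random effects
  (mother identity is retained in the data but unused); mixed-effects
  inference is out of scope.
* The first-crossing rule can under-estimate timing if a noisy spline
  wiggles above 5.5 early; the GCV default smooths most of this away,
  and `spar` is exposed for stubborn series.
* Degree-day accumulation treats air temperature as the operative
  temperature — no thermoregulation or microclimate modelling.
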