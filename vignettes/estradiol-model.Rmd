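---
title: "Modelling estradiol production from ultrasound follicle tracking"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling estradiol production from ultrasound follicle tracking}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(follE2)
```

## The model

Estradiol (E2) is produced by the granulosa cells lining ovarian follicles.
follE2 models the scaled (0–1) plasma E2 concentration during a bovine
estrous cycle as a single ordinary differential equation driven by the
summed granulosa-layer volumes of the follicles present on the ovary on each
day, as seen by ultrasound:

$$
\frac{dE2}{dt} \;=\;
\Bigl(e_1\,\mathrm{ReF} + e_2\,\mathrm{SeF} + e_3\,\mathrm{DmF}
  + e_4 \sum_{i=1}^{N} \mathrm{AtrDmF}_i\,\delta_i(t)\,
    e^{-m\,(t-\mathrm{delay}_i)}\Bigr)
\frac{\mathrm{IGF1}^{n_I}}{T_I^{n_I} + \mathrm{IGF1}^{n_I}}
\;+\; a_3\,\mathrm{DmF}\,\frac{T^{n}}{T^{n} + P4^{n}}
\;-\; \alpha_{E2}\,E2 .
$$

ReF, SeF and DmF are the summed granulosa volumes of recruited (< 5 mm),
secondary (5–8 mm) and dominant (> 8 mm) healthy follicles;
$\mathrm{AtrDmF}_i$ is the granulosa volume of the $i$-th atretic dominant
follicle, whose production decays exponentially (rate $m$) from its atresia
onset, with $\delta_i(t)$ switching the term on while the follicle is
recorded. A positive Hill function of IGF1 (threshold $T_I$, exponent
$n_I$) gates the production of all healthy and atretic classes; a negative
Hill function of progesterone (P4; threshold $T$, exponent $n$) adds the
surge of dominant-follicle production once P4 collapses at luteolysis —
a proxy for the LH environment, which is not modelled directly.
$\alpha_{E2}$ is first-order clearance.

Three supporting sub-models close the system:

* **Geometry.** The granulosa layer is a thin shell. For a spherical
  follicle its volume is $\tfrac{4}{3}\pi r_G (r_G^2 + 3 r_A r_G + 3 r_A^2)$
  (antrum radius $r_A$, granulosa thickness $r_G$); histology sections are
  treated as ellipsoids whose unmeasured third axis is the mean of the two
  measured ones. Because $r_G$ saturates as follicles grow, shell volume is
  asymptotically quadratic in diameter, motivating the regression
  $V_G(d) = 0.1741\,d^2 - 0.1407\,d + 0.1288$ mm³ used to turn an
  ultrasound diameter into a granulosa volume. The fit is valid over
  2–20 mm; outside that range the package warns and extrapolates, and the
  small positive value at $d = 0$ is left untruncated as a regression
  artifact. A cell-density constant (2,320,445 cells/mm³) converts volume
  to cell counts on request.
* **IGF1 surrogate.** Raw IGF1 is rarely assayed in the field; a
  degree-5 polynomial in scaled P4,
  $\mathrm{IGF1}(P4) = 18.311 P4^5 - 59.062 P4^4 + 68.983 P4^3 - 34.283 P4^2
  + 5.9711 P4 + 0.6839$, reproduces the observation that IGF1 is highest at
  low P4 and levels off as P4 rises. The polynomial cannot distinguish
  early-luteal from late-luteal low P4; that limitation is inherited
  knowingly. Inputs outside [0, 1] are accepted with a warning and an
  optional output clamp (off by default).
* **Atresia and classes.** A follicle is atretic from the first scan on
  which its diameter falls below 90% of its running maximum. Follicles that
  exceeded 8 mm before that onset are *atretic dominants* and keep
  producing (decaying) E2; atretic subordinates are dropped from all
  production terms — their production is treated as negligible (a flag can
  retain them in their size class to study that simplification). Dominance is necessarily retrospective: ultrasound
  alone cannot label a dominant follicle prospectively.

### Model forms

The full form gives each atresia day its own production constant
($e_4 \dots e_{14}$, ages 1–11, later ages clamped to the last value); the
exponential form replaces them with $e_4 e^{-m(t - \mathrm{delay}_i)}$ (and
analogously $a_4, m_2$ on the P4 branch); the reduced form drops the
P4-branch terms for all classes except dominant ($a_3$), which the
identified parameter values justify. The package implements all three with
exact reduction identities, which the tests verify on randomised forcing.

### The delay clock

The decay term $e^{-m(t-\mathrm{delay}_i)}$ is interpreted with
$\mathrm{delay}_i$ equal to the atresia onset day (start of calculations at
$t_0 = 0$), so the factor is exactly 1 on the onset day and declines
thereafter — production by an atretic dominant is largest at the start of
atresia and falls gradually. $\delta_i(t)$ is an on-switch, not an impulse.

## Parameters, units and defaults

All hormone values are scaled 0–1 by their cycle maximum, and times are in
days. Default parameter values are the identified estimates of the reduced
model: production rates per mm³ of granulosa per day
($e_1 = 18.747$, $e_2 = 39.006$, $e_3 = 468.12$, $e_4 = 619.56$,
$a_3 = 127.54$), Hill constants $T = 0.0020$, $n = 54.57$, $T_I = 1.3409$,
$n_I = 2.7371$, clearance $\alpha_{E2} = 3.916$ d⁻¹, atretic decay
$m = 0.2319$ d⁻¹, and $E2(0) = 0.8298$.

Two volume conventions are supported. With raw mm³ forcing the per-mm³
rates apply. Dividing each class rate by the maximum granulosa volume that
class attains in the dataset (defaults 10, 15, 65 and 39 mm³ for ReF, SeF,
DmF and AtrDmF) gives dimensionless rates (1.8747, 2.6004, 7.2019, 1.9622,
15.8861) that pair with volume-fraction forcing, i.e. each class volume
divided by its class maximum; `scale = "data"` derives those maxima from
the tracks at hand. The package simulates on the volume-fraction
convention by default in its studies, since only then do the identified
rates produce E2 on the 0–1 scale the hormones are defined on.

The exponent $n \approx 54.6$ makes naive Hill evaluation overflow
($P4^{54.6}$ exceeds double range for modest P4), so both Hill functions
are computed in log space, with an asymptotic tail beyond the exponential
range.

## Numerical choices

The E2 equation is linear in E2 — production does not depend on the state —
so two integrators are provided. `simulate_e2(method = "lsoda")` is the
adaptive reference (relative tolerance 1e-8). `method = "linear"` evaluates
the production term on a fixed 0.01-day grid and advances the exact
exponential-trapezoid recurrence; it is exact for piecewise-linear
production, handles the jump discontinuities at atresia onsets by one-sided
evaluation at grid points, and agrees with the reference to about 1e-4
while being two to three orders of magnitude faster. Fitting, posterior
sampling and prediction bands use the fast path automatically whenever the
forcing was built by `class_volume_forcing()`; the per-atresia-day full
form always uses the adaptive solver. Class-volume and P4 forcing are
piecewise-linear between scan days (step forcing is available by
configuration); the forcing at a fractional day interpolates each
follicle's own diameter track.

## Inference

The training set combines measured E2 (weight 5, assumed noise variance
0.10 × value) with gap-filling simulated values (weight 1, variance
0.50 × value): E2 is assayed only at cycle start and end (days 0–6 and
day 15 onward, at 8-h intervals), and the gap is filled by fitting the
two-parameter summed-diameter baseline
$dE2/dt = c_{FollE2}\,\mathrm{Foll}^2 - c_{E2} E2$ (with Foll the summed
diameters of all ever-dominant follicles) to the measured segments and
simulating the middle of the cycle. A full multi-hormone endocrine system
could supply those gap values instead; reproducing one is out of scope, so
the single-equation baseline fitted to the measured segments stands in for
it — a documented design choice. "Variance equal to 10% of the value" is
read literally as $\sigma_i^2 = 0.10\,y_i$ (variance, not standard
deviation, proportional to value); a $\sigma \propto y$ switch exists for
robustness checks. The value entering the variance rule is floored at 0.05
(scaled units) so that near-zero observations keep a realistic assay noise
floor instead of acquiring near-infinite precision.

Point estimation is bound-constrained Levenberg–Marquardt on the weighted
residuals. The finite-difference step for the residual Jacobian is set well
above the simulator's discretisation noise. Because the sharp P4 threshold
creates local minima in $T$, `wnls_fit()` accepts extra starts and keeps
the best objective; the studies use threshold starts at 4× and ¼×.

The prior is log-uniform: each $\log_{10}\theta_j$ uniform on the interval
between $0.6 L_j$ and $1.6 L_j$, $L_j = \log_{10}\hat\theta_j$, endpoints
ordered so negative logs work. Near $L_j = 0$ the interval degenerates;
intervals narrower than 0.2 log₁₀-units are widened symmetrically to that
minimum. The likelihood is independent Gaussian with the per-point
variances above. Sampling is adaptive random-walk Metropolis in log₁₀
space: Robbins–Monro tuning of a global proposal scale toward 30%
acceptance plus a Haario-style empirical-covariance proposal shape during
burn-in, frozen afterwards so the retained chain is a valid Metropolis
sampler; everything is reproducible from the seed. Credible intervals are
equal-tailed quantiles (90% and 95% both supported); pairwise regions for
plotting are convex hulls of the central fraction of draws. Prediction
bands re-simulate the trajectory for each draw and take per-time-point
quantiles, dropping (and counting) failed draws.

$E2(0)$ can be fitted jointly with the rates but is excluded from the
sampled parameter vector, matching the eleven-parameter uncertainty
analysis ($e_1, e_2, e_3, a_3, n, T, T_I, n_I, \alpha_{E2}, m, e_4$).
The chosen parameter subset is sampled jointly.

## Sensitivity

`scaled_jacobian()` differentiates the integrated trajectory by central (or
forward) finite differences and scales relative-relative:
$S_{ij} = (\theta_j / E2(t_i))\,\partial E2(t_i)/\partial\theta_j$
(semi-scaled and unscaled variants are selectable, since "scaled Jacobian"
admits several conventions — rankings, not magnitudes, are the robust
quantity to compare). A guard enforces that the adaptive integrator's
tolerance sits well below the squared step; the deterministic fast path is
exempt. Under pure clearance the scaled sensitivity to $\alpha_{E2}$ is
analytically $-\alpha_{E2} t$, which the tests verify.

## What the synthetic generator emulates

No follicle-tracking or hormone dataset is distributed with the package, so
`generate_cycle()` builds one: a 23-day cycle with three follicular waves
emerging on days 1, 9 and 17, four follicles per wave starting at 4–5 mm,
piecewise-linear growth at 1.2 mm/day, deviation near 8.5 mm after which
one follicle per wave (two with `double_ovulation`) grows on toward 14 mm
while subordinates peak near 7.7 mm and shrink at 1 mm/day. Dominants of
non-final waves lose dominance six days after wave emergence —
first-wave dominance is lost around days 7–9 of the cycle — so the 90%
rule fires within a day or two and an atretic dominant from the previous
wave is present at each later wave emergence. P4 rises sigmoidally from
day 3 to its plateau and decays at 1.5 d⁻¹ after luteolysis on day 17,
crossing the Hill threshold $T$ late in the cycle so the preovulatory E2
surge appears. CL size is emitted as a monotone transform of P4 for
interface completeness; a mechanistic CL-to-P4 model is out of scope (P4 is
an input). Follicles below 2 mm are not
recorded, mimicking the ultrasound detection floor.

Observations sample the simulated E2 at 8-h intervals *only* inside the
measured windows (days 0–6 and 15–end) and P4 daily everywhere (8-hourly in
the windows), with Gaussian noise of variance = fraction × value. The
generator's noise fractions default to 0.01 (measured) and 0.05
(simulated): on the 0–1 scale this is a 15–20% coefficient of variation at
mid-range values, typical of field E2/P4 immunoassays. The larger fractions
(0.10/0.50) retained in the training-set defaults are the *inference
assumptions* of the identification workflow, deliberately conservative
relative to the generated noise; the credible intervals are therefore
somewhat conservative too, which the recovery study's coverage reflects.

What the generator does **not** emulate: stochastic growth-rate variation
between follicles (a diameter-jitter option exists but defaults to 0, so
noise enters only through observation error), operator and probe error in
diameter readings, FSH/LH dynamics, herd-level variation, and any
correlation between wave timing and P4 beyond the built-in luteolysis
schedule. Passing tests therefore demonstrate internal consistency of the
method under its own assumptions — not field validity on real ultrasound
data, which would require tracking and assay data from multiple animals.

## Study protocols and problem sizes

`run_recovery_study()` (the package's parameter-recovery protocol) fits
($e_3, \alpha_{E2}, T$) — the production, clearance and threshold
parameters — on each of 20 seeded synthetic cycles and samples 1000
posterior draws after 500 burn-in iterations per replicate, recording
relative errors and 95% credible coverage. The remaining parameters are
held at their generating values: fitting all eleven from a single noisy
cycle is poorly identified (the source uncertainty analysis itself shows
very wide regions for $T_I$ and $n_I$), and a three-parameter subset keeps
each replicate's fit well-posed. Training uses the measured windows only,
and the generator's P4 curve drives the model: the observation model
describes E2 assay error, and feeding assay-noisy P4 back as ODE forcing
would introduce an error source the model does not describe.
`run_model_comparison()` refits both the granulosa-volume model and the
summed-diameter baseline on 10 seeded cycles and compares weighted SSE on
identical training points. These sizes keep the full studies at a couple of
minutes on a single core while leaving the Monte-Carlo fractions stable to
a few percent.

## Known limitations

* The granulosa quadratic is a single curve for all follicles; wall-thickness
  differences between dominant and subordinate follicles of equal size are
  absorbed into the class production rates, not the geometry.
* The P4-branch atretic constants of the full model ($a_5 \dots$) were never
  published; the full form accepts them as free inputs and defaults to the
  geometric decay implied by $a_4$ and $m_2$.
* Ovulation timing, preovulatory-vs-nonovulatory dominant distinction, and
  descaling to concentration units are out of scope.
* The atresia rule is diameter-only; basal versus antral atresia subtypes
  are indistinguishable in vivo and not modelled.

## A worked example

```{r example, eval = FALSE}
cyc <- generate_cycle(synthetic_cycle_spec(seed = 1))
params <- scale_production_rates(e2_params())
sim <- simulate_e2(params, cyc$tracks, cyc$p4, c(0, 23), scale = "data")
plot(sim$time_days, sim$value_scaled, type = "l",
     xlab = "day of cycle", ylab = "scaled E2")

obs <- generate_observations(params, cyc)
training <- build_training_set(obs$e2_measured)
forcing <- class_volume_forcing(cyc$tracks, t0 = 0, scale = "data")
init <- theta_from_params(params, c("e3", "alpha_E2", "T"))
fit <- wnls_fit(training, params, forcing, cyc$p4, c(0, 23),
                theta_init = init * c(1.2, 0.9, 1.3))
fit$theta
```
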