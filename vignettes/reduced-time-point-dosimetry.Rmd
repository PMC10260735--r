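---
title: "Reduced time point dosimetry: models, simulation design and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reduced time point dosimetry: models, simulation design and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tiafit)
library(dplyr)
```

## The problem

Internal dosimetry after radiopharmaceutical therapy (the motivating case is
¹⁷⁷Lu-DOTATATE for neuroendocrine tumors) needs the time-integrated activity
(TIA) of each organ and tumor,
$\tilde{A} = \int_0^\infty A(t)\,dt$ in MBq·h, which scales to absorbed dose
through S-values. The gold standard is a multi-point SPECT/CT time–activity
curve fit; each additional scan costs patient and camera time. `tiafit`
quantifies what is lost when TIA is instead estimated from one, two or three
imaging time points, and which sampling schedules minimize that loss.

## Kinetic models and reference TIA

Two washout models are supported, chosen per subject and structure:

* monoexponential $A(t) = C e^{-\lambda t}$, TIA $= C/\lambda$;
* biexponential $A(t) = C\,(e^{-\lambda_1 t} - e^{-\lambda_2 t})$ with
  $0 < \lambda_1 < \lambda_2$ (uptake phase rising to a peak at
  $\ln(\lambda_2/\lambda_1)/(\lambda_2-\lambda_1)$, then terminal clearance),
  TIA $= C\,(1/\lambda_1 - 1/\lambda_2)$.

All rate constants are *effective* (physical decay × biological clearance),
in 1/h; amplitudes are in MBq. Richer models (three or more exponential
terms) are deliberately out of scope: with four reference samples they are
underconstrained.

The multi-point reference fit selects between the two models by Akaike
information criterion, $AIC = n\ln(\max(rss, floor)/n) + 2k$ with a
small-sample correction discussed below; the analytic TIA of the winning
model is the reference against which every reduced estimate is scored.

## Reduced time point estimators

* **Hänscheid:** $\tilde{A} = A(t)\cdot 2t/\ln 2$. Writing $u = t/T_{1/2}$,
  the estimate-to-truth ratio for a monoexponential subject is
  $2u\,2^{-u}$: exactly 1 at $u = 1$, never above
  $2/(e\ln 2) \approx 1.0615$, and unboundedly low far from the half-life.
  The method therefore has a hard +6.1% bias ceiling but no floor — the
  asymmetric risk is underestimation.
* **Madsen:** $\tilde{A} = A(t)\,e^{\lambda_{pop}t}/\lambda_{pop}$, exact at
  every time for a subject whose effective decay constant equals the
  population value, with error growing with both $|\lambda-\lambda_{pop}|$
  and $t$.
* **2TP/3TP:** unweighted monoexponential least squares through the sampled
  points; two points give the exact closed form
  $\lambda = \ln(a_1/a_2)/(t_2-t_1)$.

Because the population half-life entering Madsen is rarely published per
structure, `population_lambda()` derives it from a reference cohort as
$\ln 2 / \mathrm{median}(T_{1/2,\mathrm{eff}})$, using the terminal-phase
half-life $\ln 2/\lambda_1$ for biexponential subjects; the median resists
the heavy right tail of clearance half-lives. A configured value always
overrides the derivation.

## Sampling schedules

Simulation grids: 240 single times (1–240 h hourly); all
$\binom{60}{2} = 1770$ pairs on the 4-h grid; and 3294 triples built from
day slots — day 0 offers 4 h and 8 h, days 1–9 the beginning/middle/end of
day times $24d, 24d{+}4, 24d{+}8$, day 10 only 240 h — with at most one scan
per day. The one-scan-per-day rule is the whole of the feasibility
constraint: it exactly generates the 3294 enumerated schedules (verified in
the tests by brute-force enumeration and by the elementary symmetric
polynomial $e_3$ of the slot multiplicities), whereas adding a further
overnight-adjacency exclusion would shrink the set.

Clinical data are grouped into four scan windows: t_D0 (3–5 h),
t_D1-2 (21–52 h), t_D3-5 (71–126 h), t_D6-8 (144–194 h), inclusive at both
ends. Scan times between windows are excluded from period-grouped analyses
with a warning rather than force-assigned — clinical series do not always
match the nominal windows, and silently stretching a window would blur the
schedule labels being compared.

## The virtual cohort generator

`simulate_cohort()` draws each kinetic parameter independently from a
truncated lognormal distribution, parameterized by the median
$\mu = \exp(\overline{\ln x})$ and shape $s = \mathrm{SD}(\ln x)$, truncated
by rejection to $[lower, upper]$. Truncation keeps every simulated curve
inside a clinically attested range; bounds default to the data range in
`estimate_lognormal()` and should be widened to literature half-life cutoffs
when available. The mono/biexponential mix is controlled by `frac_mono`
(`round(n * frac_mono)` mono curves), and biexponential draws are rejected
until $\lambda_1 < \lambda_2$.

What the generator emulates: per-structure dispersion and skew of fitted
curve parameters, the mono/biexp mixture, bounded half-lives, and
activity-dependent measurement noise on every sample. What it does not:
correlation between parameters (amplitude and clearance are sampled
independently; a joint sampler would need the unpublished clinical
covariance), circadian or inter-cycle kinetics, multi-phase clearance beyond
two exponentials, and image-domain effects (partial volume, registration
error) other than through the noise law. Passing tests on simulated cohorts
therefore demonstrate correctness of the estimation machinery and the
direction of scheduling effects, not the magnitude of errors in any real
patient population.

The shipped `default_structure_specs()` (kidney, liver, spleen, tumor) are
**synthetic surrogates** chosen once to be clinically plausible — e.g.
kidney effective half-life median 50 h, shape 0.30, bounds 20–120 h; tumor
slower (median 90 h) with much wider amplitude dispersion ($s = 0.8$) —
because per-patient fitted parameter distributions are not published.
Analyses of real cohorts should build specs with `estimate_lognormal()`.

## Measurement noise

Relative SD of quantified activity is modelled as a power law
$\sigma_{rel}(A) = c\,A^{b}$, fitted by OLS on the log–log scale from
repeat-measurement points (`fit_power_law()`), with the abscissa expressed
as *effective activity* at the 25-min reference scan length
(`effective_activity()`). Sampled activities are perturbed as
$N(a, (\sigma_{rel}(a)\,a)^2)$; negative draws are floored at zero and
counted, because a quantified activity cannot be negative and a silent
exclusion would bias the late-time samples where the floor matters most. A
zero activity then fails the log-based two-point fit, and that failure is
propagated and counted rather than patched.

The default coefficients ($c = 0.10$, $b = -0.30$, i.e. ≈2.5% relative SD at
100 MBq rising to ≈20% at 0.1 MBq) are synthetic defaults of plausible
magnitude for quantitative ¹⁷⁷Lu SPECT, not fitted phantom values; studies
with their own phantom data should fit and pass their own model.

## Numerical choices

* **AIC variant.** The default is the small-sample corrected
  $AIC_c = AIC + 2k(k{+}1)/\max(n-k-1, 1)$. The clamp matters precisely at
  the 4-point reference with the 3-parameter biexponential ($n = k + 1$),
  where the textbook correction diverges and would reject the biexponential
  no matter how decisively it fits; the clamp keeps a strong but finite
  parsimony penalty. Plain AIC is selectable, but with a single residual
  degree of freedom it follows noise readily.
* **RSS floor.** $10^{-12}\,\overline{a}^2 n$ inside the AIC logarithm
  guards $\log 0$ for interpolating fits; when both models sit at the floor
  the monoexponential wins (parsimony tie-break).
* **Fit failures are data, not errors.** A reduced fit whose decay constant
  is non-positive has a divergent TIA; it is flagged
  (`nonpositive_rate`/`nonpositive_activity`), excluded from the error
  metrics and counted in `n_failed`, never clamped — pathological schedules
  should look pathological in the output.
* **Optimizers.** Single fits use Levenberg–Marquardt (`minpack.lm`), the
  biexponential through the raw residual interface with the constraint
  enforced by the parameterization $\lambda_1 = e^{p_1}$,
  $\lambda_2 = \lambda_1 + e^{p_2}$ and multi-start over
  $\lambda_2/\lambda_1 \in \{3, 10, 30, 100\}$ (near-monoexponential data
  make the 3-parameter Jacobian rank-deficient, which the formula-interface
  wrapper rejects even at a valid optimum). Grid evaluation over thousands
  of schedules uses a vectorized damped Gauss–Newton monoexponential fitter
  across the whole cohort at once, initialized from the per-curve log-linear
  regression; it is cross-checked against the Levenberg–Marquardt reference
  in the test suite (agreement to ~1e-5 relative in TIA on noisy cases).
* **Noise realization policy.** Each curve is sampled once per grid time and
  perturbed once; all schedules share those draws. This mirrors sampling a
  full simulated study once and then reading different schedules off it, and
  makes schedule comparisons paired rather than independently noisy.
* **Tie-breaks.** Equal-RMSE schedules resolve to the earliest last imaging
  time (least burden), then lexicographic times.
* **Determinism.** Every stochastic step (cohort draws, noise) takes a seed;
  fixed configuration plus seed reproduces results byte-for-byte.

## Problem sizes used in the shipped analyses

The test suite and `scripts/acceptance.R` run cohorts of 250 curves for the
surrogate kidney-like study (the standard virtual-cohort size used
throughout), full 240-time STP and 1770-schedule 2TP grids, the full
3294-schedule 3TP grid in the acceptance script, and subsampled 3TP grids
(every 150th schedule) in the fast unit tests; Monte-Carlo recovery checks
use 10⁴–10⁵ draws. These sizes were chosen as the smallest that make the
stochastic assertions stable across seeds.

## Known limitations

* Error magnitudes depend on the surrogate population and noise parameters;
  only directional findings (optimal STP time near the population
  half-life, early-plus-late superiority for 2TP, noise blow-up for close
  late pairs) should be generalized.
* Independent parameter sampling slightly misstates the TIA dispersion a
  correlated population would show.
* The clinical mode requires at least four scans per subject-structure to
  form a reference; series failing that are skipped, not imputed.
* Absorbed dose (Gy), S-values and organ masses are out of scope; outputs
  stop at TIA.
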