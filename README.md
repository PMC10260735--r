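# tiafit

Reduced time point estimation of time-integrated activity (TIA) for
radiopharmaceutical dosimetry.

After a therapy such as ¹⁷⁷Lu-DOTATATE peptide receptor radionuclide therapy,
patient-specific dosimetry requires the time-integrated activity
$\tilde{A} = \int_0^\infty A(t)\,dt$ of each organ and tumor, conventionally
obtained from a multi-point SPECT/CT time–activity curve. Repeat imaging
burdens both patient and clinic, so a central practical question is: **how
much TIA accuracy is lost when only 1, 2 or 3 imaging time points are used,
and which imaging schedules are optimal?** `tiafit` is a toolkit for
answering that question, for dosimetry researchers and medical physicists. It
provides:

- **Kinetic models and reference fitting.** Monoexponential
  $A(t) = C e^{-\lambda t}$ and biexponential
  $A(t) = C (e^{-\lambda_1 t} - e^{-\lambda_2 t})$ time–activity curves with
  analytic TIA ($C/\lambda$ and $C(1/\lambda_1 - 1/\lambda_2)$), nonlinear
  least-squares fitting, and AIC-based model selection for multi-point
  reference data.
- **Reduced time point estimators.** The Hänscheid approximation
  $\tilde{A} = A(t)\,2t/\ln 2$, the Madsen population-half-life formula
  $\tilde{A} = A(t)\,e^{\lambda_{pop} t}/\lambda_{pop}$, and monoexponential
  refits through 2 or 3 sampled points.
- **Schedule enumeration.** The 240-time single-time-point grid, all 1770
  two-point schedules on a 4-h grid, the 3294 three-point day-slot schedules
  (at most one scan per day), and the 6 + 4 clinical time-period
  combinations over the windows t_D0 (3–5 h), t_D1-2 (21–52 h),
  t_D3-5 (71–126 h) and t_D6-8 (144–194 h).
- **Virtual cohorts with realistic noise.** Truncated lognormal sampling of
  kinetic parameters per structure (kidney, liver, spleen, tumor), and a
  power-law measurement-noise model $\sigma_{rel}(A) = c\,A^{b}$ fitted by
  log–log OLS from repeat-measurement data.
- **Schedule evaluation.** RMSE, mean percent error (with SD and range) and
  mean absolute percent error of every schedule against the reference TIA,
  minimum-RMSE optimal-schedule selection, 2TP error heatmaps, and a
  `run_pipeline()` orchestrator for both simulated and measured clinical
  tables.

## Worked example

Simulate a kidney-like cohort of 250 monoexponential curves (effective
half-life lognormal, median ≈ 50 h, truncated to 20–120 h), add
activity-dependent measurement noise, and find the optimal single imaging
time for the Madsen estimator:

```r
library(tiafit)
library(dplyr)

spec <- structure_spec(
  "kidney_like", frac_mono = 1,
  mono = list(C   = lognormal_spec(50, 0.4, 10, 250),
              lam = lognormal_spec(log(2) / 50, 0.3,
                                   log(2) / 120, log(2) / 20)))
cohort <- simulate_cohort(spec, n = 250, seed = 11)

res <- evaluate_method(cohort, "madsen",
                       noise = default_noise_model(),
                       lam_pop = population_lambda(cohort),
                       seed = 21)
optimal_schedule(res) |>
  select(method, t1, rmse, mpe, sd_pe, mape)
#> # A tibble: 1 × 6
#>   method    t1  rmse   mpe sd_pe  mape
#>   <chr>  <dbl> <dbl> <dbl> <dbl> <dbl>
#> 1 madsen    78  293. -4.44  8.40  6.33
```

Imaging at 78 h post-injection minimizes the cohort RMSE (293 MBq·h); at
that time the Madsen estimate is biased −4.4% on average with 8.4% SD across
subjects and a 6.3% mean absolute error. Two-point schedules do better when
an early scan is paired with a late one:

```r
res2 <- evaluate_method(cohort, "2tp", noise = default_noise_model(),
                        seed = 22)
optimal_schedule(res2) |> select(t1, t2, rmse, mpe, sd_pe, mape)
#> # A tibble: 1 × 6
#>      t1    t2  rmse    mpe sd_pe  mape
#>   <dbl> <dbl> <dbl>  <dbl> <dbl> <dbl>
#> 1    36   176  104. -0.440  2.99  2.39
plot_pe_heatmap(res2)          # MPE over all 1770 (t1, t2) schedules
```

Fitting measured data uses data-frame-first verbs throughout:

```r
d <- tibble::tibble(time_h = c(4, 24, 96, 168),
                    activity_MBq = c(29.0, 69.6, 38.3, 18.6))
fit <- select_by_aic(d)     # mono vs biexp reference fit
glance(fit)                 # kind, rss, aic, half-life, TIA
autoplot(fit)
```

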