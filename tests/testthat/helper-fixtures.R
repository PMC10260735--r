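# Shared fixtures: small deterministic cohorts and sampled tables built in
# code (no stored data).

ta_from_model <- function(model, times) {
  tibble::tibble(time_h = times, activity_MBq = eval_activity(model, times))
}

# All-monoexponential cohort with lognormal half-lives (median `hl_med` h).
mono_cohort_spec <- function(hl_med = 50, s = 0.3, hl_lo = 20, hl_hi = 120,
                             C_mu = 50, C_s = 0.4) {
  structure_spec(
    "kidney_like", frac_mono = 1,
    mono = list(
      C = lognormal_spec(C_mu, C_s, C_mu / 5, C_mu * 5),
      lam = lognormal_spec(log(2) / hl_med, s, log(2) / hl_hi, log(2) / hl_lo)))
}

# Degenerate cohort: single decay constant, amplitudes free.
fixed_lambda_cohort <- function(n, lam = log(2) / 72, seed = 1) {
  spec <- structure_spec(
    "fixed_lam", frac_mono = 1,
    mono = list(C = lognormal_spec(50, 0.5, 5, 500),
                lam = lognormal_spec(lam, 0, lam / 2, lam * 2)))
  simulate_cohort(spec, n = n, seed = seed)
}

# Random valid mono/biexp parameter draws for property checks.
random_mono_params <- function(n, seed) {
  withr::with_seed(seed, tibble::tibble(
    C = exp(stats::runif(n, log(1), log(500))),
    lam = exp(stats::runif(n, log(0.002), log(0.1)))))
}

random_biexp_params <- function(n, seed) {
  withr::with_seed(seed, {
    lam1 <- exp(stats::runif(n, log(0.002), log(0.05)))
    tibble::tibble(
      C = exp(stats::runif(n, log(1), log(500))),
      lam1 = lam1,
      lam2 = lam1 * exp(stats::runif(n, log(2), log(50))))
  })
}
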