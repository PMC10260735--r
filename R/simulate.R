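#' Truncated lognormal parameter distribution
#'
#' Kinetic fit parameters across a patient population are strongly
#' right-skewed and are modelled as lognormal, parameterized the way the
#' clinical estimates are formed: `mu` is the exponential of the mean of the
#' natural logarithm of the data (the lognormal median) and `s` is the
#' standard deviation of the natural logarithm. Sampling is restricted to
#' `[lower, upper]` so simulated curves stay within the clinically observed
#' (or literature-reported) range.
#'
#' @param mu Scale parameter (median), in the parameter's units (> 0).
#' @param s Shape parameter, SD of the log (>= 0).
#' @param lower,upper Truncation bounds (`0 <= lower < upper`; `upper` may be
#'   `Inf`).
#' @return A `lognormal_spec` object.
#' @export
lognormal_spec <- function(mu, s, lower = 0, upper = Inf) {
  stopifnot(is.numeric(mu), is.numeric(s))
  if (!(mu > 0)) stop("lognormal_spec: mu must be > 0", call. = FALSE)
  if (s < 0) stop("lognormal_spec: s must be >= 0", call. = FALSE)
  if (!(lower >= 0 && upper >= lower)) {
    stop("lognormal_spec: need 0 <= lower <= upper", call. = FALSE)
  }
  structure(list(mu = mu, s = s, lower = lower, upper = upper),
            class = "lognormal_spec")
}

#' @export
print.lognormal_spec <- function(x, ...) {
  cat(sprintf("<lognormal_spec> mu = %.4g, s = %.4g, bounds [%.4g, %.4g]\n",
              x$mu, x$s, x$lower, x$upper))
  invisible(x)
}

#' Estimate a lognormal spec from observed parameter values
#'
#' `mu = exp(mean(ln x))`, `s = sd(ln x)` (sample SD). Default truncation
#' bounds are the observed minimum and maximum; pass `lower`/`upper` to widen
#' them to literature cutoffs (e.g. a smaller reported minimum or larger
#' reported maximum effective half-life).
#'
#' @param values Positive observations (n >= 2).
#' @param lower,upper Optional bound overrides.
#' @return A `lognormal_spec`.
#' @examples
#' estimate_lognormal(c(1, exp(2)))   # mu = e, s = sqrt(2)
#' @export
estimate_lognormal <- function(values, lower = NULL, upper = NULL) {
  if (any(values <= 0)) {
    stop("estimate_lognormal: all values must be > 0", call. = FALSE)
  }
  if (length(values) < 2) {
    stop("estimate_lognormal: need at least 2 values", call. = FALSE)
  }
  lv <- log(values)
  lognormal_spec(mu = exp(mean(lv)), s = stats::sd(lv),
                 lower = lower %||% min(values),
                 upper = upper %||% max(values))
}

#' Sample from a truncated lognormal distribution
#'
#' Rejection sampling: lognormal draws outside `[lower, upper]` are discarded
#' and redrawn. If the truncation interval carries essentially no probability
#' mass (more than `max_reject` consecutive rejections without a single
#' acceptance), an error is raised rather than looping forever.
#'
#' @param spec A `lognormal_spec`.
#' @param n Number of samples.
#' @param max_reject Consecutive-rejection limit.
#' @return Numeric vector of `n` draws inside the bounds.
#' @export
sample_truncated <- function(spec, n = 1, max_reject = 1e4) {
  stopifnot(inherits(spec, "lognormal_spec"))
  if (spec$s == 0) {
    if (spec$mu < spec$lower || spec$mu > spec$upper) {
      stop("sample_truncated: degenerate spec outside bounds", call. = FALSE)
    }
    return(rep(spec$mu, n))
  }
  out <- numeric(0)
  consecutive <- 0
  while (length(out) < n) {
    m <- max(2 * (n - length(out)), 100)
    x <- stats::rlnorm(m, meanlog = log(spec$mu), sdlog = spec$s)
    keep <- x[x >= spec$lower & x <= spec$upper]
    if (!length(keep)) {
      consecutive <- consecutive + m
      if (consecutive > max_reject) {
        stop("sample_truncated: truncation interval has ~zero mass",
             call. = FALSE)
      }
    } else {
      consecutive <- 0
      out <- c(out, keep)
    }
  }
  out[seq_len(n)]
}

#' Per-structure cohort specification
#'
#' Describes the statistical population of time-activity curves for one
#' structure: the fraction of subjects whose kinetics are monoexponential,
#' and a truncated lognormal distribution for each kinetic parameter of each
#' fit type. The half-life-based truncation convention applies to the
#' terminal rate (`lam` for mono, `lam1` for biexp), whose bounds typically
#' come from literature half-life cutoffs; the fast uptake rate `lam2` is
#' bounded by the data range alone.
#'
#' @param name Structure name (e.g. `"kidney"`).
#' @param frac_mono Fraction of monoexponential subjects in `[0, 1]`.
#' @param mono Named list of `lognormal_spec`s for `C` and `lam` (required if
#'   `frac_mono > 0`).
#' @param biexp Named list of `lognormal_spec`s for `C`, `lam1`, `lam2`
#'   (required if `frac_mono < 1`).
#' @return A `structure_spec` object.
#' @export
structure_spec <- function(name, frac_mono, mono = NULL, biexp = NULL) {
  if (!(frac_mono >= 0 && frac_mono <= 1)) {
    stop("structure_spec: frac_mono must be in [0, 1]", call. = FALSE)
  }
  if (frac_mono > 0) {
    stopifnot(is.list(mono), all(c("C", "lam") %in% names(mono)))
  }
  if (frac_mono < 1) {
    stopifnot(is.list(biexp), all(c("C", "lam1", "lam2") %in% names(biexp)))
  }
  structure(list(name = name, frac_mono = frac_mono,
                 mono = mono, biexp = biexp),
            class = "structure_spec")
}

#' @export
print.structure_spec <- function(x, ...) {
  cat(sprintf("<structure_spec> %s: %.0f%% mono / %.0f%% biexp\n",
              x$name, 100 * x$frac_mono, 100 * (1 - x$frac_mono)))
  invisible(x)
}

#' Default synthetic cohort specifications
#'
#' Surrogate population parameters for kidney, healthy liver, spleen and
#' tumor. The shapes are clinically plausible for 177Lu-DOTATATE — e.g.
#' kidney effective half-life lognormal with median about 50 h truncated to
#' 20–120 h, tumors slower and far more dispersed in amplitude — but they are
#' *synthetic defaults*, not estimates from any patient dataset (per-patient
#' fitted distributions are not published). Use [estimate_lognormal()] on
#' reference fits to build specs from real data.
#'
#' @return Named list of `structure_spec` objects.
#' @export
default_structure_specs <- function() {
  hl <- function(h) log(2) / h   # half-life (h) -> decay constant (1/h)
  list(
    kidney = structure_spec(
      "kidney", frac_mono = 0.7,
      mono = list(C = lognormal_spec(50, 0.4, 10, 250),
                  lam = lognormal_spec(hl(50), 0.30, hl(120), hl(20))),
      biexp = list(C = lognormal_spec(60, 0.4, 10, 300),
                   lam1 = lognormal_spec(hl(50), 0.30, hl(120), hl(20)),
                   lam2 = lognormal_spec(0.15, 0.5, 0.04, 1.0))),
    liver = structure_spec(
      "liver", frac_mono = 0.8,
      mono = list(C = lognormal_spec(150, 0.4, 30, 600),
                  lam = lognormal_spec(hl(70), 0.30, hl(160), hl(30))),
      biexp = list(C = lognormal_spec(180, 0.4, 30, 700),
                   lam1 = lognormal_spec(hl(70), 0.30, hl(160), hl(30)),
                   lam2 = lognormal_spec(0.12, 0.5, 0.03, 0.8))),
    spleen = structure_spec(
      "spleen", frac_mono = 0.8,
      mono = list(C = lognormal_spec(30, 0.4, 5, 150),
                  lam = lognormal_spec(hl(65), 0.25, hl(150), hl(30))),
      biexp = list(C = lognormal_spec(35, 0.4, 5, 180),
                   lam1 = lognormal_spec(hl(65), 0.25, hl(150), hl(30)),
                   lam2 = lognormal_spec(0.12, 0.5, 0.03, 0.8))),
    tumor = structure_spec(
      "tumor", frac_mono = 0.6,
      mono = list(C = lognormal_spec(20, 0.8, 1, 200),
                  lam = lognormal_spec(hl(90), 0.40, hl(300), hl(30))),
      biexp = list(C = lognormal_spec(25, 0.8, 1, 250),
                   lam1 = lognormal_spec(hl(90), 0.40, hl(300), hl(30)),
                   lam2 = lognormal_spec(0.10, 0.5, 0.02, 0.8)))
  )
}

#' Simulate a virtual cohort of time-activity curves
#'
#' Draws `round(n * frac_mono)` monoexponential and `n - round(n * frac_mono)`
#' biexponential curves, each kinetic parameter sampled independently from
#' its truncated lognormal spec. Biexponential draws violating the shape
#' constraint `lam1 < lam2` (curve must rise then clear) are redrawn.
#'
#' @param spec A `structure_spec`.
#' @param n Cohort size (default 250 curves per structure).
#' @param seed Optional integer seed for reproducibility; when `NULL` the
#'   current RNG state is used.
#' @return A tibble of curve parameters: `curve_id`, `structure`, `kind`,
#'   `C`, `lam1`, `lam2` (`NA` for mono rows). Pipe into [analytic_tia()] for
#'   reference TIAs.
#' @examples
#' cohort <- simulate_cohort(default_structure_specs()$kidney, n = 20, seed = 1)
#' analytic_tia(cohort)
#' @export
simulate_cohort <- function(spec, n = 250, seed = NULL) {
  stopifnot(inherits(spec, "structure_spec"))
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  n_mono <- round(n * spec$frac_mono)
  n_bi <- n - n_mono

  rows <- list()
  if (n_mono > 0) {
    rows$mono <- tibble::tibble(
      kind = "mono",
      C = sample_truncated(spec$mono$C, n_mono),
      lam1 = sample_truncated(spec$mono$lam, n_mono),
      lam2 = NA_real_)
  }
  if (n_bi > 0) {
    lam1 <- sample_truncated(spec$biexp$lam1, n_bi)
    lam2 <- sample_truncated(spec$biexp$lam2, n_bi)
    for (i in seq_len(1000)) {
      bad <- !(lam1 < lam2)
      if (!any(bad)) break
      lam1[bad] <- sample_truncated(spec$biexp$lam1, sum(bad))
      lam2[bad] <- sample_truncated(spec$biexp$lam2, sum(bad))
    }
    if (any(!(lam1 < lam2))) {
      stop("simulate_cohort: could not satisfy lam1 < lam2 within the bounds",
           call. = FALSE)
    }
    rows$biexp <- tibble::tibble(
      kind = "biexp",
      C = sample_truncated(spec$biexp$C, n_bi),
      lam1 = lam1, lam2 = lam2)
  }

  out <- dplyr::bind_rows(rows)
  dplyr::bind_cols(
    tibble::tibble(curve_id = seq_len(nrow(out)), structure = spec$name),
    out)
}

#' Sample simulated curves on a schedule, optionally with noise
#'
#' Evaluates each curve at each schedule time and, when a noise model is
#' supplied, perturbs every sampled activity with a normal draw whose SD
#' follows the power law (see [apply_noise()]).
#'
#' @param curves Curve tibble (from [simulate_cohort()] or built by hand)
#'   with columns `curve_id`, `kind`, `C`, `lam1`, `lam2`.
#' @param times Sampling times, hours (> 0).
#' @param noise Optional `power_law_noise`.
#' @param seed Optional integer seed (noise draws only).
#' @return Long tibble: `curve_id`, `time_h`, `activity_MBq` (noisy when
#'   `noise` is supplied) and `activity_true_MBq`.
#' @export
sample_schedule <- function(curves, times, noise = NULL, seed = NULL) {
  check_curve_frame(curves)
  if (any(times <= 0)) stop("sample_schedule: times must be > 0", call. = FALSE)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  out <- tidyr::crossing(
    dplyr::select(tibble::as_tibble(curves), dplyr::all_of(c("curve_id", "kind", "C", "lam1", "lam2"))),
    tibble::tibble(time_h = sort(times)))
  out$activity_true_MBq <- activity_at(out$kind, out$C, out$lam1, out$lam2,
                                       out$time_h)
  out$activity_MBq <- if (is.null(noise)) {
    out$activity_true_MBq
  } else {
    as.numeric(apply_noise(out$activity_true_MBq, noise))
  }
  dplyr::select(out, dplyr::all_of(c("curve_id", "time_h", "activity_MBq",
                                     "activity_true_MBq")))
}
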