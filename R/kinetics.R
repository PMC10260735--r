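#' Kinetic curve models for time-activity analysis
#'
#' Construct a monoexponential (`mono_curve()`) or biexponential
#' (`biexp_curve()`) time-activity model. A monoexponential curve has the form
#' \eqn{A(t) = C e^{-\lambda t}} and describes a structure observed only during
#' washout; a biexponential curve
#' \eqn{A(t) = C (e^{-\lambda_1 t} - e^{-\lambda_2 t})} additionally captures
#' the uptake phase, rising from zero to a peak before clearing. Time is in
#' hours post-injection and activity in MBq throughout.
#'
#' @param C Amplitude, MBq. Must be positive.
#' @param lam Effective decay constant, 1/h (monoexponential). Must be positive
#'   for the time-integrated activity to be finite.
#' @param lam1,lam2 Slow (terminal clearance) and fast (uptake) rate constants,
#'   1/h, with `0 < lam1 < lam2` so the curve is positive for `t > 0`.
#' @return An object of class `curve_model`: a list with elements `kind`
#'   (`"mono"` or `"biexp"`), `C`, `lam1` and `lam2` (`NA` for mono).
#' @examples
#' m <- mono_curve(C = 100, lam = log(2) / 72)   # 72 h effective half-life
#' eval_activity(m, c(0, 72))                    # 100, 50
#' analytic_tia(m)
#'
#' b <- biexp_curve(C = 100, lam1 = 0.01, lam2 = 0.1)
#' analytic_tia(b)                               # 100 * (1/0.01 - 1/0.1)
#' @export
mono_curve <- function(C, lam) {
  stopifnot(is.numeric(C), is.numeric(lam), length(C) == 1, length(lam) == 1)
  if (!(C > 0)) stop("mono_curve: C must be > 0", call. = FALSE)
  if (!(lam > 0)) stop("mono_curve: lam must be > 0", call. = FALSE)
  structure(list(kind = "mono", C = C, lam1 = lam, lam2 = NA_real_),
            class = "curve_model")
}

#' @rdname mono_curve
#' @export
biexp_curve <- function(C, lam1, lam2) {
  stopifnot(is.numeric(C), is.numeric(lam1), is.numeric(lam2))
  if (!(C > 0)) stop("biexp_curve: C must be > 0", call. = FALSE)
  if (!(lam1 > 0 && lam2 > lam1)) {
    stop("biexp_curve: need 0 < lam1 < lam2", call. = FALSE)
  }
  structure(list(kind = "biexp", C = C, lam1 = lam1, lam2 = lam2),
            class = "curve_model")
}

#' @export
print.curve_model <- function(x, ...) {
  if (x$kind == "mono") {
    cat(sprintf("<curve_model mono> C = %.4g MBq, lam = %.4g /h (T1/2 = %.3g h)\n",
                x$C, x$lam1, log(2) / x$lam1))
  } else {
    cat(sprintf("<curve_model biexp> C = %.4g MBq, lam1 = %.4g /h, lam2 = %.4g /h\n",
                x$C, x$lam1, x$lam2))
  }
  invisible(x)
}

# Vectorized activity over parallel parameter/time vectors (recycled).
activity_at <- function(kind, C, lam1, lam2, t) {
  n <- max(length(kind), length(C), length(lam1), length(lam2), length(t))
  kind <- rep_len(kind, n)
  C <- rep_len(C, n)
  lam1 <- rep_len(lam1, n)
  t <- rep_len(t, n)
  out <- C * exp(-lam1 * t)
  bi <- kind == "biexp"
  if (any(bi)) {
    lam2 <- rep_len(lam2, n)
    out[bi] <- out[bi] - C[bi] * exp(-lam2[bi] * t[bi])
  }
  out
}

#' Evaluate a kinetic model's activity at given times
#'
#' @param model A `curve_model` from [mono_curve()] or [biexp_curve()].
#' @param t Times, hours post-injection (vectorized, `t >= 0`).
#' @return Activity in MBq at each `t`.
#' @export
eval_activity <- function(model, t) {
  stopifnot(inherits(model, "curve_model"), is.numeric(t))
  if (any(t < 0)) stop("eval_activity: t must be >= 0", call. = FALSE)
  activity_at(model$kind, model$C, model$lam1, model$lam2, t)
}

#' Analytic time-integrated activity (TIA)
#'
#' Integrates the kinetic model analytically from 0 to infinity:
#' \eqn{C/\lambda} for a monoexponential and
#' \eqn{C (1/\lambda_1 - 1/\lambda_2)} for a biexponential. The TIA (also
#' called cumulated activity) in MBq·h is the quantity that scales to absorbed
#' dose via S-values.
#'
#' For a data frame of curves (columns `kind`, `C`, `lam1`, `lam2`), returns
#' the same data frame with a `tia` column appended, so cohorts can be piped
#' through directly.
#'
#' @param model A `curve_model`, or a data frame of curve parameters.
#' @return A scalar TIA in MBq·h, or the input data frame with a `tia` column.
#' @export
analytic_tia <- function(model) {
  UseMethod("analytic_tia")
}

#' @export
analytic_tia.curve_model <- function(model) {
  if (!(model$lam1 > 0)) {
    stop("analytic_tia: divergent integral (lam <= 0)", call. = FALSE)
  }
  if (model$kind == "mono") {
    model$C / model$lam1
  } else {
    model$C * (1 / model$lam1 - 1 / model$lam2)
  }
}

#' @export
analytic_tia.data.frame <- function(model) {
  check_curve_frame(model)
  if (any(model$lam1 <= 0)) {
    stop("analytic_tia: divergent integral (lam1 <= 0)", call. = FALSE)
  }
  dplyr::mutate(
    tibble::as_tibble(model),
    tia = ifelse(.data$kind == "mono",
                 .data$C / .data$lam1,
                 .data$C * (1 / .data$lam1 - 1 / .data$lam2))
  )
}

check_curve_frame <- function(curves) {
  need <- c("kind", "C", "lam1", "lam2")
  missing <- setdiff(need, names(curves))
  if (length(missing)) {
    stop("curve table lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  bad <- curves$kind == "biexp" & !(curves$lam2 > curves$lam1)
  if (any(bad, na.rm = TRUE)) {
    stop("curve table: biexp rows require lam1 < lam2", call. = FALSE)
  }
  invisible(curves)
}

#' Single-time-point TIA estimators
#'
#' `hanscheid_tia()` implements the approximation
#' \eqn{TIA = A(t) \cdot 2t/\ln 2}, which is exact when the sampling time `t`
#' equals the structure's effective half-life and never overestimates a
#' monoexponential truth by more than the factor \eqn{2/(e \ln 2) \approx
#' 1.0615} (it has no lower bound, so late or early sampling can underestimate
#' badly). `madsen_tia()` implements
#' \eqn{TIA = A(t) \cdot e^{\lambda_{pop} t}/\lambda_{pop}}, which assumes a
#' population-average effective decay constant and is exact at every time for
#' a subject whose kinetics match the population.
#'
#' Both are vectorized over parallel `t` and `a` vectors, making them
#' convenient inside `dplyr::mutate()`.
#'
#' @param t Sampling time, hours post-injection (`t > 0`).
#' @param a Measured activity at `t`, MBq (`a >= 0`).
#' @param lam_pop Population effective decay constant, 1/h (`> 0`).
#' @return Estimated TIA, MBq·h.
#' @seealso [population_lambda()] to derive `lam_pop` from a reference cohort.
#' @export
hanscheid_tia <- function(t, a) {
  stopifnot(is.numeric(t), is.numeric(a))
  if (any(t <= 0)) stop("hanscheid_tia: t must be > 0", call. = FALSE)
  if (any(a < 0)) stop("hanscheid_tia: a must be >= 0", call. = FALSE)
  a * 2 * t / log(2)
}

#' @rdname hanscheid_tia
#' @export
madsen_tia <- function(t, a, lam_pop) {
  stopifnot(is.numeric(t), is.numeric(a), is.numeric(lam_pop))
  if (any(t <= 0)) stop("madsen_tia: t must be > 0", call. = FALSE)
  if (any(a < 0)) stop("madsen_tia: a must be >= 0", call. = FALSE)
  if (any(lam_pop <= 0)) stop("madsen_tia: lam_pop must be > 0", call. = FALSE)
  a * exp(lam_pop * t) / lam_pop
}

#' Population effective decay constant from a reference cohort
#'
#' Derives the population-average decay constant used by the Madsen estimator
#' as \eqn{\ln 2 / \mathrm{median}(T_{1/2,\mathrm{eff}})}, where a
#' biexponential subject's effective half-life is taken from the terminal
#' (slow) phase, \eqn{\ln 2/\lambda_1}. The median is robust to the heavy
#' right tail typical of clearance half-lives.
#'
#' @param curves Data frame of fitted curves with columns `kind`, `C`, `lam1`,
#'   `lam2` (e.g. from [simulate_cohort()] or reference fits).
#' @return Population decay constant, 1/h.
#' @export
population_lambda <- function(curves) {
  check_curve_frame(curves)
  if (any(curves$lam1 <= 0)) {
    stop("population_lambda: all lam1 must be > 0", call. = FALSE)
  }
  half_life <- log(2) / curves$lam1
  log(2) / stats::median(half_life)
}

#' Time of peak activity for a biexponential curve
#'
#' @param model A biexponential `curve_model`.
#' @return Peak time \eqn{\ln(\lambda_2/\lambda_1)/(\lambda_2 - \lambda_1)}, h.
#' @export
biexp_peak_time <- function(model) {
  stopifnot(inherits(model, "curve_model"))
  if (model$kind != "biexp") stop("biexp_peak_time: not a biexponential model",
                                  call. = FALSE)
  log(model$lam2 / model$lam1) / (model$lam2 - model$lam1)
}
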