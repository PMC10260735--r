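#' Fit a monoexponential model to time-activity samples
#'
#' With exactly two samples the two-parameter model is determined in closed
#' form: \eqn{\lambda = \ln(a_1/a_2)/(t_2 - t_1)}, \eqn{C = a_1 e^{\lambda
#' t_1}}, and the residual sum of squares is zero. With more samples an
#' unweighted nonlinear least-squares fit on the activity scale is performed
#' (Levenberg–Marquardt), initialized from the log-linear regression of
#' \eqn{\ln a} on \eqn{t}.
#'
#' A fitted decay constant \eqn{\lambda \le 0} means the extrapolated integral
#' diverges; such fits are returned with `converged = FALSE` and
#' `failure_reason = "nonpositive_rate"` rather than clamped, so downstream
#' error summaries can exclude and count them. Non-positive activities make
#' the two-point log ratio undefined (`failure_reason = "nonpositive_activity"`).
#'
#' @param data Data frame with columns `time_h` and `activity_MBq`; at least
#'   two rows with distinct times.
#' @return A `tia_fit` object; see [glance.tia_fit()] and [tidy.tia_fit()].
#' @examples
#' d <- tibble::tibble(time_h = c(24, 96), activity_MBq = c(100, 50))
#' f <- fit_monoexp(d)
#' glance(f)   # lam = log(2)/72, TIA ~ 13087 MBq.h
#' @export
fit_monoexp <- function(data) {
  d <- check_ta_frame(data, min_n = 2)
  t <- d$time_h
  a <- d$activity_MBq
  n <- length(t)

  if (n == 2) {
    if (any(a <= 0)) {
      return(new_tia_fit(NULL, "mono", d, rss = NA_real_, converged = FALSE,
                         failure_reason = "nonpositive_activity"))
    }
    lam <- log(a[1] / a[2]) / (t[2] - t[1])
    if (!(lam > 0)) {
      return(new_tia_fit(NULL, "mono", d, rss = NA_real_, converged = FALSE,
                         failure_reason = "nonpositive_rate"))
    }
    model <- mono_curve(C = a[1] * exp(lam * t[1]), lam = lam)
    return(new_tia_fit(model, "mono", d, rss = 0, converged = TRUE))
  }

  pos <- a > 0
  if (sum(pos) < 2) {
    return(new_tia_fit(NULL, "mono", d, rss = NA_real_, converged = FALSE,
                       failure_reason = "nonpositive_activity"))
  }
  ll <- stats::lm(log(a[pos]) ~ t[pos])
  lam0 <- -unname(stats::coef(ll)[2])
  C0 <- exp(unname(stats::coef(ll)[1]))
  if (!(lam0 > 0)) lam0 <- log(2) / max(t)   # weakly-decaying start

  fit <- tryCatch(
    minpack.lm::nlsLM(a ~ C * exp(-lam * t),
                      start = list(C = C0, lam = lam0),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    return(new_tia_fit(NULL, "mono", d, rss = NA_real_, converged = FALSE,
                       failure_reason = "no_convergence"))
  }
  cf <- stats::coef(fit)
  rss <- sum(stats::resid(fit)^2)
  if (!(cf[["lam"]] > 0) || !(cf[["C"]] > 0)) {
    return(new_tia_fit(NULL, "mono", d, rss = rss, converged = FALSE,
                       failure_reason = "nonpositive_rate"))
  }
  new_tia_fit(mono_curve(cf[["C"]], cf[["lam"]]), "mono", d,
              rss = rss, converged = TRUE)
}

#' Fit a biexponential model to time-activity samples
#'
#' Unweighted nonlinear least squares of
#' \eqn{A(t) = C(e^{-\lambda_1 t} - e^{-\lambda_2 t})} under the constraint
#' \eqn{0 < \lambda_1 < \lambda_2}, enforced through the parameterization
#' \eqn{\lambda_1 = e^{p_1}}, \eqn{\lambda_2 = \lambda_1 + e^{p_2}},
#' \eqn{C = e^{p_0}}. Because the surface is multimodal, several starts are
#' tried: \eqn{\lambda_1} from the log-linear slope of the last two samples
#' (the terminal phase) and \eqn{\lambda_2} from a grid of multiples of
#' \eqn{\lambda_1}; the converged fit with the lowest residual sum of squares
#' wins.
#'
#' @param data Data frame with columns `time_h`, `activity_MBq`; at least 3
#'   rows with distinct times (3 free parameters).
#' @param lam2_multiples Multiples of the initial \eqn{\lambda_1} used as
#'   \eqn{\lambda_2} starting values.
#' @return A `tia_fit` object.
#' @export
fit_biexp <- function(data, lam2_multiples = c(3, 10, 30, 100)) {
  d <- check_ta_frame(data, min_n = 3)
  t <- d$time_h
  a <- d$activity_MBq
  ord <- order(t)
  tl <- t[ord][(length(t) - 1):length(t)]
  al <- a[ord][(length(t) - 1):length(t)]

  lam1_0 <- if (all(al > 0)) log(al[1] / al[2]) / (tl[2] - tl[1]) else NA_real_
  if (!is.finite(lam1_0) || lam1_0 <= 0) lam1_0 <- log(2) / max(t)

  # raw Levenberg-Marquardt on the residual function: near-monoexponential
  # data drives the biexp Jacobian rank-deficient, which the nls-model
  # wrapper rejects even though the least-squares solution is fine
  resid_fn <- function(p) {
    a - exp(p[1]) * (exp(-exp(p[2]) * t) - exp(-(exp(p[2]) + exp(p[3])) * t))
  }
  best <- NULL
  for (m in lam2_multiples) {
    lam2_0 <- lam1_0 * m
    g <- exp(-lam1_0 * t) - exp(-lam2_0 * t)
    C0 <- sum(a * g) / sum(g^2)             # profiled linear amplitude
    if (!is.finite(C0) || C0 <= 0) C0 <- max(a)
    fit <- tryCatch(
      minpack.lm::nls.lm(
        par = c(log(C0), log(lam1_0), log(lam2_0 - lam1_0)),
        fn = resid_fn,
        control = minpack.lm::nls.lm.control(maxiter = 300)),
      error = function(e) NULL)
    if (is.null(fit) || !fit$info %in% 1:4) next
    rss <- sum(fit$fvec^2)
    if (is.null(best) || rss < best$rss) best <- list(par = fit$par, rss = rss)
  }

  if (is.null(best)) {
    return(new_tia_fit(NULL, "biexp", d, rss = NA_real_, converged = FALSE,
                       failure_reason = "no_convergence"))
  }
  lam1 <- exp(best$par[2])
  lam2 <- lam1 + exp(best$par[3])
  new_tia_fit(biexp_curve(exp(best$par[1]), lam1, lam2), "biexp", d,
              rss = best$rss, converged = TRUE)
}

#' Select between mono- and biexponential fits by AIC
#'
#' Fits both candidate models to the reference (typically 4-point)
#' time-activity data and keeps the one with the lower Akaike information
#' criterion, \eqn{AIC = n \ln(\max(rss, floor)/n) + 2k}. The residual floor
#' guards `log(0)` when a model interpolates the data exactly; when both
#' models sit at the floor, or the scores tie, the more parsimonious
#' monoexponential wins. The default `"aicc"` is the small-sample corrected
#' variant, adding \eqn{2k(k+1)/\max(n-k-1, 1)}: the denominator clamp keeps
#' the correction finite at the edge case \eqn{n = k + 1} (4 samples, a
#' 3-parameter biexponential), where the textbook correction diverges and
#' would bar the richer model regardless of fit quality. Plain `"aic"` is
#' selectable but overfits readily with only one residual degree of freedom.
#'
#' @param data Data frame with columns `time_h`, `activity_MBq`; at least 4
#'   rows with distinct times.
#' @param variant `"aicc"` (default, clamped small-sample correction) or
#'   `"aic"`.
#' @param rss_floor Lower bound applied to the residual sum of squares inside
#'   the log; default `1e-12 * mean(a)^2 * n`.
#' @return The winning `tia_fit`, with its `aic` field populated.
#' @export
select_by_aic <- function(data, variant = c("aicc", "aic"), rss_floor = NULL) {
  variant <- match.arg(variant)
  d <- check_ta_frame(data, min_n = 4)
  if (is.null(rss_floor)) {
    rss_floor <- 1e-12 * mean(d$activity_MBq)^2 * nrow(d)
  }

  fm <- fit_monoexp(d)
  fb <- fit_biexp(d)
  if (!fm$converged && !fb$converged) {
    stop("select_by_aic: both fits failed (mono: ", fm$failure_reason,
         ", biexp: ", fb$failure_reason, ")", call. = FALSE)
  }
  if (fm$converged) fm$aic <- aic_score(fm$rss, nrow(d), 2, variant, rss_floor)
  if (fb$converged) fb$aic <- aic_score(fb$rss, nrow(d), 3, variant, rss_floor)

  if (!fb$converged) return(fm)
  if (!fm$converged) return(fb)
  floored <- max(fm$rss, rss_floor) == rss_floor &&
    max(fb$rss, rss_floor) == rss_floor
  if (floored || fm$aic <= fb$aic) fm else fb    # parsimony on ties
}

aic_score <- function(rss, n, k, variant = "aicc", rss_floor = 0) {
  score <- n * log(max(rss, rss_floor) / n) + 2 * k
  if (variant == "aicc") {
    score <- score + 2 * k * (k + 1) / max(n - k - 1, 1)
  }
  score
}

#' Refit a reduced time-point subset with a monoexponential
#'
#' Selects the samples belonging to a reduced sampling schedule — given
#' either as explicit times in hours or as clinical time-period labels (see
#' [assign_period()]) — and delegates to [fit_monoexp()]. With two points the
#' fit is the exact closed form; fit failures propagate via the `converged`
#' flag.
#'
#' @param data Data frame with columns `time_h`, `activity_MBq`.
#' @param schedule Numeric vector of times (h) present in `data`, or a
#'   character vector of period labels (`"t_D0"`, `"t_D1-2"`, `"t_D3-5"`,
#'   `"t_D6-8"`); length 2 or 3.
#' @return A `tia_fit` object for the subset.
#' @export
fit_reduced <- function(data, schedule) {
  d <- check_ta_frame(data, min_n = 2)
  if (!length(schedule) %in% c(2L, 3L)) {
    stop("fit_reduced: schedule must select 2 or 3 time points", call. = FALSE)
  }
  if (is.numeric(schedule)) {
    idx <- match(schedule, d$time_h)
    if (anyNA(idx)) {
      stop("fit_reduced: no sample at time(s) ",
           paste(schedule[is.na(idx)], collapse = ", "), " h", call. = FALSE)
    }
  } else {
    periods <- assign_period(d$time_h)
    idx <- match(schedule, periods)
    if (anyNA(idx)) {
      stop("fit_reduced: no sample in period(s) ",
           paste(schedule[is.na(idx)], collapse = ", "), call. = FALSE)
    }
  }
  fit_monoexp(d[idx, , drop = FALSE])
}

# ---- tia_fit object ---------------------------------------------------------

new_tia_fit <- function(model, kind, data, rss, converged,
                        failure_reason = NA_character_, aic = NA_real_) {
  structure(
    list(model = model, kind = kind, data = tibble::as_tibble(data),
         rss = rss, n = nrow(data),
         k = if (kind == "mono") 2L else 3L,
         aic = aic, converged = converged, failure_reason = failure_reason,
         tia = if (converged) analytic_tia(model) else NA_real_),
    class = "tia_fit")
}

#' @export
print.tia_fit <- function(x, ...) {
  status <- if (x$converged) "converged" else paste0("FAILED (", x$failure_reason, ")")
  cat(sprintf("<tia_fit %s, %d points, %s>\n", x$kind, x$n, status))
  if (x$converged) {
    print(x$model)
    cat(sprintf("  rss = %.4g MBq^2, TIA = %.6g MBq.h\n", x$rss, x$tia))
  }
  invisible(x)
}

#' Tidy a fitted time-activity model
#'
#' @param x A `tia_fit`.
#' @param ... Unused.
#' @return `tidy()`: one row per parameter (`term`, `estimate`); `glance()`:
#'   a one-row tibble with `kind`, `converged`, `failure_reason`, `n`, `rss`,
#'   `aic`, `lam_eff` (terminal decay constant), `half_life_h` and `tia`.
#' @importFrom generics tidy
#' @export
tidy.tia_fit <- function(x, ...) {
  if (!x$converged) {
    return(tibble::tibble(term = character(), estimate = numeric()))
  }
  if (x$kind == "mono") {
    tibble::tibble(term = c("C", "lam"),
                   estimate = c(x$model$C, x$model$lam1))
  } else {
    tibble::tibble(term = c("C", "lam1", "lam2"),
                   estimate = c(x$model$C, x$model$lam1, x$model$lam2))
  }
}

#' @rdname tidy.tia_fit
#' @importFrom generics glance
#' @export
glance.tia_fit <- function(x, ...) {
  lam_eff <- if (x$converged) x$model$lam1 else NA_real_
  tibble::tibble(
    kind = x$kind, converged = x$converged, failure_reason = x$failure_reason,
    n = x$n, rss = x$rss, aic = x$aic,
    lam_eff = lam_eff, half_life_h = log(2) / lam_eff, tia = x$tia)
}

#' @export
fitted.tia_fit <- function(object, ...) {
  if (!object$converged) return(rep(NA_real_, object$n))
  eval_activity(object$model, object$data$time_h)
}

#' @export
residuals.tia_fit <- function(object, ...) {
  object$data$activity_MBq - fitted(object)
}

check_ta_frame <- function(data, min_n = 2) {
  need <- c("time_h", "activity_MBq")
  missing <- setdiff(need, names(data))
  if (length(missing)) {
    stop("time-activity data lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  d <- tibble::as_tibble(data)[, need]
  if (nrow(d) < min_n) {
    stop("need at least ", min_n, " samples, got ", nrow(d), call. = FALSE)
  }
  if (anyDuplicated(d$time_h)) {
    stop("duplicate sampling times: ",
         paste(unique(d$time_h[duplicated(d$time_h)]), collapse = ", "),
         call. = FALSE)
  }
  if (any(d$time_h <= 0)) stop("times must be > 0 h", call. = FALSE)
  if (any(d$activity_MBq < 0)) stop("activities must be >= 0", call. = FALSE)
  d[order(d$time_h), ]
}

# ---- vectorized cohort fitters (grid evaluation fast path) ------------------

# Closed-form 2-point monoexponential across a cohort.
# a1, a2: activity vectors at times t1 < t2. Returns lam, C, tia, ok, reason.
fit_mono2_vec <- function(t1, t2, a1, a2) {
  ok <- a1 > 0 & a2 > 0
  reason <- ifelse(ok, NA_character_, "nonpositive_activity")
  lam <- rep(NA_real_, length(a1))
  lam[ok] <- log(a1[ok] / a2[ok]) / (t2 - t1)
  bad_rate <- ok & !(lam > 0)
  reason[bad_rate] <- "nonpositive_rate"
  ok <- ok & !bad_rate
  C <- ifelse(ok, a1 * exp(lam * t1), NA_real_)
  list(lam = lam, C = C, tia = ifelse(ok, C / lam, NA_real_),
       ok = ok, reason = reason)
}

# Damped Gauss-Newton monoexponential least squares, vectorized across curves.
# times: length-m schedule; Y: n x m activity matrix. Matches nlsLM solutions
# (checked in the test suite); rows that fail to converge or have fewer than
# two positive activities are flagged, not guessed.
fit_mono_gn_vec <- function(times, Y, max_iter = 60, tol = 1e-12) {
  n <- nrow(Y)
  m <- length(times)
  stopifnot(ncol(Y) == m)

  ok <- rowSums(Y > 0) >= 2
  reason <- ifelse(ok, NA_character_, "nonpositive_activity")
  lam <- rep(NA_real_, n)
  C <- rep(NA_real_, n)

  if (any(ok)) {
    # log-linear init on the positive samples of each row
    W <- (Y > 0) * 1
    L <- suppressWarnings(log(pmax(Y, .Machine$double.xmin)))
    sw <- rowSums(W)
    tx <- matrix(times, n, m, byrow = TRUE)
    mx <- rowSums(W * tx) / sw
    my <- rowSums(W * L) / sw
    vx <- rowSums(W * (tx - mx)^2)
    beta <- rowSums(W * (tx - mx) * (L - my)) / vx
    lam0 <- -beta
    lam0[!is.finite(lam0) | lam0 <= 0] <- log(2) / max(times)
    C0 <- exp(my + lam0 * mx)

    lam[ok] <- lam0[ok]
    C[ok] <- C0[ok]

    act <- ok
    mu <- rep(1e-3, n)
    Wt <- tx
    rss_of <- function(Cv, lv, idx) {
      Wm <- exp(-outer(lv[idx], times))
      rowSums((Y[idx, , drop = FALSE] - Cv[idx] * Wm)^2)
    }
    rss <- rep(NA_real_, n)
    rss[ok] <- rss_of(C, lam, which(ok))

    for (it in seq_len(max_iter)) {
      idx <- which(act)
      if (!length(idx)) break
      lv <- lam[idx]; Cv <- C[idx]
      Wm <- exp(pmax(-outer(lv, times), -700))
      R <- Y[idx, , drop = FALSE] - Cv * Wm
      Tm <- Wt[idx, , drop = FALSE]
      # J = [w, -C t w]
      a11 <- rowSums(Wm^2)
      a12 <- -Cv * rowSums(Tm * Wm^2)
      a22 <- Cv^2 * rowSums(Tm^2 * Wm^2)
      b1 <- rowSums(Wm * R)
      b2 <- -Cv * rowSums(Tm * Wm * R)
      d11 <- a11 * (1 + mu[idx])
      d22 <- a22 * (1 + mu[idx])
      det <- d11 * d22 - a12^2
      det[abs(det) < 1e-300] <- NA_real_
      dC <- (d22 * b1 - a12 * b2) / det
      dl <- (d11 * b2 - a12 * b1) / det
      Cn <- Cv + dC
      ln <- pmax(lv + dl, -0.2)          # keep exp() bounded; <=0 flags later
      bad <- !is.finite(Cn) | !is.finite(ln)
      Cn[bad] <- Cv[bad]; ln[bad] <- lv[bad]
      rss_new <- rss_of(`[<-`(C, idx, Cn), `[<-`(lam, idx, ln), idx)
      improve <- is.finite(rss_new) & rss_new <= rss[idx] + 1e-30
      acc <- idx[improve]
      C[acc] <- Cn[improve]; lam[acc] <- ln[improve]
      step <- pmax(abs(dC[improve]) / pmax(abs(Cn[improve]), 1e-12),
                   abs(dl[improve]) / pmax(abs(ln[improve]), 1e-12))
      done <- acc[is.finite(step) & step < tol]
      rss[acc] <- rss_new[improve]
      mu[acc] <- pmax(mu[acc] / 3, 1e-12)
      rej <- idx[!improve]
      mu[rej] <- pmin(mu[rej] * 10, 1e8)
      act[done] <- FALSE
      act[rej[mu[rej] >= 1e8]] <- FALSE
    }

    bad_rate <- ok & !(lam > 0)
    reason[bad_rate] <- "nonpositive_rate"
    bad_amp <- ok & !bad_rate & !(C > 0)
    reason[bad_amp] <- "nonpositive_amplitude"
    ok <- ok & !bad_rate & !bad_amp
  }

  list(lam = lam, C = C, tia = ifelse(ok, C / lam, NA_real_),
       ok = ok, reason = reason)
}
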