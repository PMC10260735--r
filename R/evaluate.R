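#' Summarize TIA prediction errors over a cohort
#'
#' Given per-subject predicted and reference time-integrated activities,
#' computes the schedule-comparison metrics: root mean square error
#' \eqn{RMSE = \sqrt{\sum (TIA_{pred} - TIA_{ref})^2 / n}} (MBq·h), mean
#' percent error \eqn{MPE = \frac{1}{n}\sum 100 (TIA_{pred} -
#' TIA_{ref})/TIA_{ref}}, its standard deviation (sample SD, n−1), mean
#' absolute percent error (MAPE) and the percent-error range. Pairs that are
#' invalid — missing prediction (failed fit), missing or non-positive
#' reference — are excluded from the metrics and counted in `n_failed`.
#'
#' @param pairs Data frame with columns `pred` and `ref` (TIA, MBq·h) and an
#'   optional logical `valid` column.
#' @return One-row tibble: `rmse`, `mpe`, `sd_pe`, `mape`, `min_pe`,
#'   `max_pe`, `n`, `n_failed`. A single valid pair reports `sd_pe = 0`.
#' @examples
#' tia_error_summary(tibble::tibble(pred = c(110, 90), ref = c(100, 100)))
#' @export
tia_error_summary <- function(pairs) {
  stopifnot(all(c("pred", "ref") %in% names(pairs)))
  valid <- if ("valid" %in% names(pairs)) pairs$valid else TRUE
  valid <- valid & !is.na(pairs$pred) & !is.na(pairs$ref) & pairs$ref > 0
  n <- sum(valid)
  if (n == 0) stop("tia_error_summary: no valid pairs", call. = FALSE)
  pred <- pairs$pred[valid]
  ref <- pairs$ref[valid]
  pe <- 100 * (pred - ref) / ref
  tibble::tibble(
    rmse = sqrt(mean((pred - ref)^2)),
    mpe = mean(pe),
    sd_pe = if (n > 1) stats::sd(pe) else 0,
    mape = mean(abs(pe)),
    min_pe = min(pe),
    max_pe = max(pe),
    n = n,
    n_failed = length(valid) - n)
}

#' Evaluate a TIA estimation method over every candidate schedule
#'
#' For each sampling schedule, predicts every subject's TIA with the chosen
#' method — the Hänscheid or Madsen single-time-point formula, or a
#' monoexponential refit through 2 or 3 sampled points — compares against the
#' analytic reference TIA of the simulated truth, and summarizes the cohort
#' errors with [tia_error_summary()].
#'
#' Sampling follows the simulation design: each curve is sampled once at
#' every grid time and, when a noise model is supplied, perturbed once per
#' (curve, time); all schedules then share those noisy samples. Failed
#' reduced fits (non-positive decay rate, non-positive activities) are
#' excluded and counted per schedule in `n_failed`.
#'
#' @param curves Curve tibble with columns `curve_id`, `kind`, `C`, `lam1`,
#'   `lam2` (see [simulate_cohort()]).
#' @param method One of `"hanscheid"`, `"madsen"`, `"2tp"`, `"3tp"`.
#' @param schedules For the STP methods, a numeric vector of times (default
#'   [stp_grid()]); for `"2tp"`/`"3tp"`, a tibble of schedules with columns
#'   `t1`, `t2` (and `t3`), defaulting to [twotp_grid()] / [threetp_grid()].
#' @param noise Optional `power_law_noise` measurement-noise model.
#' @param lam_pop Population decay constant (1/h); required for `"madsen"`.
#' @param seed Optional integer seed controlling the noise draws.
#' @return A tibble with one row per schedule: `method`, `t1`, `t2`, `t3`
#'   (`NA` where unused) and the [tia_error_summary()] columns.
#' @seealso [optimal_schedule()], [pe_heatmap()]
#' @export
evaluate_method <- function(curves,
                            method = c("hanscheid", "madsen", "2tp", "3tp"),
                            schedules = NULL, noise = NULL, lam_pop = NULL,
                            seed = NULL) {
  method <- match.arg(method)
  check_curve_frame(curves)
  if (method == "madsen" && is.null(lam_pop)) {
    stop("evaluate_method: madsen requires lam_pop", call. = FALSE)
  }
  if (is.null(schedules)) {
    schedules <- switch(method,
                        hanscheid = stp_grid(), madsen = stp_grid(),
                        `2tp` = twotp_grid(), `3tp` = threetp_grid())
  }

  stp <- method %in% c("hanscheid", "madsen")
  if (stp) {
    stopifnot(is.numeric(schedules))
    times <- sort(unique(schedules))
  } else {
    need <- if (method == "2tp") c("t1", "t2") else c("t1", "t2", "t3")
    if (!all(need %in% names(schedules))) {
      stop("evaluate_method: schedules must have columns ",
           paste(need, collapse = ", "), call. = FALSE)
    }
    times <- sort(unique(unlist(schedules[need], use.names = FALSE)))
  }
  if (any(times <= 0)) stop("evaluate_method: times must be > 0", call. = FALSE)

  curves <- tibble::as_tibble(curves)
  ref <- analytic_tia(curves)$tia

  # one activity sample per (curve, time); shared across schedules
  A <- outer_activity(curves, times)
  if (!is.null(noise)) {
    if (!is.null(seed)) {
      old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
      on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
      set.seed(seed)
    }
    A[] <- as.numeric(apply_noise(as.vector(A), noise))
  }
  col_of <- function(t) match(t, times)

  summarize_pred <- function(pred, valid = NULL) {
    tia_error_summary(tibble::tibble(
      pred = pred, ref = ref,
      valid = if (is.null(valid)) TRUE else valid))
  }

  if (stp) {
    res <- purrr::map(schedules, function(t) {
      a <- A[, col_of(t)]
      pred <- if (method == "hanscheid") hanscheid_tia(t, pmax(a, 0))
              else madsen_tia(t, pmax(a, 0), lam_pop)
      summarize_pred(pred)
    })
    out <- dplyr::bind_cols(
      tibble::tibble(method = method, t1 = schedules,
                     t2 = NA_real_, t3 = NA_real_),
      dplyr::bind_rows(res))
  } else if (method == "2tp") {
    res <- purrr::map2(schedules$t1, schedules$t2, function(t1, t2) {
      f <- fit_mono2_vec(t1, t2, A[, col_of(t1)], A[, col_of(t2)])
      summarize_pred(f$tia, f$ok)
    })
    out <- dplyr::bind_cols(
      tibble::tibble(method = method, t1 = schedules$t1, t2 = schedules$t2,
                     t3 = NA_real_),
      dplyr::bind_rows(res))
  } else {
    res <- purrr::pmap(schedules[c("t1", "t2", "t3")], function(t1, t2, t3) {
      ts <- c(t1, t2, t3)
      f <- fit_mono_gn_vec(ts, A[, col_of(ts), drop = FALSE])
      summarize_pred(f$tia, f$ok)
    })
    out <- dplyr::bind_cols(
      tibble::tibble(method = method, t1 = schedules$t1, t2 = schedules$t2,
                     t3 = schedules$t3),
      dplyr::bind_rows(res))
  }
  out
}

outer_activity <- function(curves, times) {
  n <- nrow(curves)
  A <- matrix(NA_real_, n, length(times))
  for (j in seq_along(times)) {
    A[, j] <- activity_at(curves$kind, curves$C, curves$lam1, curves$lam2,
                          times[j])
  }
  A
}

#' Pick the minimum-RMSE (optimal) sampling schedule
#'
#' The optimal schedule is the one with the lowest cohort RMSE. Ties are
#' broken in favour of the schedule whose last imaging time is earliest
#' (least patient burden), then lexicographically by times.
#'
#' @param results Schedule-evaluation tibble from [evaluate_method()].
#' @return The single winning row.
#' @export
optimal_schedule <- function(results) {
  if (!nrow(results)) stop("optimal_schedule: empty results", call. = FALSE)
  last_t <- pmax(results$t1,
                 dplyr::coalesce(results$t2, -Inf),
                 dplyr::coalesce(results$t3, -Inf))
  ord <- order(results$rmse, last_t, results$t1,
               dplyr::coalesce(results$t2, -Inf),
               dplyr::coalesce(results$t3, -Inf))
  results[ord[1], , drop = FALSE]
}

#' Percent-error heatmap matrices for the two-time-point grid
#'
#' Reshapes 2TP schedule results into matrices indexed by first and second
#' imaging time — the machine-readable form of the MPE and SD heatmaps. Only
#' the upper triangle (`t1 < t2`) is populated.
#'
#' @param results 2TP rows from [evaluate_method()] (columns `t1`, `t2` plus
#'   metrics).
#' @param metrics Which metric matrices to build.
#' @return Named list of matrices with `t1` on rows and `t2` on columns,
#'   dimnames holding the times in hours.
#' @seealso [write_pe_heatmaps()] to export as delimited text,
#'   [plot_pe_heatmap()] to draw.
#' @export
pe_heatmap <- function(results, metrics = c("mpe", "sd_pe")) {
  stopifnot(all(c("t1", "t2") %in% names(results)))
  stopifnot(all(metrics %in% names(results)))
  t1s <- sort(unique(results$t1))
  t2s <- sort(unique(results$t2))
  out <- lapply(metrics, function(mcol) {
    m <- matrix(NA_real_, length(t1s), length(t2s),
                dimnames = list(t1 = t1s, t2 = t2s))
    m[cbind(match(results$t1, t1s), match(results$t2, t2s))] <- results[[mcol]]
    m
  })
  names(out) <- metrics
  out
}

#' Write percent-error heatmap matrices as delimited text
#'
#' @param results 2TP rows from [evaluate_method()].
#' @param dir Output directory (created if needed).
#' @param prefix Filename prefix; files are `<prefix>_<metric>.csv` with the
#'   first imaging time as the first column and second imaging times as the
#'   remaining column headers.
#' @param metrics Metrics to export.
#' @return Invisibly, the written file paths.
#' @export
write_pe_heatmaps <- function(results, dir, prefix = "heatmap",
                              metrics = c("mpe", "sd_pe")) {
  mats <- pe_heatmap(results, metrics)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- purrr::imap_chr(mats, function(m, nm) {
    path <- file.path(dir, paste0(prefix, "_", nm, ".csv"))
    df <- dplyr::bind_cols(tibble::tibble(t1_h = as.numeric(rownames(m))),
                           tibble::as_tibble(m, .name_repair = "minimal"))
    names(df)[-1] <- colnames(m)
    readr::write_csv(df, path)
    path
  })
  invisible(unname(paths))
}
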