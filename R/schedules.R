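#' Clinical imaging time periods
#'
#' Post-therapy scans cluster into four day-based windows: day 0
#' (`t_D0`, 3–5 h), days 1–2 (`t_D1-2`, 21–52 h), days 3–5 (`t_D3-5`,
#' 71–126 h) and days 6–8 (`t_D6-8`, 144–194 h) post-injection. Windows are
#' inclusive at both boundaries; times falling between windows are
#' unassigned.
#'
#' @return A tibble with columns `label`, `start_h`, `end_h`.
#' @export
time_periods <- function() {
  tibble::tibble(
    label = c("t_D0", "t_D1-2", "t_D3-5", "t_D6-8"),
    start_h = c(3, 21, 71, 144),
    end_h = c(5, 52, 126, 194))
}

#' Assign scan times to clinical time periods
#'
#' @param t Times in hours post-injection (`t > 0`), vectorized.
#' @return Character vector of period labels; `NA` for times outside every
#'   window (these are excluded from period-grouped analyses).
#' @examples
#' assign_period(c(4, 100, 60))   # "t_D0", "t_D3-5", NA
#' @export
assign_period <- function(t) {
  stopifnot(is.numeric(t))
  if (any(t <= 0)) stop("assign_period: t must be > 0", call. = FALSE)
  tp <- time_periods()
  out <- rep(NA_character_, length(t))
  for (i in seq_len(nrow(tp))) {
    out[t >= tp$start_h[i] & t <= tp$end_h[i]] <- tp$label[i]
  }
  out
}

#' Enumerate clinical reduced time-period combinations
#'
#' All ordered k-subsets of the four clinical time periods: 6 combinations
#' for two time points and 4 for three.
#'
#' @param k 2 or 3.
#' @return A tibble with one row per schedule and columns `p1`, `p2` (and
#'   `p3` for `k = 3`) holding period labels in chronological order.
#' @export
clinical_combinations <- function(k) {
  if (!length(k) == 1 || !k %in% c(2, 3)) {
    stop("clinical_combinations: k must be 2 or 3", call. = FALSE)
  }
  labels <- time_periods()$label
  cmb <- utils::combn(labels, k)
  out <- tibble::as_tibble(t(cmb), .name_repair = "minimal")
  names(out) <- paste0("p", seq_len(k))
  out
}

#' Simulation sampling-schedule grids
#'
#' `stp_grid()` returns the 240 single-time-point candidates (1-h steps from
#' 1 to 240 h post-injection). `twotp_grid()` returns all 1770 unordered pairs
#' of distinct times on the 4-h grid 4, 8, ..., 240 h. `threetp_grid()`
#' returns the 3294 triples drawn from day slots — day 0 offers 4 h and 8 h,
#' days 1–9 offer the beginning/middle/end-of-day times \eqn{24d},
#' \eqn{24d+4}, \eqn{24d+8}, and day 10 offers only 240 h — with at most one
#' time point per day, so no two scans fall within the same working day.
#'
#' @return `stp_grid()`: numeric vector of times (h). `twotp_grid()`,
#'   `threetp_grid()`: tibbles with columns `t1 < t2` (`< t3`), one row per
#'   schedule, in lexicographic order.
#' @export
stp_grid <- function() {
  seq(1, 240, by = 1)
}

#' @rdname stp_grid
#' @export
twotp_grid <- function() {
  times <- seq(4, 240, by = 4)
  pairs <- utils::combn(times, 2)
  tibble::tibble(t1 = pairs[1, ], t2 = pairs[2, ])
}

#' @rdname stp_grid
#' @export
threetp_grid <- function() {
  slots <- threetp_day_slots()
  day_of <- rep(seq_along(slots), lengths(slots))
  times <- unlist(slots, use.names = FALSE)
  trip <- utils::combn(seq_along(times), 3)
  keep <- day_of[trip[1, ]] != day_of[trip[2, ]] &
    day_of[trip[2, ]] != day_of[trip[3, ]] &
    day_of[trip[1, ]] != day_of[trip[3, ]]
  trip <- trip[, keep, drop = FALSE]
  out <- tibble::tibble(t1 = times[trip[1, ]], t2 = times[trip[2, ]],
                        t3 = times[trip[3, ]])
  dplyr::arrange(out, .data$t1, .data$t2, .data$t3)
}

# Valid imaging times per day: injection at 0 h, first slot 4 h; each later
# day has beginning (24d), middle (24d + 4) and end (24d + 8); grid stops at
# 240 h so day 10 has just its beginning.
threetp_day_slots <- function() {
  c(list(c(4, 8)),
    lapply(1:9, function(d) 24 * d + c(0, 4, 8)),
    list(240))
}
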