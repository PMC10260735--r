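test_that("error summary implements RMSE, MPE, SD, MAPE and the range", {
  s <- tia_error_summary(tibble::tibble(pred = c(110, 90), ref = c(100, 100)))
  expect_equal(s$mpe, 0)
  expect_equal(s$mape, 10)
  expect_equal(s$rmse, 10)
  expect_equal(s$sd_pe, stats::sd(c(10, -10)))
  expect_equal(c(s$min_pe, s$max_pe), c(-10, 10))

  ident <- tia_error_summary(tibble::tibble(pred = c(5, 7), ref = c(5, 7)))
  expect_equal(ident$rmse, 0)
  expect_equal(ident$mape, 0)

  one <- tia_error_summary(tibble::tibble(pred = 120, ref = 100))
  expect_equal(one$mpe, 20)
  expect_equal(one$mape, 20)
  expect_equal(one$rmse, 20)
  expect_equal(one$sd_pe, 0)        # single pair: SD reported as 0
  expect_equal(one$n, 1)

  # invalid pairs go to n_failed only
  mixed <- tia_error_summary(tibble::tibble(
    pred = c(110, NA, 90), ref = c(100, 100, 100),
    valid = c(TRUE, TRUE, FALSE)))
  expect_equal(mixed$n, 1)
  expect_equal(mixed$n_failed, 2)

  expect_error(tia_error_summary(tibble::tibble(pred = NA_real_, ref = 100)),
               "no valid")
})

test_that("MAPE >= |MPE| and RMSE = 0 iff all predictions match", {
  for (s in 1:5) {
    pairs <- withr::with_seed(s, tibble::tibble(
      ref = stats::runif(30, 100, 1000),
      pred = ref * stats::rlnorm(30, 0, 0.2)))
    out <- tia_error_summary(pairs)
    expect_gte(out$mape, abs(out$mpe))
    expect_gte(out$max_pe, out$mpe)
    expect_lte(out$min_pe, out$mpe)
    expect_gt(out$rmse, 0)
  }
})

test_that("estimator exactness propagates to cohort-level evaluation", {
  # degenerate single-lambda cohort: Madsen exact at every time
  cohort <- fixed_lambda_cohort(30, lam = log(2) / 72, seed = 8)
  res <- evaluate_method(cohort, "madsen", schedules = c(10, 72, 150),
                         lam_pop = log(2) / 72)
  expect_equal(res$mpe, rep(0, 3), tolerance = 1e-10)
  expect_equal(res$rmse, rep(0, 3), tolerance = 1e-8)

  # Hanscheid at t = common half-life: exact for every subject
  resh <- evaluate_method(cohort, "hanscheid", schedules = 72)
  expect_equal(resh$mpe, 0, tolerance = 1e-10)
  expect_equal(resh$sd_pe, 0, tolerance = 1e-10)

  # mono cohort, noise-free 2TP: every schedule is exact
  mixed <- simulate_cohort(mono_cohort_spec(), n = 25, seed = 9)
  sub <- twotp_grid()[seq(1, 1770, by = 40), ]
  res2 <- evaluate_method(mixed, "2tp", schedules = sub)
  expect_equal(res2$mpe, rep(0, nrow(sub)), tolerance = 1e-8)
  expect_equal(res2$n_failed, rep(0L, nrow(sub)))

  # noise-free 3TP mono refits are exact too
  sub3 <- threetp_grid()[seq(1, 3294, by = 150), ]
  res3 <- evaluate_method(mixed, "3tp", schedules = sub3)
  expect_equal(res3$mpe, rep(0, nrow(sub3)), tolerance = 1e-6)

  expect_error(evaluate_method(mixed, "madsen", schedules = 72), "lam_pop")
})

test_that("Hanscheid cohort bias never exceeds the theoretical upper bound", {
  cohort <- simulate_cohort(mono_cohort_spec(), n = 120, seed = 10)
  res <- evaluate_method(cohort, "hanscheid", schedules = seq(4, 240, by = 4))
  bound <- 100 * (2 / (exp(1) * log(2)) - 1)
  expect_true(all(res$mpe <= bound + 1e-9))
})

test_that("optimal schedule picks minimum RMSE with stated tie-breaks", {
  r <- tibble::tibble(method = "2tp", t1 = c(4, 8), t2 = c(96, 100),
                      t3 = NA_real_, rmse = c(10, 20))
  expect_equal(optimal_schedule(r)$t1, 4)
  expect_equal(optimal_schedule(r[1, ])$rmse, 10)

  # tie: earlier last imaging time wins
  tie <- tibble::tibble(method = "2tp", t1 = c(4, 4), t2 = c(120, 96),
                        t3 = NA_real_, rmse = c(5, 5))
  expect_equal(optimal_schedule(tie)$t2, 96)

  # Hanscheid on a spread-lambda cohort: optimum inside the half-life range,
  # cross-checked against a brute-force scan of the summaries
  cohort <- simulate_cohort(mono_cohort_spec(), n = 100, seed = 12)
  res <- evaluate_method(cohort, "hanscheid")
  opt <- optimal_schedule(res)
  expect_equal(opt$rmse, min(res$rmse))
  hl <- log(2) / cohort$lam1
  expect_gte(opt$t1, min(hl))
  expect_lte(opt$t1, max(hl))
})

test_that("2TP heatmap matrices are faithful upper-triangular bookkeeping", {
  cohort <- simulate_cohort(mono_cohort_spec(), n = 15, seed = 14)
  sched <- dplyr::filter(twotp_grid(), t1 %in% c(24, 48) & t2 %in% c(96, 120))
  res <- evaluate_method(cohort, "2tp", schedules = sched,
                         noise = default_noise_model(), seed = 3)
  mats <- pe_heatmap(res)
  expect_named(mats, c("mpe", "sd_pe"))
  cell <- res[res$t1 == 24 & res$t2 == 96, ]
  expect_equal(mats$mpe["24", "96"], cell$mpe)
  expect_equal(mats$sd_pe["48", "120"],
               res[res$t1 == 48 & res$t2 == 120, ]$sd_pe)

  # full-grid structure: strictly upper triangular (t1 < t2 only)
  full <- pe_heatmap(dplyr::mutate(twotp_grid(), mpe = 0, sd_pe = 0))
  m <- full$mpe
  t1v <- as.numeric(rownames(m)); t2v <- as.numeric(colnames(m))
  filled <- which(!is.na(m), arr.ind = TRUE)
  expect_true(all(t1v[filled[, 1]] < t2v[filled[, 2]]))

  # noise-free mono cohort: zero matrices
  clean <- evaluate_method(cohort, "2tp", schedules = sched)
  expect_equal(max(abs(pe_heatmap(clean)$mpe)), 0, tolerance = 1e-8)

  paths <- write_pe_heatmaps(res, withr::local_tempdir())
  expect_true(all(file.exists(paths)))
  back <- readr::read_csv(paths[1], show_col_types = FALSE)
  expect_equal(back$`96`[back$t1_h == 24], cell$mpe)
})

test_that("close late time pairs under noise blow up on low-activity curves", {
  # small, fast-clearing structure: very low activity beyond 150 h
  spec <- structure_spec(
    "small_tumor", frac_mono = 1,
    mono = list(C = lognormal_spec(2, 0.5, 0.2, 20),
                lam = lognormal_spec(log(2) / 30, 0.3, log(2) / 80, log(2) / 10)))
  cohort <- simulate_cohort(spec, n = 80, seed = 15)
  res <- evaluate_method(
    cohort, "2tp",
    schedules = tibble::tibble(t1 = c(196, 24), t2 = c(200, 120)),
    noise = default_noise_model(), seed = 16)
  late_close <- res[res$t1 == 196, ]
  early_late <- res[res$t1 == 24, ]
  expect_gt(late_close$mape + 100 * late_close$n_failed / 80, 100)
  expect_lt(early_late$mape, 30)
})
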