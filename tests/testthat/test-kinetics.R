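test_that("activity evaluation matches the closed exponential forms", {
  m <- mono_curve(C = 100, lam = log(2) / 72)
  expect_equal(eval_activity(m, 0), 100)
  expect_equal(eval_activity(m, 72), 50)          # one half-life
  expect_equal(eval_activity(m, c(0, 72, 144)), c(100, 50, 25))

  b <- biexp_curve(C = 100, lam1 = 0.01, lam2 = 0.1)
  expect_equal(eval_activity(b, 0), 0)            # equal terms cancel
  expect_equal(eval_activity(b, 24),
               100 * (exp(-0.24) - exp(-2.4)))

  expect_error(mono_curve(100, -0.1), "lam")
  expect_error(biexp_curve(100, 0.1, 0.01), "lam1 < lam2")
  expect_error(eval_activity(m, -1), "t must be")
})

test_that("analytic TIA equals the improper integral of the curve", {
  expect_equal(analytic_tia(mono_curve(100, 0.01)), 10000)
  expect_equal(analytic_tia(biexp_curve(100, 0.01, 0.1)), 9000)

  m <- mono_curve(125.9921, log(2) / 72)
  quad <- stats::integrate(function(t) eval_activity(m, t), 0, Inf,
                           rel.tol = 1e-8)
  expect_equal(analytic_tia(m), quad$value, tolerance = 1e-7)
  expect_equal(analytic_tia(m), 13087.31, tolerance = 1e-6)

  # random valid parameters, both model kinds
  pm <- random_mono_params(10, seed = 11)
  for (i in seq_len(nrow(pm))) {
    mi <- mono_curve(pm$C[i], pm$lam[i])
    expect_equal(analytic_tia(mi),
                 stats::integrate(function(t) eval_activity(mi, t), 0, Inf,
                                  rel.tol = 1e-9)$value,
                 tolerance = 1e-6)
  }
  pb <- random_biexp_params(10, seed = 12)
  for (i in seq_len(nrow(pb))) {
    bi <- biexp_curve(pb$C[i], pb$lam1[i], pb$lam2[i])
    expect_equal(analytic_tia(bi),
                 stats::integrate(function(t) eval_activity(bi, t), 0, Inf,
                                  rel.tol = 1e-9)$value,
                 tolerance = 1e-6)
  }
})

test_that("analytic_tia on a curve table appends a tia column", {
  curves <- tibble::tibble(kind = c("mono", "biexp"), C = c(100, 100),
                           lam1 = c(0.01, 0.01), lam2 = c(NA, 0.1))
  out <- analytic_tia(curves)
  expect_equal(out$tia, c(10000, 9000))
  expect_error(analytic_tia(dplyr::mutate(curves, lam1 = -lam1)), "divergent")
})

test_that("Hanscheid estimator is exact at the effective half-life", {
  m <- mono_curve(125.9921, log(2) / 72)
  a72 <- eval_activity(m, 72)
  expect_equal(hanscheid_tia(72, a72), analytic_tia(m), tolerance = 1e-12)
  expect_equal(hanscheid_tia(96, 50), 50 * 192 / log(2))
  expect_equal(hanscheid_tia(10, 0), 0)
  expect_error(hanscheid_tia(0, 10), "t must be")
})

test_that("Hanscheid/truth ratio obeys the 2u*2^-u law with its upper bound", {
  # ratio depends only on u = t / half-life; bound 2/(e ln2), attained at
  # u = 1/ln2, and exactly 1 at u = 1
  pm <- random_mono_params(5, seed = 21)
  bound <- 2 / (exp(1) * log(2))
  for (i in seq_len(nrow(pm))) {
    m <- mono_curve(pm$C[i], pm$lam[i])
    half <- log(2) / pm$lam[i]
    t <- seq(half / 20, half * 5, length.out = 400)
    ratio <- hanscheid_tia(t, eval_activity(m, t)) / analytic_tia(m)
    u <- t / half
    expect_equal(ratio, 2 * u * 2^(-u), tolerance = 1e-12)
    expect_true(all(ratio <= bound + 1e-12))
    expect_equal(hanscheid_tia(half, eval_activity(m, half)) / analytic_tia(m),
                 1, tolerance = 1e-12)
  }
})

test_that("Madsen estimator is exact when subject lambda equals lam_pop", {
  lam <- log(2) / 72
  m <- mono_curve(125.9921, lam)
  for (t in c(1, 24, 50, 96, 200)) {
    expect_equal(madsen_tia(t, eval_activity(m, t), lam), analytic_tia(m),
                 tolerance = 1e-12)
  }
  expect_equal(madsen_tia(50, 0, lam), 0)
  expect_error(madsen_tia(10, 5, -0.01), "lam_pop")
})

test_that("biexp curve peaks at ln(lam2/lam1)/(lam2-lam1), rising then falling", {
  pb <- random_biexp_params(6, seed = 31)
  for (i in seq_len(nrow(pb))) {
    b <- biexp_curve(pb$C[i], pb$lam1[i], pb$lam2[i])
    tp <- biexp_peak_time(b)
    expect_equal(tp, log(pb$lam2[i] / pb$lam1[i]) / (pb$lam2[i] - pb$lam1[i]))
    before <- eval_activity(b, seq(tp / 100, tp * 0.99, length.out = 50))
    after <- eval_activity(b, seq(tp * 1.01, tp * 6, length.out = 50))
    expect_true(all(diff(before) > 0))
    expect_true(all(diff(after) < 0))
    expect_true(eval_activity(b, tp) >= max(before, after))
  }
})

test_that("population lambda is ln2 over the median terminal half-life", {
  curves <- tibble::tibble(
    kind = c("mono", "mono", "biexp"),
    C = c(10, 20, 30),
    lam1 = log(2) / c(40, 60, 80),
    lam2 = c(NA, NA, 0.5))
  expect_equal(population_lambda(curves), log(2) / 60)
})
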