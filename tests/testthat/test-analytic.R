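test_that("tolerance-weighted lifetime temperature has unit weights and the stated limits", {
  ts <- linear_series()
  # constant widths: plain average of the series
  expect_equal(
    weighted_lifetime_temperature(ref_vital, life_history(3, 60), c(4, 4), ts),
    mean(ts)
  )
  # constant series: the constant, whatever the widths
  expect_equal(
    weighted_lifetime_temperature(ref_vital, life_history(3, 60), c(5, 15), rep(7, 60)),
    7
  )
  # brute-force weighted-sum oracle
  d <- c(3, 57); om <- c(5, 15)
  w_tot2 <- 1 / sum(d / om^2)
  w <- w_tot2 / rep(om, times = d)^2
  expect_equal(sum(w), 1, tolerance = 1e-14)
  expect_equal(
    weighted_lifetime_temperature(ref_vital, life_history(3, 60), om, ts),
    sum(w * ts), tolerance = 1e-13
  )
  # T_tot stays inside the range of the series
  s <- fixed_history_summary(ref_vital, life_history(20, 60), c(1, 30), ts)
  expect_gte(s$T_tot, min(ts))
  expect_lte(s$T_tot, max(ts))
})

test_that("maximal survival to harvest matches its closed forms and the warming cost", {
  # constant series at the optimum: pure product of maximal survivals
  s <- max_total_survival(ref_vital, life_history(3, 60), c(5, 15), rep(10, 60))
  expect_equal(s, 0.61^3 * 0.98^57, tolerance = 1e-12)
  # s_tot_max equals the harvest at theta = T_tot
  ts <- linear_series()
  fs <- fixed_history_summary(ref_vital, life_history(3, 60), c(5, 15), ts)
  expect_equal(
    expected_harvest_fixed(fs$T_tot, ref_vital, life_history(3, 60), c(5, 15), ts),
    fs$s_tot_max, tolerance = 1e-12
  )
  # warming strictly erodes the attainable maximum
  s_warm <- max_total_survival(ref_vital, life_history(3, 60), c(5, 15), ts)
  s_flat <- max_total_survival(ref_vital, life_history(3, 60), c(5, 15), rep(10, 60))
  expect_lt(s_warm, s_flat)
})

test_that("the Gaussian closed form equals the yearly product on random instances", {
  withr::with_seed(21, {
    for (i in 1:100) {
      n <- sample(2:4, 1)
      H <- sample(n:30, 1)
      a <- if (n > 2) sort(sample(1:(H - 1), n - 1)) else sample(1:H, 1)
      # guard strict increase for small draws
      a <- unique(a)
      while (length(a) < n - 1) a <- sort(unique(c(a, sample(1:H, 1))))
      lh <- life_history(a, H)
      v <- vital_rates(stats::runif(n, 0.3, 0.99), stats::runif(n - 1, 0.05, 0.95))
      om <- stats::runif(n, 0.5, 10)
      ts <- 10 + cumsum(stats::runif(H, -0.2, 0.4))
      th <- stats::runif(1, 8, 13)
      expect_equal(
        expected_harvest_fixed(th, v, lh, om, ts),
        expected_harvest_fixed(th, v, lh, om, ts, method = "product"),
        tolerance = 1e-12
      )
    }
  })
})

test_that("single-stage and forced-ladder cohorts reduce to explicit formulas", {
  v1 <- vital_rates(0.9, numeric(0))
  expect_equal(
    expected_harvest(11, v1, omega = 2, series = rep(10, 25)),
    0.9^25 * exp(-25 * (11 - 10)^2 / (2 * 4)),
    tolerance = 1e-12
  )
  ladder <- vital_rates(c(0.8, 0.9, 0.95), c(1, 1))
  ts <- linear_series(H = 20)
  expect_equal(
    expected_harvest(10.3, ladder, c(2, 4, 6), ts[1:20]),
    expected_harvest_fixed(10.3, ladder, life_history(c(1, 2), 20), c(2, 4, 6), ts[1:20]),
    tolerance = 1e-12
  )
})

test_that("the variable-cohort closed form matches Gaussian quadrature and its limits", {
  ts <- linear_series()
  lh <- life_history(3, 60)
  om <- calibrated_profile(2, lh, b = 0)
  fs <- fixed_history_summary(ref_vital, lh, om, ts)
  # sigma_p = 0 is the homogeneous cohort
  expect_equal(
    mixture_expected_harvest(10.5, 0, ref_vital, lh, om, ts),
    expected_harvest_fixed(10.5, ref_vital, lh, om, ts),
    tolerance = 1e-12
  )
  # quadrature oracle across spreads
  for (sp in c(0.1, 1, 5)) {
    expect_equal(
      mixture_expected_harvest(10.5, sp, ref_vital, lh, om, ts),
      mixture_expected_harvest(10.5, sp, ref_vital, lh, om, ts, method = "quadrature"),
      tolerance = 1e-8
    )
  }
  # at the optimum, sigma_p = omega_tot costs a factor sqrt(2)
  expect_equal(
    mixture_expected_harvest(fs$T_tot, fs$omega_tot, ref_vital, lh, om, ts),
    fs$s_tot_max / sqrt(2),
    tolerance = 1e-12
  )
  # variance hedges a badly matched provenance
  far <- fs$T_tot + 6
  expect_gt(
    mixture_expected_harvest(far, 2, ref_vital, lh, om, ts),
    expected_harvest_fixed(far, ref_vital, lh, om, ts)
  )
})
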