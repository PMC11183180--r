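test_that("with no warming the local provenance wins, and boundary maxima warn", {
  om <- calibrated_profile(3.5, ref_history, b = 0)
  ts <- rep(10, 60)
  expect_warning(
    fit <- best_provenance(ref_vital, om, ts, provenance_grid(10)),
    class = "agflow_boundary_warning"
  )
  expect_equal(fit$theta_star, 10)
  # interior optimum raises no warning
  expect_silent(
    fit <- best_provenance(ref_vital, om, linear_series(), provenance_grid(10))
  )
  expect_equal(fit$theta_star, 10.86)
})

test_that("analytic and projection engines find the same optimum", {
  om <- calibrated_profile(3.5, ref_history, ratio = 3)
  ts <- linear_series()
  grid <- provenance_grid(10)
  f1 <- best_provenance(ref_vital, om, ts, grid, engine = "project")
  f2 <- best_provenance(ref_vital, om, ts, grid, engine = "analytic")
  expect_equal(f1$theta_star, f2$theta_star)
  expect_equal(f1$harvest_star, f2$harvest_star, tolerance = 1e-8)
  expect_equal(nrow(tidy(f1)), length(grid))
})

test_that("the optimum shifts warmer with faster warming and longer rotations", {
  om60 <- calibrated_profile(3.5, ref_history, b = 0)
  stars <- vapply(c("control", "intermediate", "high", "very_high"), function(w) {
    ts <- temperature_series(climate_scenario(10, 60, total_warming = w))
    suppressWarnings(best_provenance(ref_vital, om60, ts, provenance_grid(10))$theta_star)
  }, numeric(1))
  expect_true(all(diff(stars) >= 0))
  expect_true(any(diff(stars) > 0))
  # longer rotation under the same warming rate
  lh100 <- typical_life_history(fundamental_matrix(rebuild_matrix(ref_vital)), 100)
  om100 <- calibrated_profile(3.5, lh100, b = 0)
  ts100 <- temperature_series(climate_scenario(10, 100, total_warming = "intermediate"))
  star100 <- best_provenance(ref_vital, om100, ts100, provenance_grid(10))$theta_star
  expect_gte(star100, stars[["intermediate"]])
})

test_that("the optimum ignores the cumulative-tolerance magnitude at fixed ontogeny", {
  ts <- linear_series()
  stars <- vapply(c(2, 3.5, 5), function(wt) {
    om <- calibrated_profile(wt, ref_history, ratio = 3)
    best_provenance(ref_vital, om, ts, provenance_grid(10))$theta_star
  }, numeric(1))
  expect_lte(max(stars) - min(stars), 0.01 + 1e-9)
})

test_that("a less tolerant juvenile stage pulls the optimum cooler, non-monotonically in a", {
  ts <- linear_series()
  grid <- provenance_grid(10)
  star_for <- function(a1, ratio) {
    lh <- life_history(a1, 60)
    om <- calibrated_profile(3.5, lh, ratio = ratio)
    h <- expected_harvest_fixed(grid, ref_vital, lh, om, ts)
    grid[which.max(h)]
  }
  const_star <- 10.86
  stars <- vapply(c(1, 5, 20, 40, 59), star_for, numeric(1), ratio = 9)
  expect_true(all(stars < const_star))
  # dips at intermediate ages and climbs back toward the ends
  expect_gt(stars[1], min(stars))
  expect_gt(stars[5], min(stars))
  expect_lt(abs(stars[5] - const_star), 0.05)
})

test_that("stage-structured optima sit between the age-structured and constant-tolerance predictions", {
  ts <- linear_series()
  grid <- provenance_grid(10)
  const_star <- 10.86
  cycles <- random_life_cycles(100, n = 2, H = 60, seed = 31)
  ok <- 0L
  for (v in cycles) {
    lh <- typical_life_history(fundamental_matrix(rebuild_matrix(v)), 60)
    om <- calibrated_profile(3.5, lh, ratio = 3)
    staged <- suppressWarnings(
      best_provenance(v, om, ts, grid, engine = "analytic")$theta_star
    )
    # mean survivor maturation age, weighting histories by their harvest share
    e <- enumerate_life_histories(v$g, 2, 60)
    contrib <- vapply(seq_len(nrow(e)), function(i) {
      e$probability[i] * expected_harvest_fixed(staged, v, life_history(e$a[[i]], 60), om, ts)
    }, numeric(1))
    a_bar <- sum(unlist(e$a) * contrib) / sum(contrib)
    # the age-structured prediction at the (non-integer) mean age, bracketed
    # by its two neighbouring whole-year histories
    aged <- vapply(c(max(1, floor(a_bar)), min(59, ceiling(a_bar))), function(a1) {
      lh_bar <- life_history(a1, 60)
      om_bar <- calibrated_profile(3.5, lh_bar, ratio = 3)
      grid[which.max(expected_harvest_fixed(grid, v, lh_bar, om_bar, ts))]
    }, numeric(1))
    lo <- min(aged, const_star) - 0.011
    hi <- max(aged, const_star) + 0.011
    if (staged >= lo && staged <= hi) ok <- ok + 1L
  }
  expect_gte(ok, 90)
})

test_that("quarter-rotation rule snaps to the grid away from the baseline", {
  expect_equal(quarter_rotation_theta(climate_scenario(0, 60, total_warming = 1.7)), 0.43)
  expect_equal(quarter_rotation_theta(climate_scenario(0, 60, total_warming = 0)), 0)
  expect_equal(quarter_rotation_theta(climate_scenario(0, 60, total_warming = 3.3)), 0.83)
  expect_equal(quarter_rotation_theta(climate_scenario(5, 60, total_warming = 1.7)), 5.43)
})

test_that("harvest loss is a plain relative shortfall, unclamped", {
  expect_equal(harvest_loss(0.04, 0.04), 0)
  expect_equal(harvest_loss(0.02, 0.04), 0.5)
  expect_equal(harvest_loss(0.05, 0.04), -0.25)
  expect_error(harvest_loss(0.1, 0), class = "agflow_loss_error")
})

test_that("strategy comparison favours the model optimum over rules of thumb", {
  sc <- climate_scenario(10, 60, total_warming = "intermediate")
  om <- calibrated_profile(3.5, ref_history, b = 0)
  cmp <- compare_strategies(ref_vital, om, sc)
  expect_named(cmp, c("strategy", "theta", "harvest", "loss"))
  loss <- setNames(cmp$loss, cmp$strategy)
  expect_lte(loss[["best"]], loss[["quarter_rotation"]])
  expect_lte(loss[["best"]], loss[["local"]])
  expect_lt(loss[["best"]], loss[["local"]]) # warming > 0, constant tolerance
  expect_equal(cmp$theta[cmp$strategy == "quarter_rotation"], 10.43)
})

test_that("ensembles are reproducible, degenerate without noise, and spread with ontogeny", {
  om <- calibrated_profile(3.5, ref_history, b = 0)
  quiet <- climate_scenario(10, 60, total_warming = "intermediate", sigma_f = 0)
  ens0 <- fluctuation_ensemble(ref_vital, om, quiet, replicates = 3, base_seed = 5)
  td0 <- tidy(ens0)
  expect_equal(unique(td0$theta_star), ens0$deterministic$theta_star)
  expect_equal(sd(td0$theta_star), 0)

  noisy <- climate_scenario(10, 60, total_warming = "intermediate", sigma_f = 0.5)
  ens_a <- fluctuation_ensemble(ref_vital, om, noisy, replicates = 20, base_seed = 5)
  ens_b <- fluctuation_ensemble(ref_vital, om, noisy, replicates = 20, base_seed = 5)
  expect_equal(tidy(ens_a), tidy(ens_b))

  om9 <- calibrated_profile(3.5, ref_history, ratio = 9)
  ens9 <- fluctuation_ensemble(ref_vital, om9, noisy, replicates = 20, base_seed = 5)
  expect_gt(glance(ens9)$sd_theta_star, glance(ens_a)$sd_theta_star)
})
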