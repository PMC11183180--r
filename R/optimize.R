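#' Provenance grid
#'
#' The candidate thermal optima examined by the grid search, expressed in
#' absolute degrees C. The default spans the planting-site temperature to
#' 4 degrees above it in steps of 0.01 — wide enough to cover every
#' deterministic warming scenario over a 60-year rotation. For runs with
#' interannual fluctuations use `widened = TRUE`, which spans 5 degrees
#' below to 5 above the baseline so that stochastically cold early years
#' cannot push the optimum off the grid.
#'
#' @param T0 Baseline temperature at the planting site (degrees C).
#' @param lo,hi Grid bounds relative to `T0` (degrees C).
#' @param step Grid increment (degrees C).
#' @param widened Use the symmetric wide bounds (-5, +5) for fluctuation
#'   runs.
#' @return Numeric vector of candidate optima.
#' @examples
#' head(provenance_grid(10))
#' @export
provenance_grid <- function(T0, lo = 0, hi = 4, step = 0.01, widened = FALSE) {
  if (widened) {
    lo <- -5
    hi <- 5
  }
  if (lo >= hi || step <= 0) {
    abort("Grid needs lo < hi and a positive step.", class = "agflow_grid_error")
  }
  T0 + seq(lo, hi, by = step)
}

#' Grid search for the best provenance
#'
#' Evaluates the expected harvest of every candidate thermal optimum and
#' returns the maximiser. Ties are broken toward the cooler provenance
#' (the conservative translocation); a maximum on a grid boundary raises a
#' warning since the true optimum may lie outside the examined range.
#'
#' @param vital A [vital_rates()] object.
#' @param omega Per-stage tolerance widths (degrees C).
#' @param series Yearly temperatures (vector or [temperature_series()]
#'   tibble).
#' @param grid Candidate optima from [provenance_grid()].
#' @param engine `"project"` (cohort projection, default) or `"analytic"`
#'   (life-history enumeration; identical results, used for
#'   cross-checking).
#' @param N0 Initial cohort size in stage 1.
#' @param growth_climate Should growth also decline with mismatch
#'   (projection engine only)?
#' @return A `provenance_fit` object; `tidy()` gives the harvest curve,
#'   `glance()` the optimum.
#' @examples
#' v <- vital_rates(c(0.61, 0.98), 0.012)
#' sc <- climate_scenario(10, 60, total_warming = 1.7)
#' fit <- best_provenance(v, omega = c(27.1, 27.1), temperature_series(sc),
#'                        grid = provenance_grid(10))
#' glance(fit)
#' @export
best_provenance <- function(vital, omega, series, grid,
                            engine = c("project", "analytic"),
                            N0 = 1, growth_climate = FALSE) {
  engine <- match.arg(engine)
  temps <- as_temperatures(series)
  h <- switch(engine,
    project = harvest_over_grid(grid, vital, omega, temps,
                                N0 = c(N0, rep(0, vital$n - 1)),
                                growth_climate = growth_climate),
    analytic = expected_harvest(grid, vital, omega, temps, N0 = N0)
  )
  i <- which.max(h)  # which.max takes the first (coolest) of exact ties
  if (i == 1L || i == length(grid)) {
    warn("Best provenance lies on a grid boundary; the range may be truncated.",
         class = "agflow_boundary_warning")
  }
  structure(
    list(theta_star = grid[i], harvest_star = h[i],
         curve = tibble(theta = grid, harvest = h),
         engine = engine, omega = omega, temps = temps),
    class = "provenance_fit"
  )
}

#' @export
print.provenance_fit <- function(x, ...) {
  cat(sprintf("<provenance_fit> theta* = %.2f C, harvest = %.6g (engine: %s)\n",
              x$theta_star, x$harvest_star, x$engine))
  invisible(x)
}

#' @export
tidy.provenance_fit <- function(x, ...) x$curve

#' @export
glance.provenance_fit <- function(x, ...) {
  tibble(theta_star = x$theta_star, harvest_star = x$harvest_star,
         engine = x$engine)
}

#' @export
autoplot.provenance_fit <- function(object, ...) {
  ggplot2::ggplot(object$curve, ggplot2::aes(x = .data$theta, y = .data$harvest)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$theta_star, linetype = "dashed") +
    ggplot2::labs(x = "Provenance thermal optimum (°C)",
                  y = "Expected harvest") +
    ggplot2::theme_minimal()
}

#' Thermal optimum of the quarter-rotation rule
#'
#' The operational forestry guideline: plant the provenance adapted to the
#' projected temperature a quarter of the way through the rotation,
#' theta = T0 + k H/4. The value is snapped to the provenance grid,
#' rounding halves away from the baseline (toward warmer), so a projected
#' offset of +0.425 reads +0.43 on a 0.01-degree grid.
#'
#' @param scenario A [climate_scenario()].
#' @param step Grid step used for snapping (degrees C).
#' @return Thermal optimum in degrees C.
#' @examples
#' quarter_rotation_theta(climate_scenario(0, 60, total_warming = 1.7))
#' @export
quarter_rotation_theta <- function(scenario, step = 0.01) {
  stopifnot(inherits(scenario, "climate_scenario"))
  offset <- scenario$k * scenario$H / 4
  scenario$T0 + sign(offset) * floor(abs(offset) / step + 0.5 + 1e-9) * step
}

#' Harvest loss of a strategy relative to a reference
#'
#' loss = 1 - strategy / reference. The reference is conventionally the
#' local provenance under a no-warming climate, so the loss reads as the
#' fraction of the undisturbed harvest forfeited. A negative loss (a
#' strategy beating the reference) is reported as-is, never clamped.
#'
#' @param strategy_harvest Expected harvest of the strategy.
#' @param reference_harvest Expected harvest of the reference (> 0).
#' @return Loss fraction.
#' @examples
#' harvest_loss(0.02, 0.04)
#' @export
harvest_loss <- function(strategy_harvest, reference_harvest) {
  if (any(reference_harvest <= 0)) {
    abort("The reference harvest must be positive.", class = "agflow_loss_error")
  }
  1 - strategy_harvest / reference_harvest
}

#' Compare seed-sourcing strategies
#'
#' Evaluates three strategies under one warming scenario: the local
#' provenance (adapted to the planting-year climate, theta = T0), the
#' model-predicted best provenance (grid search), and the
#' quarter-rotation rule. Losses are measured against the local provenance
#' in a matching scenario with no climate change.
#'
#' @param vital A [vital_rates()] object.
#' @param omega Per-stage tolerance widths (degrees C).
#' @param scenario A [climate_scenario()] (the warming scenario).
#' @param grid Candidate optima; defaults to [provenance_grid()] at the
#'   scenario baseline.
#' @param N0 Initial cohort size.
#' @return A tibble with one row per strategy: `strategy`, `theta`,
#'   `harvest`, `loss`.
#' @examples
#' v <- vital_rates(c(0.61, 0.98), 0.012)
#' sc <- climate_scenario(10, 60, total_warming = 1.7)
#' compare_strategies(v, omega = c(27.1, 27.1), sc)
#' @export
compare_strategies <- function(vital, omega, scenario, grid = NULL, N0 = 1) {
  stopifnot(inherits(scenario, "climate_scenario"))
  if (is.null(grid)) grid <- provenance_grid(scenario$T0)
  temps <- as_temperatures(temperature_series(scenario))
  ref_series <- rep(scenario$T0, scenario$H)
  reference <- harvest_over_grid(scenario$T0, vital, omega, ref_series,
                                 N0 = c(N0, rep(0, vital$n - 1)))
  fit <- best_provenance(vital, omega, temps, grid, N0 = N0)
  thetas <- c(local = scenario$T0,
              best = fit$theta_star,
              quarter_rotation = quarter_rotation_theta(scenario))
  h <- harvest_over_grid(thetas, vital, omega, temps,
                         N0 = c(N0, rep(0, vital$n - 1)))
  tibble(
    strategy = names(thetas),
    theta = unname(thetas),
    harvest = unname(h),
    loss = harvest_loss(unname(h), reference)
  )
}

#' Replicated grid searches under interannual fluctuations
#'
#' Draws `replicates` stochastic temperature series around the scenario's
#' warming trend (replicate r uses seed `base_seed + r`), finds the best
#' provenance for each realisation, and summarises the spread of the
#' per-replicate optima. With differing stage tolerances the realised
#' optimum varies strongly across climate trajectories even though its
#' mean stays at the deterministic value.
#'
#' @param vital A [vital_rates()] object.
#' @param omega Per-stage tolerance widths (degrees C).
#' @param scenario A [climate_scenario()] with `sigma_f > 0` (with
#'   `sigma_f = 0` every replicate reproduces the deterministic run).
#' @param grid Candidate optima; defaults to the widened grid at the
#'   scenario baseline.
#' @param replicates Number of stochastic replicates.
#' @param base_seed Seed offset; replicate r uses `base_seed + r`.
#' @param N0 Initial cohort size.
#' @return A `fluctuation_ensemble` object; `tidy()` gives per-replicate
#'   results, `glance()` the across-replicate summary.
#' @export
fluctuation_ensemble <- function(vital, omega, scenario, grid = NULL,
                                 replicates = 100, base_seed = 1, N0 = 1) {
  stopifnot(inherits(scenario, "climate_scenario"))
  if (replicates < 1) abort("`replicates` must be >= 1.", class = "agflow_ensemble_error")
  if (is.null(grid)) grid <- provenance_grid(scenario$T0, widened = TRUE)
  ref_series <- rep(scenario$T0, scenario$H)
  reference <- harvest_over_grid(scenario$T0, vital, omega, ref_series,
                                 N0 = c(N0, rep(0, vital$n - 1)))
  runs <- purrr::map(seq_len(replicates), function(r) {
    sc_r <- climate_scenario(scenario$T0, scenario$H, k = scenario$k,
                             sigma_f = scenario$sigma_f,
                             seed = base_seed + r)
    fit <- suppressWarnings(
      best_provenance(vital, omega, temperature_series(sc_r), grid, N0 = N0)
    )
    list(replicate = r, seed = as.integer(base_seed + r),
         theta_star = fit$theta_star, harvest_star = fit$harvest_star,
         curve = fit$curve)
  })
  deterministic <- suppressWarnings(best_provenance(
    vital, omega,
    temperature_series(climate_scenario(scenario$T0, scenario$H,
                                        k = scenario$k, sigma_f = 0)),
    grid, N0 = N0
  ))
  structure(
    list(runs = runs, scenario = scenario, reference = reference,
         deterministic = deterministic, grid = grid),
    class = "fluctuation_ensemble"
  )
}

#' @export
print.fluctuation_ensemble <- function(x, ...) {
  g <- glance(x)
  cat(sprintf(
    "<fluctuation_ensemble> %d replicates, sigma_f = %g C\n  mean theta* = %.3f C (sd %.3f); deterministic theta* = %.2f C\n",
    g$replicates, x$scenario$sigma_f, g$mean_theta_star, g$sd_theta_star,
    g$deterministic_theta_star))
  invisible(x)
}

#' Per-replicate results of a fluctuation ensemble
#'
#' @param x A `fluctuation_ensemble`.
#' @param ... Unused.
#' @return A tibble with columns `replicate`, `seed`, `theta_star`,
#'   `harvest_star`, `loss` (vs. the no-warming local reference).
#' @export
tidy.fluctuation_ensemble <- function(x, ...) {
  tibble(
    replicate = purrr::map_int(x$runs, "replicate"),
    seed = purrr::map_int(x$runs, "seed"),
    theta_star = purrr::map_dbl(x$runs, "theta_star"),
    harvest_star = purrr::map_dbl(x$runs, "harvest_star"),
    loss = harvest_loss(purrr::map_dbl(x$runs, "harvest_star"), x$reference)
  )
}

#' @export
glance.fluctuation_ensemble <- function(x, ...) {
  td <- tidy(x)
  tibble(
    replicates = nrow(td),
    mean_theta_star = mean(td$theta_star),
    sd_theta_star = sd(td$theta_star),
    mean_harvest = mean(td$harvest_star),
    mean_loss = mean(td$loss),
    deterministic_theta_star = x$deterministic$theta_star
  )
}

#' @export
autoplot.fluctuation_ensemble <- function(object, ...) {
  td <- tidy(object)
  ggplot2::ggplot(td, ggplot2::aes(x = .data$theta_star)) +
    ggplot2::geom_histogram(binwidth = 0.05, fill = "grey70", colour = "grey30") +
    ggplot2::geom_vline(xintercept = object$deterministic$theta_star,
                        linetype = "dashed") +
    ggplot2::labs(x = "Best provenance per replicate (°C)", y = "Replicates") +
    ggplot2::theme_minimal()
}
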