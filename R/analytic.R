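#' Closed-form harvest summary for a fixed life history
#'
#' For a cohort whose members all transition at the same ages, the
#' expected harvest is Gaussian in the provenance's thermal optimum:
#' E(N_H) = N0 s_tot_max exp(-(theta - T_tot)^2 / (2 omega_tot^2)),
#' where
#' * `omega_tot` is the cumulative tolerance (the inverse-sum aggregation
#'   of stage durations over squared widths),
#' * `T_tot` is the tolerance-weighted lifetime temperature, the average
#'   of the yearly temperatures with weight omega_tot^2/omega_i^2 for a
#'   year spent in stage i (the weights sum to one), and
#' * `s_tot_max` is the survival-to-harvest probability of the best
#'   possible provenance (theta = T_tot).
#' Year t belongs to stage i when a_(i-1) < t <= a_i (and to the final
#' stage after the last transition).
#'
#' @param vital A [vital_rates()] object.
#' @param history A [life_history()].
#' @param omega Per-stage tolerance widths (degrees C).
#' @param series Yearly temperatures for t = 1..H (vector or tibble from
#'   [temperature_series()]).
#' @return A `fixed_history_summary`: list with `omega_tot`, `T_tot`,
#'   `s_tot_max`, plus the inputs needed to evaluate the harvest.
#' @examples
#' v <- vital_rates(c(0.61, 0.98), 0.012)
#' fixed_history_summary(v, life_history(3, 60), omega = c(27, 27),
#'                       series = rep(10, 60))
#' @export
fixed_history_summary <- function(vital, history, omega, series) {
  stopifnot(inherits(vital, "vital_rates"), inherits(history, "life_history"))
  temps <- as_temperatures(series)
  n <- vital$n
  if (history$n != n) {
    abort("Life history and vital rates disagree on the number of stages.",
          class = "agflow_analytic_error")
  }
  H <- length(temps)
  d <- stage_durations(history, H)
  stage_of_year <- rep(seq_len(n), times = d)
  omega_tot <- cumulative_tolerance(d, omega)
  w <- omega_tot^2 / omega[stage_of_year]^2          # one weight per year, sums to 1
  T_tot <- sum(w * temps)
  log_s <- sum(d * log(vital$s_max)) +
    T_tot^2 / (2 * omega_tot^2) -
    sum(temps^2 / (2 * omega[stage_of_year]^2))
  structure(
    list(omega_tot = omega_tot, T_tot = T_tot, s_tot_max = exp(log_s),
         history = history, d = d, omega = omega, vital = vital, temps = temps),
    class = "fixed_history_summary"
  )
}

#' @export
print.fixed_history_summary <- function(x, ...) {
  cat(sprintf(
    "<fixed_history_summary> omega_tot = %.4f C, T_tot = %.4f C, s_tot_max = %.6g\n",
    x$omega_tot, x$T_tot, x$s_tot_max))
  invisible(x)
}

#' @export
glance.fixed_history_summary <- function(x, ...) {
  tibble(omega_tot = x$omega_tot, T_tot = x$T_tot, s_tot_max = x$s_tot_max)
}

#' Tolerance-weighted lifetime temperature
#'
#' The thermal optimum that maximises survival to harvest for a fixed life
#' history: each yearly temperature is weighted by omega_tot^2/omega_i^2
#' for the stage occupied that year. With constant tolerance this is the
#' plain average temperature over the rotation.
#'
#' @inheritParams fixed_history_summary
#' @return T_tot in degrees C.
#' @export
weighted_lifetime_temperature <- function(vital, history, omega, series) {
  fixed_history_summary(vital, history, omega, series)$T_tot
}

#' Maximal survival to harvest for a fixed life history
#'
#' The survival-to-harvest probability of the best-matched provenance
#' (theta = T_tot). Under warming this is strictly below its no-warming
#' value: no single optimum can match every year of a moving climate, the
#' cost of within-generation selection.
#'
#' @inheritParams fixed_history_summary
#' @return s_tot_max, a probability.
#' @export
max_total_survival <- function(vital, history, omega, series) {
  fixed_history_summary(vital, history, omega, series)$s_tot_max
}

#' Expected harvest of a fixed-history cohort
#'
#' Evaluates the Gaussian closed form at the given thermal optima. With
#' `method = "product"` the same quantity is computed as the direct
#' product of yearly stage survivals — an independent route used to verify
#' the closed form.
#'
#' @inheritParams fixed_history_summary
#' @param theta Thermal optimum (degrees C); vectorised.
#' @param N0 Initial cohort size.
#' @param method `"closed_form"` (default) or `"product"`.
#' @return Expected number of survivors in the last stage at harvest.
#' @examples
#' v <- vital_rates(c(0.61, 0.98), 0.012)
#' expected_harvest_fixed(10.8, v, life_history(3, 60), omega = c(27, 27),
#'                        series = 10 + (1.7 / 60) * (1:60))
#' @export
expected_harvest_fixed <- function(theta, vital, history, omega, series,
                                   N0 = 1, method = c("closed_form", "product")) {
  method <- match.arg(method)
  if (method == "product") {
    temps <- as_temperatures(series)
    d <- stage_durations(history, length(temps))
    stage_of_year <- rep(seq_len(vital$n), times = d)
    return(vapply(theta, function(th) {
      N0 * prod(stage_survival(th, temps, vital$s_max[stage_of_year],
                               omega[stage_of_year]))
    }, numeric(1)))
  }
  s <- fixed_history_summary(vital, history, omega, series)
  N0 * s$s_tot_max * exp(-(theta - s$T_tot)^2 / (2 * s$omega_tot^2))
}

#' Expected harvest mixing over all feasible life histories
#'
#' Individuals of a stage-structured cohort transition at stochastic ages,
#' so the expected harvest is the probability-weighted sum of the
#' fixed-history closed form over every life history feasible by harvest.
#' Agrees with the cohort projection engine ([project_cohort()]) wherever
#' enumeration is feasible; beyond the enumeration cap it falls back to
#' the projection engine (with a message), which computes the same
#' expectation without enumeration.
#'
#' @inheritParams expected_harvest_fixed
#' @param cap Maximum number of histories to enumerate.
#' @return Expected number of survivors at harvest (vectorised over
#'   `theta`).
#' @examples
#' v <- vital_rates(c(0.61, 0.98), 0.012)
#' expected_harvest(10.5, v, omega = c(27, 27), series = rep(10, 60))
#' @export
expected_harvest <- function(theta, vital, omega, series, N0 = 1, cap = 2e5) {
  stopifnot(inherits(vital, "vital_rates"))
  temps <- as_temperatures(series)
  n <- vital$n
  H <- length(temps)
  if (n == 1) {
    return(expected_harvest_fixed(theta, vital, life_history(integer(0), H),
                                  omega, temps, N0))
  }
  A <- tryCatch(enumerate_history_matrix(n, H, cap), agflow_cap_error = function(e) NULL)
  if (is.null(A)) {
    rlang::inform("Enumeration cap exceeded; using the cohort projection engine.")
    return(harvest_over_grid(theta, vital, omega, temps) * N0)
  }
  p <- history_probabilities(A, vital$g)
  keep <- p > 0
  out <- numeric(length(theta))
  for (j in which(keep)) {
    s <- fixed_history_summary(vital, life_history(A[, j], H), omega, temps)
    out <- out + p[j] * s$s_tot_max *
      exp(-(theta - s$T_tot)^2 / (2 * s$omega_tot^2))
  }
  N0 * out
}

#' Expected harvest of a phenotypically variable cohort
#'
#' Relaxes the assumption that every planted individual shares one thermal
#' optimum: optima are Gaussian around `theta_mean` with standard
#' deviation `sigma_p`. Averaging the fixed-history Gaussian harvest over
#' that distribution gives another Gaussian (the convolution):
#' E(N_H) = N0 s_tot_max (omega_tot / sqrt(omega_tot^2 + sigma_p^2))
#' exp(-(theta_mean - T_tot)^2 / (2 (omega_tot^2 + sigma_p^2))).
#' Variance costs survivors when the mean optimum is well chosen but
#' hedges against planting a badly matched provenance.
#'
#' @inheritParams expected_harvest_fixed
#' @param theta_mean Mean thermal optimum of the cohort (degrees C).
#' @param sigma_p Within-cohort standard deviation of the optimum
#'   (degrees C, >= 0); 0 recovers the homogeneous cohort.
#' @param method `"closed_form"` (default) or `"quadrature"` (numerical
#'   integration of the homogeneous closed form against the Gaussian
#'   distribution of optima, the independent check).
#' @return Expected number of survivors at harvest.
#' @export
mixture_expected_harvest <- function(theta_mean, sigma_p, vital, history, omega,
                                     series, N0 = 1,
                                     method = c("closed_form", "quadrature")) {
  method <- match.arg(method)
  if (sigma_p < 0) abort("`sigma_p` must be non-negative.", class = "agflow_analytic_error")
  s <- fixed_history_summary(vital, history, omega, series)
  if (method == "quadrature") {
    if (sigma_p == 0) {
      return(expected_harvest_fixed(theta_mean, vital, history, omega, series, N0))
    }
    f <- function(th) {
      stats::dnorm(th, theta_mean, sigma_p) *
        s$s_tot_max * exp(-(th - s$T_tot)^2 / (2 * s$omega_tot^2))
    }
    val <- integrate(f, theta_mean - 12 * sigma_p, theta_mean + 12 * sigma_p,
                     rel.tol = 1e-12, abs.tol = 0)$value
    return(N0 * val)
  }
  v2 <- s$omega_tot^2 + sigma_p^2
  N0 * s$s_tot_max * (s$omega_tot / sqrt(v2)) *
    exp(-(theta_mean - s$T_tot)^2 / (2 * v2))
}
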