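#' Stage durations implied by a life history
#'
#' Splits the rotation into the number of years spent in each stage:
#' d_1 = a_1, d_i = a_i - a_(i-1), and d_n = H - a_(n-1) for the final
#' stage (possibly 0 when the last transition happens at harvest).
#'
#' @param history A [life_history()].
#' @param H Rotation length; defaults to the history's own horizon.
#' @return Integer vector of durations summing to H.
#' @examples
#' stage_durations(life_history(3, 60))
#' @export
stage_durations <- function(history, H = history$H) {
  stopifnot(inherits(history, "life_history"))
  diff(c(0L, history$a, as.integer(H)))
}

#' Cumulative (lifetime) thermal tolerance
#'
#' Aggregates per-stage tolerance widths over a lifetime split into stage
#' durations d_i: omega_tot^2 = (sum_i d_i / omega_i^2)^-1. With a
#' constant width omega this reduces to omega / sqrt(H): each additional
#' year of Gaussian selection narrows the lifetime tolerance.
#'
#' @param d Per-stage durations in years (from [stage_durations()]).
#' @param omega Per-stage tolerance widths (degrees C, > 0).
#' @return The cumulative tolerance omega_tot in degrees C.
#' @examples
#' cumulative_tolerance(d = c(3, 57), omega = c(5, 15))
#' @export
cumulative_tolerance <- function(d, omega) {
  check_widths(d, omega)
  if (sum(d) == 0) {
    abort("Cumulative tolerance is undefined for an empty lifetime.",
          class = "agflow_tolerance_error")
  }
  sqrt(1 / sum(d / omega^2))
}

#' Tolerance-ontogeny profile
#'
#' Per-stage tolerance widths under the linear ontogeny model
#' omega_i^2 = omega_1^2 (1 + b (i - 1)). Positive b makes older stages
#' more tolerant; b = 0 keeps tolerance constant across life. Instead of
#' `b` the profile may be given as the last/first width ratio
#' omega_n / omega_1 = sqrt(1 + b (n - 1)).
#'
#' @param n Number of stages.
#' @param omega1 First-stage width (degrees C, > 0).
#' @param b Ontogeny slope (> -1/(n-1)); give either `b` or `ratio`.
#' @param ratio Last/first width ratio omega_n / omega_1 (> 0).
#' @return Numeric vector of per-stage widths omega_i.
#' @examples
#' tolerance_profile(n = 5, omega1 = 3, ratio = 9)
#' @export
tolerance_profile <- function(n, omega1, b = NULL, ratio = NULL) {
  b <- resolve_ontogeny_slope(n, b, ratio)
  if (omega1 <= 0) abort("`omega1` must be positive.", class = "agflow_tolerance_error")
  omega1 * sqrt(1 + b * (seq_len(n) - 1))
}

#' @rdname tolerance_profile
#' @export
ontogeny_slope_from_ratio <- function(n, ratio) {
  if (ratio <= 0) abort("`ratio` must be positive.", class = "agflow_tolerance_error")
  if (n < 2) abort("A ratio needs at least two stages.", class = "agflow_tolerance_error")
  (ratio^2 - 1) / (n - 1)
}

resolve_ontogeny_slope <- function(n, b, ratio) {
  if (is.null(b) == is.null(ratio)) {
    abort("Give exactly one of `b` or `ratio`.", class = "agflow_tolerance_error")
  }
  if (is.null(b)) b <- ontogeny_slope_from_ratio(n, ratio)
  if (n > 1 && b <= -1 / (n - 1)) {
    abort(sprintf("`b` must exceed -1/(n-1) = %g so every width stays positive.",
                  -1 / (n - 1)),
          class = "agflow_tolerance_error")
  }
  b
}

#' Calibrate the first-stage width against a fixed cumulative tolerance
#'
#' Given a target lifetime tolerance, an ontogeny slope and a typical life
#' history, solves the lifetime-aggregation identity for the first-stage
#' width: omega_1^2 = omega_tot^2 sum_i d_i / (1 + b (i - 1)). Holding
#' the cumulative tolerance fixed while varying `b` is how profiles with
#' different ontogeny are made comparable across species and scenarios.
#'
#' @param omega_tot_target Target cumulative tolerance (degrees C, > 0).
#' @param history A [life_history()] supplying the stage durations.
#' @param b Ontogeny slope; give either `b` or `ratio`.
#' @param ratio Last/first width ratio.
#' @param H Rotation length; defaults to the history's horizon.
#' @return The calibrated first-stage width omega_1 (degrees C).
#' @examples
#' calibrate_omega1(3.5, life_history(3, 60), b = 0)
#' @export
calibrate_omega1 <- function(omega_tot_target, history, b = NULL, ratio = NULL,
                             H = history$H) {
  stopifnot(inherits(history, "life_history"))
  if (omega_tot_target <= 0) {
    abort("`omega_tot_target` must be positive.", class = "agflow_tolerance_error")
  }
  n <- history$n
  b <- resolve_ontogeny_slope(n, b, ratio)
  d <- stage_durations(history, H)
  omega_tot_target * sqrt(sum(d / (1 + b * (seq_len(n) - 1))))
}

#' Calibrated per-stage widths in one call
#'
#' Convenience wrapper: calibrates omega_1 with [calibrate_omega1()] and
#' expands the full profile with [tolerance_profile()].
#'
#' @inheritParams calibrate_omega1
#' @return Numeric vector of per-stage widths.
#' @export
calibrated_profile <- function(omega_tot_target, history, b = NULL, ratio = NULL,
                               H = history$H) {
  n <- history$n
  b <- resolve_ontogeny_slope(n, b, ratio)
  omega1 <- calibrate_omega1(omega_tot_target, history, b = b, H = H)
  tolerance_profile(n, omega1, b = b)
}

#' Effective cumulative tolerance of a stochastic life cycle
#'
#' The theoretical cumulative tolerance is computed from one typical life
#' history, but survivors at harvest realise many histories, so the width
#' of the provenance-response curve of the whole cohort can differ from
#' the theoretical value. This diagnostic measures that realised width: it
#' evaluates the expected harvest across a provenance grid under a
#' constant climate (no warming) and fits a quadratic to log harvest
#' around its maximum; the curvature gives the effective Gaussian width.
#' With no life-history variation (all g_i = 1, or a single feasible
#' history) it equals the theoretical value exactly.
#'
#' @param vital A [vital_rates()] object.
#' @param omega Per-stage tolerance widths.
#' @param H Rotation length in years.
#' @param T0 Constant temperature used for the probe climate (degrees C).
#' @param halfwidth Half-range of the probe grid around T0 (degrees C).
#' @param step Grid step (degrees C).
#' @return The effective cumulative tolerance (degrees C).
#' @export
effective_cumulative_tolerance <- function(vital, omega, H, T0 = 10,
                                           halfwidth = 1, step = 0.01) {
  stopifnot(inherits(vital, "vital_rates"))
  series <- rep(T0, H)
  thetas <- T0 + seq(-halfwidth, halfwidth, by = step)
  h <- expected_harvest(thetas, vital, omega, series)
  if (any(h <= 0)) {
    abort("Harvest vanished on the probe grid; widen the tolerances or shrink the grid.",
          class = "agflow_tolerance_error")
  }
  x <- thetas - T0
  fit <- lm(log(h) ~ x + I(x^2))
  c2 <- coef(fit)[["I(x^2)"]]
  if (c2 >= 0) {
    abort("Log-harvest is not concave on the probe grid; cannot measure a width.",
          class = "agflow_tolerance_error")
  }
  sqrt(-1 / (2 * c2))
}

check_widths <- function(d, omega) {
  if (length(d) != length(omega)) {
    abort("`d` and `omega` must have one entry per stage.",
          class = "agflow_tolerance_error")
  }
  if (any(omega <= 0)) {
    abort("Tolerance widths must be positive.", class = "agflow_tolerance_error")
  }
  if (any(d < 0)) abort("Durations cannot be negative.", class = "agflow_tolerance_error")
  invisible(NULL)
}
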