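#' Project a planted cohort through a climate series
#'
#' Iterates the expectation dynamics N_(t+1) = M(theta, T_(t+1)) N_t over
#' the yearly temperatures of the rotation and records the expected
#' abundance of every stage each year. The harvest is the expected number
#' of individuals in the last stage at year H. Abundances are
#' expectations, not individual-level realisations: total abundance can
#' only decrease (no reproduction) and the dynamics are linear in the
#' initial vector.
#'
#' @param theta Thermal optimum of the provenance (degrees C).
#' @param vital A [vital_rates()] object.
#' @param omega Per-stage tolerance widths (degrees C).
#' @param series Yearly temperatures for t = 1..H: either the tibble from
#'   [temperature_series()] or a plain numeric vector.
#' @param N0 Initial stage vector; by default one seedling-equivalent in
#'   stage 1, so the harvest reads as a per-seedling probability.
#' @param growth_climate Should growth also decline with mismatch?
#' @return A `cohort_trajectory` object; see [tidy.cohort_trajectory()]
#'   and [harvest()].
#' @examples
#' v <- vital_rates(c(0.61, 0.98), 0.012)
#' sc <- climate_scenario(10, 60, total_warming = 1.7)
#' traj <- project_cohort(theta = 10.5, v, omega = c(27, 27), temperature_series(sc))
#' harvest(traj)
#' @export
project_cohort <- function(theta, vital, omega, series, N0 = NULL,
                           growth_climate = FALSE) {
  stopifnot(inherits(vital, "vital_rates"))
  temps <- as_temperatures(series)
  n <- vital$n
  H <- length(temps)
  if (is.null(N0)) N0 <- c(1, rep(0, n - 1))
  if (length(N0) != n || any(N0 < 0)) {
    abort("`N0` must be a non-negative vector with one entry per stage.",
          class = "agflow_cohort_error")
  }
  N <- matrix(0, H + 1, n)
  N[1, ] <- N0
  for (t in seq_len(H)) {
    M <- projection_matrix(theta, temps[t], vital, omega, growth_climate)
    N[t + 1, ] <- as.vector(unclass_matrix(M) %*% N[t, ])
  }
  structure(
    list(N = N, theta = theta, temps = temps, n = n, H = H),
    class = "cohort_trajectory"
  )
}

#' Expected survivors in the last stage at harvest
#'
#' @param trajectory A `cohort_trajectory` from [project_cohort()].
#' @return Expected abundance of the last stage at year H.
#' @export
harvest <- function(trajectory) {
  stopifnot(inherits(trajectory, "cohort_trajectory"))
  trajectory$N[trajectory$H + 1, trajectory$n]
}

#' @export
print.cohort_trajectory <- function(x, ...) {
  cat(sprintf(
    "<cohort_trajectory> theta = %g C, %d stages, H = %d; harvest = %.6g\n",
    x$theta, x$n, x$H, harvest(x)))
  invisible(x)
}

#' Tidy a cohort trajectory into long form
#'
#' @param x A `cohort_trajectory`.
#' @param ... Unused.
#' @return A tibble with columns `year` (0..H), `stage` and `abundance`.
#' @export
tidy.cohort_trajectory <- function(x, ...) {
  tibble(
    year = rep(0:x$H, times = x$n),
    stage = rep(seq_len(x$n), each = x$H + 1),
    abundance = as.vector(x$N)
  )
}

#' @export
glance.cohort_trajectory <- function(x, ...) {
  tibble(theta = x$theta, n_stages = x$n, H = x$H,
         harvest = harvest(x), total_final = sum(x$N[x$H + 1, ]))
}

#' @export
autoplot.cohort_trajectory <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(x = .data$year, y = .data$abundance,
                               colour = factor(.data$stage))) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Year since planting", y = "Expected abundance",
                  colour = "Stage") +
    ggplot2::theme_minimal()
}

#' Expected harvest across many provenances at once
#'
#' Runs the cohort expectation dynamics simultaneously for a vector of
#' thermal optima, exploiting the bidiagonal structure of the projection
#' matrix. This is the engine behind the provenance grid search.
#'
#' @inheritParams project_cohort
#' @param theta Vector of thermal optima (degrees C).
#' @return Numeric vector of expected harvests, one per `theta`.
#' @export
harvest_over_grid <- function(theta, vital, omega, series, N0 = NULL,
                              growth_climate = FALSE) {
  stopifnot(inherits(vital, "vital_rates"))
  temps <- as_temperatures(series)
  n <- vital$n
  if (length(omega) != n) {
    abort("`omega` must have one width per stage.", class = "agflow_cohort_error")
  }
  if (is.null(N0)) N0 <- c(1, rep(0, n - 1))
  nt <- length(theta)
  N <- matrix(N0, n, nt)
  inv2o2 <- 1 / (2 * omega^2)
  g <- c(vital$g, 0)
  for (t in seq_along(temps)) {
    mis <- (theta - temps[t])^2           # one mismatch per provenance
    S <- vital$s_max * exp(-outer(inv2o2, mis))
    geff <- if (growth_climate) {
      g * exp(-outer(inv2o2, mis))        # last row multiplied by g_n = 0
    } else {
      matrix(g, n, nt)
    }
    grown <- S * geff * N
    N <- S * N - grown
    if (n > 1) N[2:n, ] <- N[2:n, , drop = FALSE] + grown[1:(n - 1), , drop = FALSE]
  }
  N[n, ]
}

as_temperatures <- function(series) {
  if (is.data.frame(series)) {
    if (!"temperature" %in% names(series)) {
      abort("`series` data frame must have a `temperature` column.",
            class = "agflow_cohort_error")
    }
    series <- series$temperature
  }
  if (!is.numeric(series) || length(series) < 1L) {
    abort("`series` must be a numeric vector of yearly temperatures.",
          class = "agflow_cohort_error")
  }
  as.numeric(series)
}
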