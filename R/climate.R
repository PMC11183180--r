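#' Warming and fluctuation presets
#'
#' Named scenarios for the total rise in mean annual temperature over a
#' 60-year rotation, taken from end-of-century multi-model projections
#' (SSP2-4.5, SSP3-7.0, SSP5-8.5 plus a no-change control), and for the
#' standard deviation of interannual temperature fluctuations around the
#' trend (30% below, at, and 30% above the observed global-average local
#' year-to-year sd of about 0.5 degrees C).
#'
#' @param name Preset name.
#' @return A single numeric value: total warming in degrees C over 60 years
#'   for `warming_preset()`, fluctuation sd in degrees C for
#'   `fluctuation_preset()`.
#' @examples
#' warming_preset("intermediate")
#' fluctuation_preset("moderate")
#' @export
warming_preset <- function(name = c("control", "intermediate", "high", "very_high")) {
  name <- match.arg(name)
  c(control = 0, intermediate = 1.7, high = 2.6, very_high = 3.3)[[name]]
}

#' @rdname warming_preset
#' @export
fluctuation_preset <- function(name = c("weak", "moderate", "strong")) {
  name <- match.arg(name)
  c(weak = 0.35, moderate = 0.5, strong = 0.65)[[name]]
}

#' Per-year warming rate from the warming realised over a rotation
#'
#' Converts a total temperature rise over the rotation into the slope of a
#' linear warming trend, k = total / H.
#'
#' @param total_warming Temperature rise over the whole rotation (degrees C).
#' @param H Rotation length in years (positive integer).
#' @return Warming rate k in degrees C per year.
#' @examples
#' rate_from_endpoints(1.7, 60)
#' @export
rate_from_endpoints <- function(total_warming, H) {
  check_horizon(H)
  total_warming / H
}

#' Define a climate scenario for one rotation
#'
#' A scenario is a linear warming trend T_t = T0 + k t for planting years
#' t = 1..H, optionally with independent Gaussian interannual fluctuations
#' around the trend. The planting-year temperature (t = 0) never enters the
#' model: selection acts from the first full year, whose expected
#' temperature is T0 + k.
#'
#' @param T0 Baseline mean annual temperature at planting (degrees C).
#' @param H Rotation length in years.
#' @param k Warming rate (degrees C / year). Give either `k` or
#'   `total_warming`.
#' @param total_warming Total rise over the rotation (degrees C), or a
#'   preset name accepted by [warming_preset()] (interpreted as a rise over
#'   60 years regardless of `H`, matching how the projections are quoted).
#' @param sigma_f Standard deviation of interannual fluctuations
#'   (degrees C, >= 0), or a preset name accepted by [fluctuation_preset()].
#' @param seed Integer seed used when drawing fluctuations. Required when
#'   `sigma_f > 0` so that every series is reproducible.
#' @return An object of class `climate_scenario`.
#' @examples
#' climate_scenario(T0 = 10, H = 60, total_warming = "intermediate")
#' @export
climate_scenario <- function(T0, H, k = NULL, total_warming = NULL,
                             sigma_f = 0, seed = NULL) {
  check_horizon(H)
  if (is.character(sigma_f)) sigma_f <- fluctuation_preset(sigma_f)
  if (!is.numeric(sigma_f) || length(sigma_f) != 1L || sigma_f < 0) {
    abort("`sigma_f` must be a single non-negative number.", class = "agflow_scenario_error")
  }
  if (is.null(k) == is.null(total_warming)) {
    abort("Give exactly one of `k` or `total_warming`.", class = "agflow_scenario_error")
  }
  if (is.null(k)) {
    if (is.character(total_warming)) {
      k <- rate_from_endpoints(warming_preset(total_warming), 60)
    } else {
      k <- rate_from_endpoints(total_warming, H)
    }
  }
  structure(
    list(T0 = T0, k = k, H = as.integer(H), sigma_f = sigma_f,
         seed = if (!is.null(seed)) as.integer(seed)),
    class = "climate_scenario"
  )
}

#' @export
print.climate_scenario <- function(x, ...) {
  cat(sprintf(
    "<climate_scenario> T0 = %g C, k = %g C/yr (%+.2f C over %d yr), sigma_f = %g C%s\n",
    x$T0, x$k, x$k * x$H, x$H, x$sigma_f,
    if (is.null(x$seed)) "" else sprintf(", seed = %d", x$seed)
  ))
  invisible(x)
}

#' Generate the yearly temperature series of a scenario
#'
#' Returns one temperature per planting year t = 1..H. With `sigma_f = 0`
#' the series is exactly the trend T0 + k t; otherwise each year adds an
#' independent Gaussian deviate with sd `sigma_f`, drawn reproducibly from
#' the scenario seed.
#'
#' @param scenario A [climate_scenario()].
#' @return A tibble with columns `year`, `trend` and `temperature`.
#' @examples
#' temperature_series(climate_scenario(10, 60, total_warming = 1.7))
#' @export
temperature_series <- function(scenario) {
  stopifnot(inherits(scenario, "climate_scenario"))
  t <- seq_len(scenario$H)
  trend <- scenario$T0 + scenario$k * t
  if (scenario$sigma_f > 0) {
    if (is.null(scenario$seed)) {
      abort("A seed is required to draw interannual fluctuations reproducibly.",
            class = "agflow_config_error")
    }
    noise <- withr::with_seed(scenario$seed, rnorm(scenario$H, 0, scenario$sigma_f))
  } else {
    noise <- 0
  }
  tibble(year = t, trend = trend, temperature = trend + noise)
}

check_horizon <- function(H) {
  if (!is.numeric(H) || length(H) != 1L || H < 1 || H != floor(H)) {
    abort("`H` must be a positive integer number of years.",
          class = "agflow_scenario_error")
  }
  invisible(H)
}
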