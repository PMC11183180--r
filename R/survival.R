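#' Gaussian climate-dependent stage survival
#'
#' Annual survival in a stage declines as a Gaussian function of the
#' mismatch between the provenance's thermal optimum and the yearly
#' temperature: s = s_max exp(-(theta - T)^2 / (2 omega^2)). At one
#' tolerance width of mismatch survival is reduced by a factor
#' 1 - exp(-1/2), about 40%.
#'
#' @param theta Thermal optimum of the provenance (degrees C). Vectorised.
#' @param temp Realised mean annual temperature (degrees C).
#' @param s_max Maximal annual survival, in (0, 1].
#' @param omega Tolerance width of the stage (degrees C, > 0).
#' @return Survival probability (same length as the longest argument).
#' @examples
#' stage_survival(theta = 12, temp = 10, s_max = 0.98, omega = 2)
#' @export
stage_survival <- function(theta, temp, s_max, omega) {
  if (any(omega <= 0)) {
    abort("`omega` must be positive.", class = "agflow_survival_error")
  }
  if (any(s_max <= 0) || any(s_max > 1)) {
    abort("`s_max` must lie in (0, 1].", class = "agflow_survival_error")
  }
  s_max * exp(-(theta - temp)^2 / (2 * omega^2))
}

#' Temperature- and provenance-dependent projection matrix
#'
#' Builds the annual transition matrix of a provenance with thermal
#' optimum `theta` in a year with temperature `temp`: stasis
#' s_i(theta,T)(1-g_i), growth s_i(theta,T) g_i, and absorbing last-stage
#' survival s_n(theta,T). At theta = T this recovers the empirical matrix
#' exactly. With `growth_climate = TRUE` the conditional growth
#' probability is additionally damped by the same Gaussian factor, so both
#' growth and survival respond to mismatch (a model variant; the default
#' keeps growth climate-independent).
#'
#' @param theta Thermal optimum (degrees C).
#' @param temp Yearly temperature (degrees C).
#' @param vital A [vital_rates()] object.
#' @param omega Per-stage tolerance widths (degrees C).
#' @param growth_climate Should growth also decline with mismatch?
#' @return A [stage_matrix()].
#' @examples
#' v <- vital_rates(c(0.61, 0.98), 0.012)
#' projection_matrix(theta = 10, temp = 10, v, omega = c(5, 15))
#' @export
projection_matrix <- function(theta, temp, vital, omega, growth_climate = FALSE) {
  stopifnot(inherits(vital, "vital_rates"))
  n <- vital$n
  if (length(omega) != n) {
    abort("`omega` must have one width per stage.", class = "agflow_survival_error")
  }
  s <- stage_survival(theta, temp, vital$s_max, omega)
  g <- vital$g
  if (growth_climate && n > 1) {
    g <- g * exp(-(theta - temp)^2 / (2 * omega[-n]^2))
  }
  U <- matrix(0, n, n)
  diag(U) <- s * c(1 - g, 1)
  if (n > 1) U[cbind(2:n, 1:(n - 1))] <- s[-n] * g
  stage_matrix(U)
}
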