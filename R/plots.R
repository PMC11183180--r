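#' Plot a strategy comparison
#'
#' Bar chart of the harvest loss of each seed-sourcing strategy relative
#' to the local provenance under no climate change.
#'
#' @param comparison Tibble from [compare_strategies()].
#' @return A ggplot object.
#' @export
plot_strategy_comparison <- function(comparison) {
  stopifnot(all(c("strategy", "loss") %in% names(comparison)))
  df <- dplyr::mutate(
    comparison,
    strategy = factor(.data$strategy, levels = c("local", "quarter_rotation", "best"))
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$strategy, y = .data$loss)) +
    ggplot2::geom_col(fill = "grey60") +
    ggplot2::geom_hline(yintercept = 0) +
    ggplot2::labs(x = NULL, y = "Harvest loss vs. local, no warming") +
    ggplot2::theme_minimal()
}

#' Plot harvest curves of an ensemble
#'
#' Overlays the per-replicate harvest-vs-provenance curves (relative to
#' the no-warming local harvest) with the deterministic curve.
#'
#' @param ensemble A `fluctuation_ensemble`.
#' @param max_curves Cap on the number of replicate curves drawn.
#' @return A ggplot object.
#' @export
plot_ensemble_curves <- function(ensemble, max_curves = 25) {
  stopifnot(inherits(ensemble, "fluctuation_ensemble"))
  keep <- ensemble$runs[seq_len(min(max_curves, length(ensemble$runs)))]
  curves <- purrr::map_dfr(keep, function(r) {
    dplyr::mutate(r$curve, replicate = r$replicate,
                  relative = .data$harvest / ensemble$reference)
  })
  det <- dplyr::mutate(ensemble$deterministic$curve,
                       relative = .data$harvest / ensemble$reference)
  ggplot2::ggplot(curves,
                  ggplot2::aes(x = .data$theta, y = .data$relative,
                               group = .data$replicate)) +
    ggplot2::geom_line(alpha = 0.25, colour = "steelblue") +
    ggplot2::geom_line(data = det, ggplot2::aes(group = NULL), colour = "black") +
    ggplot2::labs(x = "Provenance thermal optimum (°C)",
                  y = "Harvest relative to local, no warming") +
    ggplot2::theme_minimal()
}
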