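#' Reference two-stage life cycle
#'
#' A juvenile/adult life cycle with maximal survivals 0.61 and 0.98 and a
#' conditional growth probability of 0.012 per year — slow maturation with
#' high adult survival, typical of a long-lived conifer. Used throughout
#' the documentation and tests as the canonical worked example, with a
#' default 60-year rotation and a 100-year long-rotation variant.
#'
#' @return A list with elements `vital` (a [vital_rates()]), `H` (60) and
#'   `H_long` (100).
#' @examples
#' two_stage_example()$vital
#' @export
two_stage_example <- function() {
  list(vital = vital_rates(s_max = c(0.61, 0.98), g = 0.012),
       H = 60L, H_long = 100L)
}

#' Draw random conformant life cycles
#'
#' Draws `count` sets of vital rates with every maximal survival and
#' growth probability uniform on `s_range` / `g_range`. For life cycles
#' with more than two stages, draws whose typical life history (from the
#' fundamental matrix) fails to reach the last stage by harvest are
#' rejected and redrawn — the same filter applied to empirical matrices.
#'
#' @param count Number of life cycles.
#' @param n Number of stages.
#' @param H Rotation length used by the reachability filter.
#' @param s_range,g_range Bounds of the uniform draws.
#' @param seed Integer seed (draws are reproducible).
#' @return A list of [vital_rates()] objects.
#' @examples
#' random_life_cycles(3, n = 2, H = 60, seed = 1)
#' @export
random_life_cycles <- function(count, n = 2, H = 60, s_range = c(0.01, 0.99),
                               g_range = c(0.01, 0.99), seed = 1) {
  check_horizon(H)
  withr::with_seed(seed, {
    out <- vector("list", count)
    kept <- 0L
    tried <- 0L
    while (kept < count) {
      tried <- tried + 1L
      if (tried > 100 * count + 100) {
        abort("More than 99% of draws rejected; the horizon is too short for this stage count.",
              class = "agflow_fixture_error")
      }
      v <- vital_rates(
        s_max = stats::runif(n, s_range[1], s_range[2]),
        g = stats::runif(n - 1, g_range[1], g_range[2])
      )
      ok <- tryCatch({
        typical_life_history(fundamental_matrix(rebuild_matrix(v)), H)
        TRUE
      }, agflow_species_excluded = function(e) FALSE)
      if (ok) {
        kept <- kept + 1L
        out[[kept]] <- v
      }
    }
    out
  })
}

#' Construct a species-like stage matrix with a target first-stage duration
#'
#' Builds a conformant stage matrix whose typical (fundamental-matrix)
#' first-stage duration is within one year of `target`, standing in for
#' empirical tree matrices that differ mainly in how long individuals
#' linger in the youngest stage. Later stages get moderately high survival
#' and growth rates drawn reproducibly from the seed, re-drawn until the
#' typical history reaches the last stage by `H`.
#'
#' @param n Number of stages (>= 2).
#' @param target Target expected first-stage duration in years (>= 1).
#' @param H Rotation length the typical history must fit into.
#' @param seed Integer seed.
#' @return A [stage_matrix()].
#' @examples
#' species_like_matrix(n = 5, target = 4, seed = 2)
#' @export
species_like_matrix <- function(n, target, H = 60, seed = 1) {
  if (n < 2) abort("Need at least two stages.", class = "agflow_fixture_error")
  if (target < 1) abort("`target` must be at least one year.", class = "agflow_fixture_error")
  check_horizon(H)
  # expected first-stage duration is 1 / (1 - s1 (1 - g1)); pin it to target,
  # keeping survival strictly above the stasis so growth stays positive
  stay1 <- 1 - 1 / target
  s1 <- max(0.61, stay1 + 0.3 * (1 - stay1))
  g1 <- 1 - stay1 / s1
  withr::with_seed(seed, {
    for (attempt in 1:200) {
      s_rest <- stats::runif(n - 1, 0.9, 0.98)
      g_rest <- stats::runif(max(n - 2, 0), 0.3, 0.8)
      v <- vital_rates(s_max = c(s1, s_rest), g = c(g1, g_rest))
      M <- rebuild_matrix(v)
      ok <- tryCatch({
        typical_life_history(fundamental_matrix(M), H)
        TRUE
      }, agflow_species_excluded = function(e) FALSE)
      if (ok) {
        d1 <- fundamental_matrix(M)[1, 1]
        if (abs(d1 - target) > 1) {
          abort("Realised first-stage duration misses the target by more than a year.",
                class = "agflow_fixture_error")
        }
        return(M)
      }
    }
    abort("Could not reach the last stage by H with this target; raise H or lower `target`.",
          class = "agflow_fixture_error")
  })
}
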