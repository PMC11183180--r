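#' Stage transition matrices for a non-reproducing cohort
#'
#' A stage matrix holds the survival/growth component of an annual
#' transition matrix: entry (i, j) is the probability that an individual
#' now in stage j is alive and in stage i one year later. The model tracks
#' a planted cohort with no reproduction, and trees neither shrink nor skip
#' stages, so only the diagonal (stasis) and first subdiagonal (one-step
#' growth) may be non-zero; the deficit of each column sum from 1 is
#' mortality. `as_stage_matrix()` validates (and under `policy = "drop"`
#' cleans) a raw square table; `stage_matrix()` is the strict constructor.
#'
#' Empirical matrices often carry entries the model excludes: fecundity in
#' the first row, retrogression above the diagonal, stage-skipping below
#' the subdiagonal. Under `policy = "drop"` those entries are zeroed and
#' recorded in the conformance report (see [conformance_report()]); the
#' removed mass becomes additional mortality and is never renormalised back
#' into the remaining transitions. Under `policy = "strict"` any
#' non-conforming entry above `tol` is an error.
#'
#' @param U A square numeric matrix of per-year transition probabilities,
#'   stages ordered youngest to oldest.
#' @param policy `"strict"` (default) or `"drop"`.
#' @param tol Tolerance below which a non-conforming entry is silently
#'   zeroed under `"strict"`.
#' @return A `stage_matrix`: the cleaned numeric matrix with a conformance
#'   report attached as an attribute.
#' @examples
#' U <- rbind(c(0.60268, 0), c(0.00732, 0.98))
#' stage_matrix(U)
#' @export
stage_matrix <- function(U) {
  as_stage_matrix(U, policy = "strict")
}

#' @rdname stage_matrix
#' @export
as_stage_matrix <- function(U, policy = c("strict", "drop"), tol = 0) {
  policy <- match.arg(policy)
  U <- as.matrix(U)
  if (nrow(U) != ncol(U) || nrow(U) < 1L) {
    abort("A stage matrix must be square.", class = "agflow_matrix_error")
  }
  if (!is.numeric(U) || anyNA(U) || any(U < 0)) {
    abort("Stage-matrix entries must be non-negative numbers.",
          class = "agflow_matrix_error")
  }
  n <- nrow(U)
  allowed <- diag(TRUE, n)
  if (n > 1) allowed[cbind(2:n, 1:(n - 1))] <- TRUE
  bad <- which(!allowed & U != 0, arr.ind = TRUE)
  report <- tibble(
    row = integer(), column = integer(), value = double(), kind = character()
  )
  if (nrow(bad) > 0) {
    kind <- ifelse(bad[, "row"] < bad[, "col"],
                   ifelse(bad[, "row"] == 1L, "fecundity_or_retrogression", "retrogression"),
                   "stage_skip")
    report <- tibble(
      row = as.integer(bad[, "row"]),
      column = as.integer(bad[, "col"]),
      value = U[bad],
      kind = kind
    )
    if (policy == "strict" && any(report$value > tol)) {
      abort(
        paste0("Non-conforming entries (retrogression, stage skips or fecundity) ",
               "found; use policy = \"drop\" to zero them. Offending entries: ",
               paste(sprintf("(%d,%d)=%g", report$row, report$column, report$value),
                     collapse = ", ")),
        class = "agflow_conformance_error"
      )
    }
    U[bad] <- 0
  }
  if (any(U > 1)) {
    abort("Transition probabilities must lie in [0, 1].", class = "agflow_matrix_error")
  }
  cs <- colSums(U)
  if (any(cs > 1 + 1e-9)) {
    abort(sprintf("Column sums must not exceed 1 (max %.6f): survival cannot exceed certainty.",
                  max(cs)),
          class = "agflow_matrix_error")
  }
  structure(U, class = c("stage_matrix", "matrix", "array"),
            conformance = report)
}

#' Conformance report of a stage matrix
#'
#' @param M A [stage_matrix()].
#' @return A tibble listing every entry zeroed during conformance
#'   enforcement (`row`, `column`, `value`, `kind`); empty when the input
#'   was already conformant.
#' @export
conformance_report <- function(M) {
  stopifnot(inherits(M, "stage_matrix"))
  attr(M, "conformance") %||%
    tibble(row = integer(), column = integer(), value = double(), kind = character())
}

#' @export
print.stage_matrix <- function(x, ...) {
  cat(sprintf("<stage_matrix> %d stages\n", nrow(x)))
  print(unclass_matrix(x))
  rep <- conformance_report(x)
  if (nrow(rep) > 0) {
    cat(sprintf("%d non-conforming entr%s dropped (total mass %g)\n",
                nrow(rep), if (nrow(rep) == 1) "y" else "ies", sum(rep$value)))
  }
  invisible(x)
}

unclass_matrix <- function(x) {
  attr(x, "conformance") <- NULL
  unclass(x)
}

#' Per-stage vital rates at the thermal optimum
#'
#' Holds the maximal annual survival probabilities s_i,max (one per stage)
#' and the conditional growth probabilities g_i (probability of advancing
#' to stage i+1 given survival; the last stage is absorbing, g_n = 0).
#'
#' @param s_max Numeric vector of per-stage maximal survivals, each in (0, 1].
#' @param g Numeric vector of length `length(s_max) - 1` of conditional
#'   growth probabilities in [0, 1].
#' @return A `vital_rates` object.
#' @examples
#' vital_rates(s_max = c(0.61, 0.98), g = 0.012)
#' @export
vital_rates <- function(s_max, g) {
  n <- length(s_max)
  if (n < 1L) abort("At least one stage is required.", class = "agflow_rates_error")
  if (length(g) != n - 1L) {
    abort("`g` must have one entry per transition, i.e. length(s_max) - 1.",
          class = "agflow_rates_error")
  }
  if (any(s_max <= 0) || any(s_max > 1)) {
    abort("Maximal survivals must lie in (0, 1].", class = "agflow_rates_error")
  }
  if (n > 1 && (any(g < 0) || any(g > 1))) {
    abort("Growth probabilities must lie in [0, 1].", class = "agflow_rates_error")
  }
  structure(list(n = n, s_max = as.numeric(s_max), g = as.numeric(g)),
            class = "vital_rates")
}

#' @export
print.vital_rates <- function(x, ...) {
  cat(sprintf("<vital_rates> %d stages\n  s_max: %s\n  g:     %s\n",
              x$n, paste(signif(x$s_max, 4), collapse = ", "),
              if (x$n > 1) paste(signif(x$g, 4), collapse = ", ") else "-"))
  invisible(x)
}

#' @export
tidy.vital_rates <- function(x, ...) {
  tibble(stage = seq_len(x$n), s_max = x$s_max, g = c(x$g, 0))
}

#' Decompose a stage matrix into maximal vital rates
#'
#' Assumes the empirical matrix was measured at the population's thermal
#' optimum, so stasis = s_i (1 - g_i) and growth = s_i g_i. Survival is
#' recovered as the column sum s_i = U[i,i] + U[i+1,i] (last stage:
#' s_n = U[n,n]) and growth as g_i = U[i+1,i] / s_i.
#'
#' @param M A [stage_matrix()].
#' @return A [vital_rates()] object.
#' @examples
#' decompose_matrix(stage_matrix(rbind(c(0.60268, 0), c(0.00732, 0.98))))
#' @export
decompose_matrix <- function(M) {
  stopifnot(inherits(M, "stage_matrix"))
  n <- nrow(M)
  if (n == 1L) return(vital_rates(s_max = M[1, 1], g = numeric(0)))
  growth <- M[cbind(2:n, 1:(n - 1))]
  s <- c(diag(M)[-n] + growth, M[n, n])
  if (any(s == 0 & c(growth, 0) > 0)) {
    abort("Zero survival with non-zero growth is inconsistent.",
          class = "agflow_matrix_error")
  }
  g <- ifelse(s[-n] > 0, growth / s[-n], 0)
  vital_rates(s_max = s, g = g)
}

#' Rebuild the optimal-temperature stage matrix from vital rates
#'
#' Inverse of [decompose_matrix()]: the matrix an unstressed cohort
#' (temperature at the thermal optimum) would follow.
#'
#' @param vital A [vital_rates()] object.
#' @return A [stage_matrix()].
#' @export
rebuild_matrix <- function(vital) {
  stopifnot(inherits(vital, "vital_rates"))
  n <- vital$n
  U <- matrix(0, n, n)
  diag(U) <- vital$s_max * c(1 - vital$g, 1)
  if (n > 1) U[cbind(2:n, 1:(n - 1))] <- vital$s_max[-n] * vital$g
  stage_matrix(U)
}

#' Fundamental matrix of a stage matrix
#'
#' F = (I - U)^-1; entry (i, j) is the expected number of years an
#' individual now in stage j will spend in stage i before dying. Defined
#' whenever some mortality keeps the spectral radius of U below 1.
#'
#' @param M A [stage_matrix()].
#' @return An n x n numeric matrix.
#' @examples
#' fundamental_matrix(stage_matrix(rbind(c(0.60268, 0), c(0.00732, 0.98))))
#' @export
fundamental_matrix <- function(M) {
  stopifnot(inherits(M, "stage_matrix"))
  n <- nrow(M)
  IU <- diag(n) - unclass_matrix(M)
  F_ <- tryCatch(solve(IU), error = function(e) {
    abort("I - U is singular: the life cycle has no mortality (immortal cohort).",
          class = "agflow_matrix_error")
  })
  if (any(!is.finite(F_)) || any(F_ < -1e-9)) {
    abort("Fundamental matrix is not defined: spectral radius of U must be below 1.",
          class = "agflow_matrix_error")
  }
  pmax(F_, 0)
}

#' Typical life history from the fundamental matrix
#'
#' The expected age at the transition out of stage i, for an individual
#' planted in stage 1, is the expected total time spent in stages 1..i:
#' the partial column sums of the fundamental matrix. These are rounded up
#' to whole years, and ties are bumped so ages stay strictly increasing.
#' Species whose typical history does not reach the last stage by harvest
#' are rejected, mirroring the species filter used when the model is
#' parameterised from empirical matrices.
#'
#' @param F_ Fundamental matrix from [fundamental_matrix()].
#' @param H Rotation length in years.
#' @return A [life_history()] object.
#' @export
typical_life_history <- function(F_, H) {
  n <- nrow(F_)
  check_horizon(H)
  a <- ceiling(cumsum(F_[, 1])[seq_len(n - 1)] - 1e-9)
  if (n > 2) {
    for (i in 2:(n - 1)) if (a[i] <= a[i - 1]) a[i] <- a[i - 1] + 1
  }
  if (a[n - 1] > H) {
    abort(sprintf(
      "Typical life history reaches the last stage at age %d, after harvest (H = %d); species excluded.",
      a[n - 1], H), class = "agflow_species_excluded")
  }
  life_history(a, H)
}

#' A fixed life history: ages of transition between stages
#'
#' `a[i]` is the age (in years since planting) at which the individual
#' moves from stage i to stage i+1; with n stages there are n-1 transition
#' ages, strictly increasing, with `a[i] >= i` (one stage per year at most)
#' and `a[n-1] <= H` (the last stage is reached by harvest).
#'
#' @param a Integer vector of transition ages.
#' @param H Rotation length in years.
#' @return A `life_history` object.
#' @examples
#' life_history(a = 3, H = 60)
#' @export
life_history <- function(a, H) {
  check_horizon(H)
  a <- as.integer(a)
  k <- length(a)
  if (k > 0) {
    if (any(diff(a) <= 0) || any(a < seq_len(k))) {
      abort("Transition ages must be strictly increasing with a[i] >= i.",
            class = "agflow_history_error")
    }
    if (a[k] > H) {
      abort("The last transition must occur no later than harvest (a[n-1] <= H).",
            class = "agflow_history_error")
    }
  }
  structure(list(a = a, n = k + 1L, H = as.integer(H)), class = "life_history")
}

#' @export
print.life_history <- function(x, ...) {
  cat(sprintf("<life_history> %d stages, H = %d, transitions at: %s\n",
              x$n, x$H,
              if (length(x$a)) paste(x$a, collapse = ", ") else "-"))
  invisible(x)
}

#' Probability of a life history under the growth process
#'
#' For conditional growth probabilities g_i, the probability that the
#' transitions happen exactly at ages a_1 < ... < a_(n-1) is
#' prod_i (1 - g_i)^(a_i - a_(i-1) - 1) g_i with a_0 = 0. Survival does
#' not enter: this is the timing distribution of the growth process alone.
#'
#' @param history A [life_history()].
#' @param g Conditional growth probabilities, length n-1.
#' @return A probability.
#' @examples
#' life_history_probability(life_history(5, 60), g = 0.012)
#' @export
life_history_probability <- function(history, g) {
  stopifnot(inherits(history, "life_history"))
  a <- history$a
  if (length(g) != length(a)) {
    abort("`g` must have one entry per transition.", class = "agflow_history_error")
  }
  d <- diff(c(0L, a))
  prod((1 - g)^(d - 1) * g)
}

#' Enumerate all life histories feasible by harvest
#'
#' Yields every strictly increasing vector of transition ages with the
#' last transition at or before harvest, together with its probability
#' under the growth process. There are choose(H, n-1) of them; the
#' probabilities sum to the probability that the growth process completes
#' all n-1 transitions within H years (< 1 in general).
#'
#' @param g Conditional growth probabilities, length n-1.
#' @param n Number of stages (>= 2).
#' @param H Rotation length in years.
#' @param cap Refuse enumeration when choose(H, n-1) exceeds this many
#'   histories; use the cohort projection engine instead for such cases.
#' @return A tibble with a list-column `a` (integer transition ages) and a
#'   column `probability`.
#' @examples
#' enumerate_life_histories(g = 0.012, n = 2, H = 5)
#' @export
enumerate_life_histories <- function(g, n, H, cap = 2e5) {
  check_horizon(H)
  if (n < 2) abort("Enumeration needs at least two stages.", class = "agflow_history_error")
  if (length(g) != n - 1L) {
    abort("`g` must have one entry per transition.", class = "agflow_history_error")
  }
  A <- enumerate_history_matrix(n, H, cap)
  p <- history_probabilities(A, g)
  tibble(
    a = lapply(seq_len(ncol(A)), function(j) A[, j]),
    probability = p
  )
}

# histories as an (n-1) x count integer matrix, one column per history
enumerate_history_matrix <- function(n, H, cap = 2e5) {
  count <- choose(H, n - 1)
  if (count > cap) {
    abort(sprintf(
      "choose(%d, %d) = %g life histories exceeds the cap (%g); use project_cohort() instead.",
      H, n - 1, count, cap), class = "agflow_cap_error")
  }
  if (n == 2) {
    matrix(seq_len(H), nrow = 1)
  } else {
    combn(H, n - 1)
  }
}

history_probabilities <- function(A, g) {
  d <- A - rbind(0L, A[-nrow(A), , drop = FALSE])
  pw <- (1 - g)^(d - 1) * g  # g recycles down columns; 0^0 = 1 covers g = 1
  p <- rep(1, ncol(A))
  for (i in seq_len(nrow(A))) p <- p * pw[i, ]
  p
}
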