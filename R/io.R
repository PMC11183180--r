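#' Read and write stage matrices as plain CSV
#'
#' One matrix per file: n header-less rows of n comma-separated transition
#' probabilities, stages ordered youngest to oldest, entry (i, j) the
#' probability of moving from stage j to stage i in one year. Matrices
#' extracted from demographic databases may carry fecundity or
#' retrogression entries the cohort model excludes; `policy = "drop"`
#' zeroes and reports them (see [as_stage_matrix()]).
#'
#' @param path File path.
#' @param policy Conformance policy, `"strict"` or `"drop"`.
#' @return `read_stage_matrix()` returns a [stage_matrix()];
#'   `write_stage_matrix()` returns `path` invisibly.
#' @export
read_stage_matrix <- function(path, policy = c("strict", "drop")) {
  raw <- as.matrix(readr::read_csv(path, col_names = FALSE,
                                   col_types = readr::cols(.default = "d"),
                                   progress = FALSE))
  dimnames(raw) <- NULL
  as_stage_matrix(raw, policy = match.arg(policy))
}

#' @rdname read_stage_matrix
#' @param M A [stage_matrix()] (or plain square matrix) to write.
#' @export
write_stage_matrix <- function(M, path) {
  M <- as.matrix(M)
  attr(M, "conformance") <- NULL
  utils::write.table(unclass(M), path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Export a cohort trajectory as CSV
#'
#' Long format: one row per year and stage with the expected abundance.
#'
#' @param trajectory A `cohort_trajectory` from [project_cohort()].
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(trajectory, path) {
  readr::write_csv(tidy(trajectory), path, progress = FALSE)
  invisible(path)
}
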