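#' Fisher z-transform of a correlation
#'
#' `z = atanh(r)`, variance-stabilising for Pearson correlations; applied
#' elementwise. Requires `|r| < 1`.
#'
#' @param r Correlation value(s) in (-1, 1).
#' @return Numeric vector of z-scores.
#' @export
fisher_z <- function(r) {
  if (any(!is.finite(r)) || any(abs(r) >= 1)) {
    abort("fisher_z requires finite |r| < 1")
  }
  atanh(r)
}

#' Static functional network connectivity of one subject
#'
#' Full-length Pearson correlation matrix over all timepoints of the
#' conditioned time course, plus the Fisher-z transform of its unique pairs.
#'
#' @param tc A conditioned [subject_timecourse()] with T >= 3.
#' @return List of class `static_fnc`: `subject_id`, `matrix` (C x C),
#'   `zvector` (named P-vector).
#' @export
static_fnc_matrix <- function(tc) {
  stopifnot(inherits(tc, "subject_tc"))
  if (nrow(tc$values) < 3) abort("static FNC requires at least 3 timepoints")
  v <- apply(tc$values, 2, var)
  if (any(v == 0)) {
    abort(paste0("zero-variance component(s): ",
                 paste(tc$component_names[v == 0], collapse = ", ")))
  }
  m <- cor(tc$values)
  rvec <- vectorize_fnc(m)
  rvec <- pmin(pmax(rvec, -1 + 1e-12), 1 - 1e-12)
  structure(
    list(subject_id = tc$subject_id, matrix = m, zvector = fisher_z(rvec)),
    class = "static_fnc"
  )
}

#' Static FNC z-values for a whole cohort
#'
#' @param cohort A `dfnc_cohort` or list of `subject_tc`.
#' @param condition Condition each time course first. Default TRUE.
#' @return Tibble: `subject_id` plus one Fisher-z column per component pair.
#' @export
static_fnc_table <- function(cohort, condition = TRUE) {
  subjects <- if (inherits(cohort, "dfnc_cohort")) cohort$subjects else cohort
  rows <- lapply(subjects, function(tc) {
    if (condition) tc <- condition_timecourse(tc)
    sf <- static_fnc_matrix(tc)
    tibble::as_tibble(c(list(subject_id = sf$subject_id), as.list(sf$zvector)))
  })
  dplyr::bind_rows(rows)
}
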