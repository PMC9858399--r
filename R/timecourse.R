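#' Construct a subject time course
#'
#' A subject time course holds the T x C matrix of network component signals
#' for one subject (rows = timepoints, columns = components) together with
#' the repetition time and identifying labels. It is the unit of input for
#' conditioning, static FNC and sliding-window dynamic FNC.
#'
#' @param values Numeric matrix, T rows (timepoints) by C columns
#'   (components). T >= 2 and all values finite.
#' @param tr_seconds Repetition time in seconds (sampling interval of the
#'   rows). Default 2.4.
#' @param subject_id Character scalar identifying the subject.
#' @param component_names Optional character vector of C component labels;
#'   defaults to the matrix column names, or `comp1..compC`.
#'
#' @return An object of class `subject_tc`.
#' @export
#' @examples
#' tc <- subject_timecourse(matrix(rnorm(40), 20, 2), subject_id = "s01")
#' dim(tc$values)
subject_timecourse <- function(values, tr_seconds = 2.4, subject_id = "subject",
                               component_names = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (nrow(values) < 2) {
    abort("a subject time course needs at least 2 timepoints")
  }
  if (!all(is.finite(values))) {
    abort("time course contains non-finite values")
  }
  if (!is.numeric(tr_seconds) || length(tr_seconds) != 1 || tr_seconds <= 0) {
    abort("`tr_seconds` must be a positive scalar")
  }
  if (is.null(component_names)) {
    component_names <- colnames(values)
    if (is.null(component_names)) {
      component_names <- paste0("comp", seq_len(ncol(values)))
    }
  }
  if (length(component_names) != ncol(values)) {
    abort("`component_names` length must equal the number of columns")
  }
  if (anyDuplicated(component_names)) {
    abort("component names must be unique")
  }
  colnames(values) <- component_names
  structure(
    list(
      values = values,
      tr_seconds = as.numeric(tr_seconds),
      subject_id = as.character(subject_id),
      component_names = component_names
    ),
    class = "subject_tc"
  )
}

#' @export
print.subject_tc <- function(x, ...) {
  cat(sprintf(
    "<subject_tc> %s: %d timepoints x %d components (TR = %g s)\n",
    x$subject_id, nrow(x$values), ncol(x$values), x$tr_seconds
  ))
  invisible(x)
}

#' @export
dim.subject_tc <- function(x) dim(x$values)

# replace the value matrix, keeping metadata
tc_update <- function(tc, values) {
  tc$values <- values
  colnames(tc$values) <- tc$component_names
  tc
}

#' Names of component pairs in vectorisation order
#'
#' @param component_names Character vector of C component labels.
#' @return Character vector of P = C(C-1)/2 names `"a~b"`, upper triangle in
#'   row-major order.
#' @export
pair_names <- function(component_names) {
  C <- length(component_names)
  out <- character(0)
  for (i in seq_len(C - 1)) {
    for (j in seq(i + 1, C)) {
      out <- c(out, paste0(component_names[i], "~", component_names[j]))
    }
  }
  out
}
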