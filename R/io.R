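#' Read a subject time-course TSV
#'
#' Strict parser for the package's interchange format: a tab-separated file
#' with a header row of component names and a numeric body, rows =
#' timepoints. Ragged rows, non-numeric cells and duplicate component names
#' are errors that name the offending line.
#'
#' @param path File path.
#' @param tr_seconds Repetition time to record. Default 2.4.
#' @param subject_id Identifier; defaults to the file name without
#'   extension.
#' @return A [subject_timecourse()].
#' @export
read_timecourse_matrix <- function(path, tr_seconds = 2.4, subject_id = NULL) {
  lines <- readLines(path)
  if (length(lines) < 2) abort("time-course file needs a header and at least one row")
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  if (anyDuplicated(header)) {
    abort(paste0("duplicate component names in header: ",
                 paste(unique(header[duplicated(header)]), collapse = ", ")))
  }
  C <- length(header)
  body <- lines[-1]
  body <- body[nzchar(body)]
  cells <- strsplit(body, "\t", fixed = TRUE)
  widths <- lengths(cells)
  if (any(widths != C)) {
    bad <- which(widths != C)[1]
    abort(sprintf("ragged row at line %d: %d fields, expected %d",
                  bad + 1, widths[bad], C))
  }
  suppressWarnings(vals <- vapply(cells, as.numeric, numeric(C)))
  if (anyNA(vals)) {
    bad <- which(apply(is.na(vals), 2, any))[1]
    abort(sprintf("non-numeric cell at line %d", bad + 1))
  }
  m <- t(vals)
  colnames(m) <- header
  if (is.null(subject_id)) {
    subject_id <- tools::file_path_sans_ext(basename(path))
  }
  subject_timecourse(m, tr_seconds = tr_seconds, subject_id = subject_id,
                     component_names = header)
}

#' Write a subject time course as TSV
#'
#' @param tc A [subject_timecourse()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_timecourse_matrix <- function(tc, path) {
  stopifnot(inherits(tc, "subject_tc"))
  readr::write_tsv(tibble::as_tibble(tc$values), path)
  invisible(path)
}

#' Read a behavioural table CSV
#'
#' Expects a `subject_id` column plus the six mandatory behavioural
#' measures; any further columns are kept and recorded as covariates.
#'
#' @param path File path.
#' @param required Mandatory measure columns; default the six of
#'   [behavior_measures()].
#' @return Tibble with attribute `covariates` listing the extra columns.
#' @export
read_behavior_table <- function(path, required = behavior_measures()$measure) {
  tbl <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!"subject_id" %in% names(tbl)) abort("behaviour table needs a `subject_id` column")
  tbl$subject_id <- as.character(tbl$subject_id)
  if (anyDuplicated(tbl$subject_id)) {
    abort(paste0("duplicate subject ids: ",
                 paste(unique(tbl$subject_id[duplicated(tbl$subject_id)]),
                       collapse = ", ")))
  }
  missing <- setdiff(required, names(tbl))
  if (length(missing)) {
    abort(paste0("missing mandatory measure(s): ", paste(missing, collapse = ", ")))
  }
  if (!all(vapply(tbl[required], is.numeric, logical(1)))) {
    abort("behavioural measures must be numeric")
  }
  attr(tbl, "covariates") <- setdiff(names(tbl), c("subject_id", required))
  tbl
}

#' Write a synthetic cohort to disk
#'
#' Emits one time-course TSV per subject, a manifest CSV (subject id, file,
#' seed), the behaviour CSV and a ground-truth state-sequence TSV (subjects
#' as columns).
#'
#' @param cohort A `dfnc_cohort`.
#' @param dir Output directory (created if absent).
#' @return Tibble manifest, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "dfnc_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ids <- names(cohort$subjects)
  files <- file.path(dir, paste0(ids, ".tsv"))
  for (i in seq_along(ids)) {
    write_timecourse_matrix(cohort$subjects[[i]], files[i])
  }
  manifest <- tibble::tibble(subject_id = ids, file = basename(files),
                             seed = cohort$seed)
  readr::write_csv(manifest, file.path(dir, "manifest.csv"))
  readr::write_csv(cohort$behavior, file.path(dir, "behavior.csv"))
  states <- tibble::as_tibble(setNames(cohort$true_states, ids))
  readr::write_tsv(states, file.path(dir, "true_states.tsv"))
  invisible(manifest)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir Directory containing `manifest.csv`, per-subject TSVs and
#'   `behavior.csv`.
#' @param tr_seconds Repetition time to record on the time courses.
#' @return List with `subjects` (named list of `subject_tc`) and `behavior`.
#' @export
read_cohort <- function(dir, tr_seconds = 2.4) {
  manifest <- readr::read_csv(file.path(dir, "manifest.csv"),
                              show_col_types = FALSE, progress = FALSE)
  subjects <- lapply(seq_len(nrow(manifest)), function(i) {
    read_timecourse_matrix(file.path(dir, manifest$file[i]),
                           tr_seconds = tr_seconds,
                           subject_id = manifest$subject_id[i])
  })
  names(subjects) <- manifest$subject_id
  behavior <- read_behavior_table(file.path(dir, "behavior.csv"))
  list(subjects = subjects, behavior = behavior)
}
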