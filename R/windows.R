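#' Build a tapered sliding window
#'
#' The taper is the discrete convolution of a rectangle of ones (length
#' `width`) with a Gaussian kernel sampled at integer offsets
#' `-half_support..half_support`, peak-normalised to 1. The defaults
#' (width 15 TRs, sigma 3 TRs, truncation at +/- 8 TRs) give a total support
#' of L = 31 TRs, which at TR 2.4 s corresponds to a 36-second rectangular
#' core with soft Gaussian shoulders.
#'
#' @param width Rectangle length in TRs (>= 1). Default 15.
#' @param sigma Gaussian sigma in TRs (> 0). Default 3.
#' @param half_support Gaussian truncation in TRs (>= 1). Default 8.
#' @return List of class `taper_window`: `weights` (length
#'   `width + 2 * half_support`), `width`, `sigma`, `half_support`.
#' @export
#' @examples
#' tw <- build_taper()
#' length(tw$weights)  # 31
build_taper <- function(width = 15, sigma = 3, half_support = 8) {
  if (width < 1) abort("`width` must be >= 1")
  if (sigma <= 0) abort("`sigma` must be > 0")
  if (half_support < 1) abort("`half_support` must be >= 1")
  rect <- rep(1, width)
  offs <- seq(-half_support, half_support)
  gauss <- exp(-offs^2 / (2 * sigma^2))
  w <- convolve(rect, rev(gauss), type = "open")
  w <- w / max(w)
  structure(
    list(weights = as.numeric(w), width = width, sigma = sigma,
         half_support = half_support),
    class = "taper_window"
  )
}

#' Window start indices for a sliding window
#'
#' @param T_len Number of timepoints.
#' @param taper A [build_taper()] result (or its length L as an integer).
#' @param step Slide step in TRs (>= 1). Default 1.
#' @return Integer vector of 0-based inclusive start indices
#'   `0, step, ... <= T_len - L`. With T = 190, L = 31, step = 1 this yields
#'   160 windows.
#' @export
extract_windows <- function(T_len, taper, step = 1) {
  L <- if (inherits(taper, "taper_window")) length(taper$weights) else as.integer(taper)
  if (step < 1) abort("`step` must be >= 1")
  if (T_len < L) {
    abort(sprintf("time course too short: %d timepoints < window length %d", T_len, L))
  }
  seq(0L, T_len - L, by = step)
}

#' Vectorise a connectivity matrix to its unique pairs
#'
#' Upper triangle excluding the diagonal, row-major, so C components give
#' P = C(C-1)/2 values. [unvectorize_fnc()] inverts the operation exactly.
#'
#' @param m Symmetric matrix with unit diagonal.
#' @param tol Maximum tolerated asymmetry. Default 1e-8.
#' @return Numeric P-vector, named `"a~b"` when `m` has dimnames.
#' @export
vectorize_fnc <- function(m, tol = 1e-8) {
  m <- as.matrix(m)
  if (nrow(m) != ncol(m)) abort("matrix must be square")
  if (max(abs(m - t(m))) > tol) abort("matrix is not symmetric")
  C <- nrow(m)
  v <- t(m)[lower.tri(m)]          # upper triangle, row-major
  if (!is.null(rownames(m))) names(v) <- pair_names(rownames(m))
  v
}

#' @rdname vectorize_fnc
#' @param v A P-vector produced by [vectorize_fnc()].
#' @param component_names Optional labels for the reconstructed matrix.
#' @export
unvectorize_fnc <- function(v, component_names = NULL) {
  P <- length(v)
  C <- (1 + sqrt(1 + 8 * P)) / 2
  if (C != round(C)) abort("vector length is not C(C-1)/2 for integer C")
  C <- as.integer(C)
  m <- diag(C)
  m[lower.tri(m)] <- v
  m <- t(m)
  m[lower.tri(m)] <- v
  m <- t(m)                        # fill both triangles in row-major pair order
  if (!is.null(component_names)) dimnames(m) <- list(component_names, component_names)
  m
}

# taper-weighted correlation matrix of an L x C slice; zero-variance pairs -> 0
weighted_corr <- function(x, w) {
  w <- w / sum(w)
  mu <- drop(crossprod(w, x))
  xc <- sweep(x, 2, mu)
  cv <- crossprod(xc, w * xc)
  v <- diag(cv)
  zero <- v <= .Machine$double.eps * max(v, 1)
  if (any(zero)) {
    warn("zero weighted variance in a window; affected pairs set to 0")
    v[zero] <- 1
    cv[zero, ] <- 0
    cv[, zero] <- 0
  }
  r <- cv / sqrt(outer(v, v))
  diag(r) <- 1
  r[r > 1] <- 1
  r[r < -1] <- -1
  (r + t(r)) / 2
}

new_windowed_fnc <- function(subject_id, starts, vectors, component_names,
                             taper, estimator, lambda = NA_real_) {
  colnames(vectors) <- pair_names(component_names)
  structure(
    list(subject_id = subject_id, starts = starts, vectors = vectors,
         component_names = component_names, taper = taper,
         estimator = estimator, lambda = lambda),
    class = "windowed_fnc"
  )
}

#' Tapered sliding-window functional network connectivity
#'
#' For each window, the taper-weighted Pearson correlation matrix of the
#' L-row slice is computed (taper weights act as observation weights in the
#' means and covariances), then vectorised to its P unique pairs.
#'
#' @param tc A conditioned [subject_timecourse()].
#' @param taper A [build_taper()] result.
#' @param step Slide step in TRs. Default 1.
#' @return A `windowed_fnc` object: `starts` (0-based), `vectors` (W x P),
#'   `estimator = "sample"`.
#' @export
#' @examples
#' coh <- generate_cohort(cohort_config(n_subjects = 1, n_timepoints = 60), seed = 1)
#' wf <- windowed_fnc(coh$subjects[[1]], build_taper())
#' dim(wf$vectors)
windowed_fnc <- function(tc, taper = build_taper(), step = 1) {
  stopifnot(inherits(tc, "subject_tc"), inherits(taper, "taper_window"))
  L <- length(taper$weights)
  starts <- extract_windows(nrow(tc$values), taper, step)
  P <- ncol(tc$values) * (ncol(tc$values) - 1) / 2
  vecs <- matrix(NA_real_, length(starts), P)
  for (i in seq_along(starts)) {
    slice <- tc$values[(starts[i] + 1):(starts[i] + L), , drop = FALSE]
    vecs[i, ] <- vectorize_fnc(weighted_corr(slice, taper$weights))
  }
  new_windowed_fnc(tc$subject_id, starts, vecs, tc$component_names,
                   taper, estimator = "sample")
}

#' Reconstruct the connectivity matrix of one window
#'
#' @param series A `windowed_fnc` object.
#' @param i Window index (1-based).
#' @return The C x C correlation matrix of window `i`.
#' @export
window_matrix <- function(series, i) {
  stopifnot(inherits(series, "windowed_fnc"))
  unvectorize_fnc(series$vectors[i, ], series$component_names)
}

#' Windowed FNC for every subject of a cohort
#'
#' @param cohort A `dfnc_cohort` (or a plain list of `subject_tc`).
#' @param taper,step See [windowed_fnc()].
#' @param condition Logical; condition each time course first with
#'   [condition_timecourse()] defaults. Default TRUE.
#' @return Named list of `windowed_fnc`, one per subject.
#' @export
cohort_windowed_fnc <- function(cohort, taper = build_taper(), step = 1,
                                condition = TRUE) {
  subjects <- if (inherits(cohort, "dfnc_cohort")) cohort$subjects else cohort
  lapply(subjects, function(tc) {
    if (condition) tc <- condition_timecourse(tc)
    windowed_fnc(tc, taper = taper, step = step)
  })
}

#' Pool windowed FNC vectors across subjects
#'
#' @param series_list Named list of `windowed_fnc`.
#' @return List with `vectors` (stacked W_total x P matrix), `subject`
#'   (factor of subject ids per row), `window` (within-subject window index).
#' @export
pool_windows <- function(series_list) {
  vectors <- do.call(rbind, lapply(series_list, function(s) s$vectors))
  subject <- rep(names(series_list),
                 vapply(series_list, function(s) nrow(s$vectors), integer(1)))
  window <- unlist(lapply(series_list, function(s) seq_len(nrow(s$vectors))),
                   use.names = FALSE)
  list(vectors = vectors, subject = subject, window = window)
}
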