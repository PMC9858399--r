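#' Remove per-column linear trends
#'
#' Least-squares removal of intercept and linear slope from every component,
#' so each column of the result has zero mean and zero linear trend.
#'
#' @param tc A [subject_timecourse()].
#' @return The detrended `subject_tc`.
#' @export
detrend_linear <- function(tc) {
  stopifnot(inherits(tc, "subject_tc"))
  T_len <- nrow(tc$values)
  t0 <- seq_len(T_len) - (T_len + 1) / 2        # centered time, orthogonal to intercept
  x <- sweep(tc$values, 2, colMeans(tc$values))
  slope <- crossprod(t0, x) / sum(t0^2)
  tc_update(tc, x - outer(t0, drop(slope)))
}

#' Replace spikes by the running median
#'
#' A point is a spike when its deviation from the running median exceeds
#' `threshold` robust standard deviations, where the robust sigma is
#' 1.4826 times the median absolute deviation of the median residuals.
#' Spikes are replaced by the running-median value; everything else is
#' untouched. Columns with zero MAD (e.g. constant signals) are returned
#' unchanged.
#'
#' @param tc A [subject_timecourse()].
#' @param threshold Spike threshold in robust sigmas (> 0). Default 3.
#' @param window Odd running-median window length (>= 3). Default 7.
#' @return The despiked `subject_tc`.
#' @export
despike_mad <- function(tc, threshold = 3, window = 7) {
  stopifnot(inherits(tc, "subject_tc"))
  if (window < 3 || window %% 2 == 0) abort("`window` must be odd and >= 3")
  if (threshold <= 0) abort("`threshold` must be > 0")
  x <- tc$values
  for (j in seq_len(ncol(x))) {
    med <- runmed(x[, j], k = min(window, odd_floor(nrow(x))), endrule = "median")
    res <- x[, j] - med
    sigma <- mad(res)  # 1.4826 * median(|res - median(res)|)
    if (sigma == 0) next
    bad <- abs(res) > threshold * sigma
    x[bad, j] <- med[bad]
  }
  tc_update(tc, x)
}

odd_floor <- function(n) if (n %% 2 == 1) n else n - 1

#' Zero-phase Butterworth low-pass filter
#'
#' Designs a digital Butterworth low-pass filter at `cutoff_hz` (given the
#' time course's TR) and applies it forward and backward
#' ([signal::filtfilt()]), so the output is phase-neutral and the effective
#' magnitude response is the squared one-pass response.
#'
#' @param tc A [subject_timecourse()].
#' @param cutoff_hz Cutoff frequency in Hz; must be below the Nyquist
#'   frequency `1 / (2 * tr_seconds)`. Default 0.15.
#' @param order Filter order (>= 1). Default 5.
#' @return The filtered `subject_tc`.
#' @export
butterworth_lowpass <- function(tc, cutoff_hz = 0.15, order = 5) {
  stopifnot(inherits(tc, "subject_tc"))
  if (order < 1) abort("`order` must be >= 1")
  nyquist <- 1 / (2 * tc$tr_seconds)
  if (cutoff_hz >= nyquist) {
    abort(sprintf("`cutoff_hz` (%g Hz) must be below the Nyquist frequency %g Hz",
                  cutoff_hz, nyquist))
  }
  bf <- signal::butter(order, cutoff_hz / nyquist, type = "low")
  T_len <- nrow(tc$values)
  # odd-reflection padding suppresses the zero-initial-condition transient
  # of the forward-backward pass at both ends
  nfact <- min(T_len - 1, 9 * order)
  x <- apply(tc$values, 2, function(col) {
    mu <- mean(col)
    xc <- col - mu
    pre <- 2 * xc[1] - xc[(nfact + 1):2]
    post <- 2 * xc[T_len] - xc[(T_len - 1):(T_len - nfact)]
    y <- signal::filtfilt(bf, c(pre, xc, post))
    y[(nfact + 1):(nfact + T_len)] + mu
  })
  tc_update(tc, x)
}

#' Regress nuisance signals out of every component
#'
#' Each column is replaced by its least-squares residual against an
#' intercept plus the supplied regressors. With no regressors this reduces
#' to mean-centering.
#'
#' @param tc A [subject_timecourse()].
#' @param nuisance Numeric matrix or data frame with T rows (one column per
#'   regressor), or NULL for intercept only.
#' @return The residualised `subject_tc`.
#' @export
regress_columns <- function(tc, nuisance = NULL) {
  stopifnot(inherits(tc, "subject_tc"))
  T_len <- nrow(tc$values)
  if (is.null(nuisance) || NCOL(nuisance) == 0 ||
      (is.matrix(nuisance) && ncol(nuisance) == 0)) {
    design <- matrix(1, T_len, 1)
  } else {
    nuisance <- as.matrix(nuisance)
    if (nrow(nuisance) != T_len) {
      abort("nuisance regressors must have one row per timepoint")
    }
    design <- cbind(1, nuisance)
  }
  q <- qr(design)
  if (q$rank < ncol(design)) abort("nuisance design matrix is rank deficient")
  tc_update(tc, tc$values - design %*% qr.coef(q, tc$values))
}

#' Condition a time course for FNC estimation
#'
#' Applies, in fixed order: linear detrend, running-median despiking,
#' zero-phase Butterworth low-pass, then (optionally) nuisance regression.
#' Any stage can be disabled.
#'
#' @param tc A [subject_timecourse()].
#' @param detrend,despike,filter Logical switches for the three stages.
#' @param cutoff_hz,order Filter settings, see [butterworth_lowpass()].
#' @param despike_threshold,despike_window Despiking settings, see
#'   [despike_mad()].
#' @param nuisance Optional T x R regressor matrix; when supplied, nuisance
#'   regression runs as the final stage.
#' @return The conditioned `subject_tc`.
#' @export
condition_timecourse <- function(tc, detrend = TRUE, despike = TRUE,
                                 filter = TRUE, cutoff_hz = 0.15, order = 5,
                                 despike_threshold = 3, despike_window = 7,
                                 nuisance = NULL) {
  stopifnot(inherits(tc, "subject_tc"))
  if (detrend) tc <- detrend_linear(tc)
  if (despike) tc <- despike_mad(tc, threshold = despike_threshold,
                                 window = despike_window)
  if (filter) tc <- butterworth_lowpass(tc, cutoff_hz = cutoff_hz, order = order)
  if (!is.null(nuisance)) tc <- regress_columns(tc, nuisance)
  if (!all(is.finite(tc$values))) {
    abort("conditioning produced non-finite values")
  }
  tc
}
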