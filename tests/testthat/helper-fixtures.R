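# small shared fixtures, built in code

tiny_cohort <- function(n = 3, T_len = 60, seed = 11) {
  generate_cohort(cohort_config(n_subjects = n, n_timepoints = T_len),
                  seed = seed)
}

# a short taper so small fixtures have several windows
short_taper <- function() build_taper(width = 5, sigma = 2, half_support = 3)

random_tc <- function(T_len = 60, C = 4, seed = 1, tr = 2.4) {
  set.seed(seed)
  subject_timecourse(matrix(rnorm(T_len * C), T_len, C), tr_seconds = tr,
                     subject_id = "rnd")
}

# fit amplitude of a known-frequency sinusoid by least squares on the
# central portion of a signal (avoids filtfilt edge transients)
fitted_amplitude <- function(x, freq_hz, tr, trim = 50) {
  T_len <- length(x)
  idx <- (trim + 1):(T_len - trim)
  tt <- (idx - 1) * tr
  fit <- lm(x[idx] ~ sin(2 * pi * freq_hz * tt) + cos(2 * pi * freq_hz * tt))
  sqrt(sum(coef(fit)[2:3]^2))
}
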