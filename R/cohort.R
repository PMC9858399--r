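#' Behavioural measures and their cohort-level location/scale defaults
#'
#' Six self-report measures: two Youth Self Report (YSR) attention scales
#' (T-scores) and four UPPS impulsivity facets (1-4 Likert means). Defaults
#' are the means and standard deviations of the emulated adolescent cohort.
#'
#' @return Tibble with columns `measure`, `mean`, `sd`.
#' @export
behavior_measures <- function() {
  tibble::tribble(
    ~measure,                    ~mean,  ~sd,
    "ysr_attention_problems",    57.19,  6.85,
    "ysr_adhd",                  57.00,  6.67,
    "upps_urgency",               2.46,  0.66,
    "upps_lack_premeditation",    2.21,  0.63,
    "upps_lack_perseverance",     2.04,  0.64,
    "upps_sensation_seeking",     2.82,  0.64
  )
}

#' Default planted feature-behaviour effects
#'
#' The generator plants correlations between ground-truth dynamic features
#' and behavioural scores so that downstream correlation screens have known
#' signal to recover: diminished state-1 SN-lECN coupling with both attention
#' scales, longer state-3 dwell with ADHD manifestations and lack of
#' perseverance, and more state switching / a longer connectivity path with
#' ADHD manifestations.
#'
#' @return Tibble with columns `feature`, `behavior`, `rho`.
#' @export
default_planted_effects <- function() {
  tibble::tribble(
    ~feature,            ~behavior,                  ~rho,
    "state1_sn_lecn_z",  "ysr_adhd",                -0.38,
    "state1_sn_lecn_z",  "ysr_attention_problems",  -0.39,
    "mdt_state3",        "ysr_adhd",                 0.30,
    "mdt_state3",        "upps_lack_perseverance",   0.33,
    "nt",                "ysr_adhd",                 0.24,
    "path_length",       "ysr_adhd",                 0.35
  )
}

#' Simulate a behavioural table with planted feature correlations
#'
#' Each measure with planted effects is built as
#' `mean + sd * (sum_i rho_i * z(feature_i) + sqrt(1 - sum_i rho_i^2) * eps)`
#' with `eps` standard normal; measures without effects are pure noise. With
#' a single effect the population correlation between feature and measure is
#' exactly `rho` (up to cross-feature correlation when several effects share
#' a measure).
#'
#' @param features Tibble with a `subject_id` column plus one numeric column
#'   per feature.
#' @param effects Tibble of `(feature, behavior, rho)`;
#'   see [default_planted_effects()]. May be empty (all-null behaviour).
#' @param means_sds Tibble `(measure, mean, sd)`; default [behavior_measures()].
#' @param seed Optional integer seed.
#'
#' @return Tibble: `subject_id` plus one column per measure.
#' @export
simulate_behavior_table <- function(features,
                                    effects = default_planted_effects(),
                                    means_sds = behavior_measures(),
                                    seed = NULL) {
  stopifnot(is.data.frame(features), "subject_id" %in% names(features))
  if (!is.null(seed)) set.seed(seed)
  if (nrow(effects) > 0) {
    if (any(abs(effects$rho) >= 1)) abort("planted |rho| must be < 1")
    missing_f <- setdiff(effects$feature, names(features))
    if (length(missing_f)) {
      abort(paste0("unknown planted feature(s): ", paste(missing_f, collapse = ", ")))
    }
    missing_b <- setdiff(effects$behavior, means_sds$measure)
    if (length(missing_b)) {
      abort(paste0("unknown behaviour measure(s): ", paste(missing_b, collapse = ", ")))
    }
    if (anyDuplicated(effects[, c("feature", "behavior")])) {
      abort("at most one planted effect per (feature, behavior) pair")
    }
  }
  n <- nrow(features)
  zscore <- function(x) {
    # subjects with an undefined feature (NA) contribute no signal
    s <- sd(x, na.rm = TRUE)
    if (!is.finite(s) || s == 0) return(rep(0, n))
    z <- (x - mean(x, na.rm = TRUE)) / s
    z[!is.finite(z)] <- 0
    z
  }
  out <- tibble::tibble(subject_id = features$subject_id)
  for (i in seq_len(nrow(means_sds))) {
    m <- means_sds$measure[i]
    eff <- effects[effects$behavior == m, , drop = FALSE]
    signal <- rep(0, n)
    rho2 <- 0
    if (nrow(eff) > 0) {
      for (j in seq_len(nrow(eff))) {
        signal <- signal + eff$rho[j] * zscore(features[[eff$feature[j]]])
        rho2 <- rho2 + eff$rho[j]^2
      }
      if (rho2 >= 1) abort(sprintf("planted effects on '%s' imply variance > 1", m))
    }
    eps <- rnorm(n)
    out[[m]] <- means_sds$mean[i] +
      means_sds$sd[i] * (signal + sqrt(1 - rho2) * eps)
  }
  out
}

#' Generator settings for a synthetic dynamic-connectivity cohort
#'
#' Defaults emulate the study conditions the package targets: 80 subjects,
#' 190 retained timepoints at TR 2.4 s, 6 triple-network components, 4 latent
#' connectivity states with geometric dwell (self-transition 0.9) and
#' separation 0.6.
#'
#' @param n_subjects,n_timepoints,n_components,n_states Cohort dimensions.
#' @param tr_seconds Repetition time in seconds.
#' @param separation Off-diagonal strength of the state templates.
#' @param self_transition Markov self-transition probability.
#' @param effects Planted feature-behaviour effects tibble.
#' @return A named list of class `dfnc_cohort_config`.
#' @export
cohort_config <- function(n_subjects = 80, n_timepoints = 190,
                          n_components = 6, n_states = 4, tr_seconds = 2.4,
                          separation = 0.6, self_transition = 0.9,
                          effects = default_planted_effects()) {
  structure(
    list(
      n_subjects = n_subjects, n_timepoints = n_timepoints,
      n_components = n_components, n_states = n_states,
      tr_seconds = tr_seconds, separation = separation,
      self_transition = self_transition, effects = effects
    ),
    class = "dfnc_cohort_config"
  )
}

#' Generate a synthetic cohort with ground truth
#'
#' Composes the state templates, Markov chain, Gaussian emissions and
#' behaviour generator into a full cohort: per-subject time courses, the true
#' latent state sequence for every timepoint, ground-truth dynamic features
#' and a behavioural table with the configured planted effects.
#'
#' Ground-truth features per subject: fraction time and mean dwell time per
#' state and transition count from the true sequence; `state1_sn_lecn_z`,
#' the Fisher-z SN-lECN sample correlation over true state-1 timepoints
#' (NA when state 1 has fewer than 10 timepoints); and `path_length`, the
#' summed L1 distance between consecutive states' connectivity vectors, a
#' ground-truth analogue of distance travelled through connectivity space.
#'
#' @param config A [cohort_config()].
#' @param seed Integer seed; the same seed and config reproduce the cohort
#'   bit-for-bit.
#' @return List of class `dfnc_cohort`: `subjects` (list of `subject_tc`),
#'   `true_states` (list of integer vectors), `features` (tibble),
#'   `behavior` (tibble), `states` (the generating `state_covariance_set`),
#'   `config`, `seed`.
#' @export
#' @examples
#' coh <- generate_cohort(cohort_config(n_subjects = 3, n_timepoints = 60), seed = 1)
#' length(coh$subjects)
generate_cohort <- function(config = cohort_config(), seed = 1) {
  stopifnot(inherits(config, "dfnc_cohort_config"))
  set.seed(seed)
  states <- make_default_states(C = config$n_components, K = config$n_states,
                                separation = config$separation)
  model <- markov_model(config$n_states, self_transition = config$self_transition)
  n <- config$n_subjects
  sub_seeds <- sample.int(2147483647L, 2 * n)
  ids <- sprintf("sub%03d", seq_len(n))

  subjects <- vector("list", n)
  true_states <- vector("list", n)
  feats <- vector("list", n)
  state_vecs <- do.call(rbind, lapply(states$covariances, vectorize_fnc))
  comp <- colnames(states$covariances[[1]])
  for (i in seq_len(n)) {
    sq <- simulate_state_sequence(model, config$n_timepoints,
                                  seed = sub_seeds[2 * i - 1])
    tc <- simulate_subject_timecourse(states, sq, seed = sub_seeds[2 * i],
                                      tr_seconds = config$tr_seconds,
                                      subject_id = ids[i])
    subjects[[i]] <- tc
    true_states[[i]] <- sq
    feats[[i]] <- true_sequence_features(sq, tc$values, state_vecs, comp,
                                         K = config$n_states)
  }
  features <- dplyr::bind_cols(
    tibble::tibble(subject_id = ids),
    dplyr::bind_rows(feats)
  )
  behavior <- simulate_behavior_table(features, effects = config$effects,
                                      seed = sample.int(2147483647L, 1))
  structure(
    list(subjects = setNames(subjects, ids),
         true_states = setNames(true_states, ids),
         features = features, behavior = behavior,
         states = states, config = config, seed = seed),
    class = "dfnc_cohort"
  )
}

# ground-truth dynamic features from one subject's latent sequence
true_sequence_features <- function(sq, values, state_vecs, comp, K) {
  r <- rle(sq)
  T_len <- length(sq)
  ft <- tabulate(sq, nbins = K) / T_len
  mdt <- vapply(seq_len(K), function(k) {
    runs <- r$lengths[r$values == k]
    if (length(runs) == 0) 0 else mean(runs)
  }, numeric(1))
  nt <- sum(sq[-1] != sq[-T_len])
  path <- if (length(r$values) > 1) {
    sum(vapply(seq_len(length(r$values) - 1), function(j) {
      sum(abs(state_vecs[r$values[j], ] - state_vecs[r$values[j + 1], ]))
    }, numeric(1)))
  } else 0
  s1 <- which(sq == 1)
  z_sn_lecn <- NA_real_
  if (length(s1) >= 10 && all(c("SN", "lECN") %in% comp)) {
    rr <- cor(values[s1, "SN"], values[s1, "lECN"])
    if (is.finite(rr) && abs(rr) < 1) z_sn_lecn <- atanh(rr)
  }
  out <- c(setNames(ft, paste0("ft_state", seq_len(K))),
           setNames(mdt, paste0("mdt_state", seq_len(K))),
           nt = nt, path_length = path, state1_sn_lecn_z = z_sn_lecn)
  tibble::as_tibble(as.list(out))
}

#' @export
print.dfnc_cohort <- function(x, ...) {
  cat(sprintf(
    "<dfnc_cohort> %d subjects x %d timepoints x %d components, %d latent states (seed %d)\n",
    length(x$subjects), x$config$n_timepoints, x$config$n_components,
    x$config$n_states, x$seed
  ))
  invisible(x)
}
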