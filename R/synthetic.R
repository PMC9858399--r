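#' Default triple-network component labels
#'
#' Six components covering the default mode (dorsal, posterior ventral,
#' posterior dorsal), executive control (right, left) and salience networks.
#'
#' @return Character vector of length 6.
#' @export
triple_network_components <- function() {
  c("dDMN", "pvDMN", "pdDMN", "rECN", "lECN", "SN")
}

# project a symmetric matrix to the nearest unit-diagonal positive-definite
# correlation-like matrix: clip eigenvalues at eps, rescale to unit diagonal
repair_correlation <- function(m, eps = 1e-6) {
  m <- (m + t(m)) / 2
  e <- eigen(m, symmetric = TRUE)
  vals <- pmax(e$values, eps)
  m2 <- e$vectors %*% (vals * t(e$vectors))
  d <- sqrt(diag(m2))
  m2 <- m2 / tcrossprod(d)
  diag(m2) <- 1
  (m2 + t(m2)) / 2
}

#' Latent connectivity-state covariance templates
#'
#' Builds K unit-diagonal positive-definite covariance (correlation) matrices
#' describing recurring cross-network connectivity states. With the defaults
#' (`C = 6`, `K = 4`) the four states emulate the canonical resting-state
#' repertoire seen with the triple-network components:
#'
#' 1. a posterior-DMN / ECN block of positive connectivity with the salience
#'    network decoupled (its row near zero);
#' 2. a strongly modular state: positive within DMN and within ECN, DMN-ECN
#'    anti-correlated, moderate DMN-SN coupling;
#' 3. a globally hyperconnected state: every off-diagonal positive;
#' 4. an isolated strong pvDMN-SN synchronisation, both decoupled from the
#'    remaining components, which stay positively coupled amongst themselves.
#'
#' Off-diagonal magnitudes scale linearly with `separation`; `separation = 0`
#' gives identity matrices. Templates that are not positive definite after
#' scaling are repaired by eigenvalue clipping at 1e-6 followed by rescaling
#' to unit diagonal.
#'
#' @param C Number of components (>= 2). Only `C = 6` carries the named
#'   template structure; other C get generic block patterns.
#' @param K Number of states (1..4 for the named templates).
#' @param separation Positive scalar scaling off-diagonal strength. Default 0.6.
#'
#' @return A list of class `state_covariance_set` with elements `K`,
#'   `covariances` (list of K matrices) and `labels`.
#' @export
#' @examples
#' st <- make_default_states()
#' all(st$covariances[[3]][upper.tri(diag(6))] > 0)
make_default_states <- function(C = 6, K = 4, separation = 0.6) {
  if (C < 2) abort("`C` must be >= 2")
  if (K < 1) abort("`K` must be >= 1")
  if (separation < 0) abort("`separation` must be >= 0")

  comp <- if (C == 6) triple_network_components() else paste0("comp", seq_len(C))
  templates <- default_state_templates(C)
  if (K > length(templates)) {
    # cycle templates with mild perturbation for K beyond the repertoire
    templates <- rep(templates, length.out = K)
  }
  covs <- vector("list", K)
  for (k in seq_len(K)) {
    m <- diag(C) + separation * templates[[k]]
    m <- repair_correlation(m)
    ev <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) <= 0) {
      abort(sprintf("state %d not positive definite after repair (min eig %.3g)", k, min(ev)))
    }
    dimnames(m) <- list(comp, comp)
    covs[[k]] <- m
  }
  structure(
    list(K = K, covariances = covs, labels = paste0("state", seq_len(K))),
    class = "state_covariance_set"
  )
}

# off-diagonal templates (zero diagonal), entries in [-1, 1], scaled by
# `separation` in make_default_states. Component order for C = 6:
# dDMN, pvDMN, pdDMN, rECN, lECN, SN.
default_state_templates <- function(C) {
  tpl <- function(fill) {
    m <- matrix(0, C, C)
    fill(m)
  }
  if (C == 6) {
    s1 <- tpl(function(m) {
      m[1:5, 1:5] <- 0.3            # weak coupling among non-SN components
      m[2, 3] <- 1.0                # posterior DMN block
      m[3, 4] <- 0.9                # pdDMN-rECN
      m[4, 5] <- 0.8                # ECN block
      m[6, ] <- 0; m[, 6] <- 0      # SN segregated
      diag(m) <- 0
      m[lower.tri(m)] <- t(m)[lower.tri(m)]
      m
    })
    s2 <- tpl(function(m) {
      m[1:3, 1:3] <- 1.0            # DMN block
      m[4:5, 4:5] <- 1.0            # ECN block
      m[1:3, 4:5] <- -0.6           # DMN-ECN anticorrelation
      m[4:5, 1:3] <- -0.6
      m[1:3, 6] <- 0.5; m[6, 1:3] <- 0.5  # DMN-SN coupling
      diag(m) <- 0
      m
    })
    s3 <- tpl(function(m) {
      m[] <- 0.7                    # global hyperconnectivity
      diag(m) <- 0
      m
    })
    s4 <- tpl(function(m) {
      others <- c(1, 3, 4, 5)
      m[others, others] <- 0.6
      m[2, ] <- -0.2; m[, 2] <- -0.2
      m[6, ] <- -0.2; m[, 6] <- -0.2
      m[2, 6] <- 1.0; m[6, 2] <- 1.0  # isolated pvDMN-SN synchrony
      diag(m) <- 0
      m
    })
    return(list(s1, s2, s3, s4))
  }
  # generic fallback for other C: block patterns of varying sign structure
  half <- max(1, floor(C / 2))
  list(
    tpl(function(m) { m[1:half, 1:half] <- 0.8; diag(m) <- 0; m }),
    tpl(function(m) {
      m[1:half, 1:half] <- 0.8
      m[(half + 1):C, (half + 1):C] <- 0.8
      m[1:half, (half + 1):C] <- -0.5
      m[(half + 1):C, 1:half] <- -0.5
      diag(m) <- 0
      m
    }),
    tpl(function(m) { m[] <- 0.7; diag(m) <- 0; m }),
    tpl(function(m) { m[C, 1] <- 0.9; m[1, C] <- 0.9; m })
  )
}

#' First-order Markov model for latent state dynamics
#'
#' @param K Number of states.
#' @param self_transition Probability of staying in the current state;
#'   off-diagonal mass is spread uniformly. Default 0.9, giving geometric
#'   dwell lengths with mean 10 steps.
#' @param transition Optional explicit K x K row-stochastic matrix
#'   (overrides `self_transition`).
#' @param initial Optional initial distribution; defaults to uniform.
#'
#' @return List of class `markov_model` with `transition` and `initial`.
#' @export
markov_model <- function(K, self_transition = 0.9, transition = NULL,
                         initial = NULL) {
  if (is.null(transition)) {
    if (K == 1) {
      transition <- matrix(1, 1, 1)
    } else {
      off <- (1 - self_transition) / (K - 1)
      transition <- matrix(off, K, K)
      diag(transition) <- self_transition
    }
  }
  transition <- as.matrix(transition)
  if (nrow(transition) != K || ncol(transition) != K) {
    abort("transition matrix must be K x K")
  }
  if (any(transition < 0)) abort("transition probabilities must be >= 0")
  if (any(abs(rowSums(transition) - 1) > 1e-12)) {
    abort("transition matrix rows must sum to 1")
  }
  if (is.null(initial)) initial <- rep(1 / K, K)
  if (length(initial) != K || any(initial < 0) || abs(sum(initial) - 1) > 1e-12) {
    abort("`initial` must be a length-K probability vector")
  }
  structure(list(K = K, transition = transition, initial = initial),
            class = "markov_model")
}

#' Simulate a latent state sequence from a Markov model
#'
#' @param model A [markov_model()].
#' @param T_len Sequence length (>= 1).
#' @param seed Optional integer seed for reproducibility.
#' @return Integer vector of length `T_len` with values in `1..K`.
#' @export
simulate_state_sequence <- function(model, T_len, seed = NULL) {
  stopifnot(inherits(model, "markov_model"))
  if (T_len < 1) abort("`T_len` must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  K <- model$K
  s <- integer(T_len)
  s[1] <- sample.int(K, 1, prob = model$initial)
  if (T_len > 1) {
    for (t in 2:T_len) {
      s[t] <- sample.int(K, 1, prob = model$transition[s[t - 1], ])
    }
  }
  s
}

#' Simulate a subject time course from state covariances and a state sequence
#'
#' At each timepoint the emission is an independent zero-mean multivariate
#' Gaussian draw with the active state's covariance (no within-state temporal
#' autocorrelation), so windowed correlations are unbiased estimates of the
#' state matrices.
#'
#' @param states A [make_default_states()] result (`state_covariance_set`).
#' @param sequence Integer state labels, one per timepoint.
#' @param seed Optional integer seed.
#' @param tr_seconds Repetition time recorded on the result.
#' @param subject_id Identifier recorded on the result.
#' @return A [subject_timecourse()] with `length(sequence)` rows.
#' @export
simulate_subject_timecourse <- function(states, sequence, seed = NULL,
                                        tr_seconds = 2.4,
                                        subject_id = "subject") {
  stopifnot(inherits(states, "state_covariance_set"))
  sequence <- as.integer(sequence)
  if (any(sequence < 1 | sequence > states$K)) {
    abort("`sequence` labels must index into the state set")
  }
  if (!is.null(seed)) set.seed(seed)
  C <- ncol(states$covariances[[1]])
  T_len <- length(sequence)
  z <- matrix(rnorm(T_len * C), T_len, C)
  out <- matrix(0, T_len, C)
  chols <- lapply(states$covariances, chol)
  for (k in unique(sequence)) {
    idx <- which(sequence == k)
    out[idx, ] <- z[idx, , drop = FALSE] %*% chols[[k]]
  }
  comp <- colnames(states$covariances[[1]])
  if (is.null(comp)) comp <- paste0("comp", seq_len(C))
  if (T_len == 1) {
    # below the constructor's T >= 2 floor; build the single-row object directly
    colnames(out) <- comp
    return(structure(
      list(values = out, tr_seconds = tr_seconds,
           subject_id = as.character(subject_id), component_names = comp),
      class = "subject_tc"
    ))
  }
  subject_timecourse(out, tr_seconds = tr_seconds, subject_id = subject_id,
                     component_names = comp)
}
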