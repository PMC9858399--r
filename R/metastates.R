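#' Maximally independent connectivity patterns
#'
#' Models pooled windowed FNC vectors as weighted sums of `m` maximally
#' independent connectivity patterns: the pooled vectors are centred,
#' reduced to their top `m` principal components, whitened, and rotated by a
#' symmetric fixed-point independence-maximising iteration (logcosh
#' contrast). Patterns are oriented so each one's largest-magnitude element
#' is positive and ordered by explained variance (descending), which makes
#' the decomposition reproducible across seeds up to the stochastic
#' initialisation.
#'
#' @param pooled A [pool_windows()] structure (or a plain W_total x P
#'   matrix, in which case all windows are treated as one subject).
#' @param m Number of patterns (2 <= m <= P, m < W_total). Default 4.
#' @param seed Optional integer seed for the rotation's initialisation.
#' @param max_iter,tol Fixed-point iteration controls.
#' @return List of class `metastate_patterns`: `m`, `patterns` (m x P),
#'   `weights` (named list of per-subject W x m matrices), `center` (P
#'   pooled means), `seed`.
#' @export
fit_connectivity_patterns <- function(pooled, m = 4, seed = NULL,
                                      max_iter = 500, tol = 1e-8) {
  if (is.matrix(pooled)) {
    pooled <- list(vectors = pooled,
                   subject = rep("pooled", nrow(pooled)),
                   window = seq_len(nrow(pooled)))
  }
  x <- pooled$vectors
  N <- nrow(x); P <- ncol(x)
  if (m < 2) abort("`m` must be >= 2")
  if (m > P) abort("more patterns than connectivity pairs")
  if (N <= m) abort("need more pooled windows than patterns")
  if (!is.null(seed)) set.seed(seed)

  center <- colMeans(x)
  xc <- sweep(x, 2, center)
  sv <- svd(xc, nu = m, nv = m)
  if (sv$d[m] < 1e-12) abort("pooled windows are rank deficient for this m")
  Z <- sv$u * sqrt(N - 1)                     # whitened scores, unit variance
  R <- fastica_rotation(Z, m, max_iter, tol)  # orthonormal m x m
  S <- Z %*% R                                # independent weights, unit variance
  patterns <- t(R) %*% (sv$d[1:m] / sqrt(N - 1) * t(sv$v))  # m x P

  # orientation: largest-|element| positive; order by explained variance
  for (i in seq_len(m)) {
    peak <- which.max(abs(patterns[i, ]))
    if (patterns[i, peak] < 0) {
      patterns[i, ] <- -patterns[i, ]
      S[, i] <- -S[, i]
    }
  }
  ev <- rowSums(patterns^2)
  ord <- order(ev, decreasing = TRUE)
  patterns <- patterns[ord, , drop = FALSE]
  S <- S[, ord, drop = FALSE]
  colnames(patterns) <- colnames(x)
  rownames(patterns) <- paste0("pattern", seq_len(m))

  subj <- factor(pooled$subject, levels = unique(pooled$subject))
  weights <- lapply(split(seq_len(N), subj), function(idx) {
    S[idx, , drop = FALSE]
  })
  structure(
    list(m = m, patterns = patterns, weights = weights, center = center,
         seed = seed),
    class = "metastate_patterns"
  )
}

# symmetric fixed-point ICA rotation (logcosh contrast) on whitened Z
fastica_rotation <- function(Z, m, max_iter, tol) {
  N <- nrow(Z)
  W <- orthonormalize(matrix(rnorm(m * m), m, m))
  for (it in seq_len(max_iter)) {
    Y <- Z %*% t(W)              # N x m current components
    G <- tanh(Y)
    Gp <- 1 - G^2
    W_new <- crossprod(G, Z) / N - diag(colMeans(Gp)) %*% W
    W_new <- orthonormalize(W_new)
    delta <- max(abs(abs(diag(W_new %*% t(W))) - 1))
    W <- W_new
    if (delta < tol) break
  }
  t(W)                           # rotation applied as Z %*% R
}

# symmetric decorrelation: W <- (W W')^{-1/2} W
orthonormalize <- function(W) {
  e <- eigen(W %*% t(W), symmetric = TRUE)
  e$vectors %*% diag(1 / sqrt(pmax(e$values, 1e-300)), nrow(W)) %*%
    t(e$vectors) %*% W
}

#' Signed quartile discretisation of pattern weights
#'
#' Per pattern, quartile boundaries (25/50/75th percentiles) of the absolute
#' weights pooled over all subjects and windows are computed; each weight is
#' mapped to `sign(weight) * q` where `q` in 1..4 is the quartile of its
#' magnitude (boundary ties go to the lower quartile; an exactly zero weight
#' codes as +1). Codes therefore lie in {-4..-1, 1..4}, never 0.
#'
#' @param patterns A [fit_connectivity_patterns()] result.
#' @return List of class `metastate_trajectory`: `codes` (named list of
#'   per-subject W x m integer matrices), `boundaries` (3 x m quartile
#'   boundaries), `m`.
#' @export
discretize_weights <- function(patterns) {
  stopifnot(inherits(patterns, "metastate_patterns"))
  m <- patterns$m
  all_w <- do.call(rbind, patterns$weights)
  boundaries <- vapply(seq_len(m), function(j) {
    quantile(abs(all_w[, j]), c(0.25, 0.5, 0.75), names = FALSE)
  }, numeric(3))
  codes <- lapply(patterns$weights, function(w) {
    out <- matrix(0L, nrow(w), m)
    for (j in seq_len(m)) {
      a <- abs(w[, j])
      q <- 1L + (a > boundaries[1, j]) + (a > boundaries[2, j]) +
        (a > boundaries[3, j])
      s <- sign(w[, j])
      s[s == 0] <- 1
      out[, j] <- as.integer(s * q)
    }
    out
  })
  structure(list(codes = codes, boundaries = boundaries, m = m),
            class = "metastate_trajectory")
}

#' Meta-state dynamism indices
#'
#' Four per-subject summaries of the discretised trajectory through
#' meta-state space: `number` (distinct meta-states occupied), `changes`
#' (switches between successive windows), `span` (largest L1 distance
#' between two occupied meta-states) and `total_distance` (summed L1
#' distance along the trajectory).
#'
#' @param trajectory A [discretize_weights()] result.
#' @return Tibble: `subject_id`, `number`, `changes`, `span`,
#'   `total_distance`.
#' @export
#' @examples
#' traj <- structure(list(codes = list(a = rbind(c(-4, -4), c(4, 4))), m = 2),
#'                   class = "metastate_trajectory")
#' metastate_metrics(traj)
metastate_metrics <- function(trajectory) {
  stopifnot(inherits(trajectory, "metastate_trajectory"))
  rows <- lapply(names(trajectory$codes), function(id) {
    v <- trajectory$codes[[id]]
    W <- nrow(v)
    key <- apply(v, 1, paste, collapse = ",")
    number <- length(unique(key))
    changes <- if (W > 1) sum(key[-1] != key[-W]) else 0L
    occupied <- unique(v)
    span <- 0
    if (nrow(occupied) > 1) {
      dmat <- as.matrix(stats::dist(occupied, method = "manhattan"))
      span <- max(dmat)
    }
    total <- if (W > 1) sum(abs(diff(v))) else 0
    tibble::tibble(subject_id = id, number = number, changes = changes,
                   span = span, total_distance = total)
  })
  dplyr::bind_rows(rows)
}

#' Full meta-state analysis of pooled windowed FNC
#'
#' Convenience wrapper: fit patterns, discretise, compute indices.
#'
#' @inheritParams fit_connectivity_patterns
#' @return List: `patterns`, `trajectory`, `metrics` (tibble).
#' @export
metastate_analysis <- function(pooled, m = 4, seed = NULL) {
  patterns <- fit_connectivity_patterns(pooled, m = m, seed = seed)
  trajectory <- discretize_weights(patterns)
  list(patterns = patterns, trajectory = trajectory,
       metrics = metastate_metrics(trajectory))
}
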