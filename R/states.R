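#' k-means clustering under the L1 (Manhattan) distance
#'
#' Lloyd-style iteration with Manhattan distance: each point is assigned to
#' the nearest centroid (ties to the lowest centroid index) and each
#' centroid is updated to the componentwise median of its members, the L1
#' minimiser. Empty clusters are re-seeded from the point currently farthest
#' from its assigned centroid. The best of `replicates` independently
#' initialised runs (lowest total within-cluster L1 dispersion) is returned.
#'
#' @param x Numeric matrix, rows = observations (pooled windowed FNC
#'   vectors), columns = features.
#' @param k Number of clusters; must not exceed the number of distinct rows.
#' @param replicates Number of restarts. Default 10.
#' @param max_iter Maximum Lloyd iterations per restart. Default 200.
#' @param seed Optional integer seed; per-replicate seeds are drawn from it.
#' @return List of class `kmeans_l1`: `centroids` (k x P), `cluster`
#'   (per-row labels), `dispersion`, `replicate_seeds`, `iterations`.
#' @export
#' @examples
#' x <- matrix(c(0, 1, 10, 11), ncol = 1)
#' km <- kmeans_l1(x, 2, seed = 1)
#' sort(km$centroids)
kmeans_l1 <- function(x, k, replicates = 10, max_iter = 200, seed = NULL) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < k) abort("fewer observations than clusters")
  ux <- unique(x)
  if (nrow(ux) < k) abort("fewer distinct observations than clusters")
  if (replicates < 1) abort("`replicates` must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  rep_seeds <- sample.int(2147483647L, replicates)
  best <- NULL
  for (r in seq_len(replicates)) {
    set.seed(rep_seeds[r])
    init <- ux[sample.int(nrow(ux), k), , drop = FALSE]
    fit <- lloyd_l1_cpp(x, init, max_iter)
    if (is.null(best) || fit$dispersion < best$dispersion) best <- fit
  }
  colnames(best$centroids) <- colnames(x)
  best$replicate_seeds <- rep_seeds
  class(best) <- "kmeans_l1"
  best
}

#' Elbow-based choice of the number of connectivity states
#'
#' Runs [kmeans_l1()] for each `k` in `k_min..k_max` and computes the
#' cluster index `I(k)` = (mean within-cluster L1 distance to the assigned
#' centroid) / (mean pairwise L1 distance between centroids). The chosen `k`
#' maximises the perpendicular distance from `(k, I(k))` to the chord
#' joining `(k_min, I(k_min))` and `(k_max, I(k_max))`; ties go to the
#' smaller `k`.
#'
#' @param x Pooled windowed-FNC matrix (rows = windows).
#' @param k_min,k_max Range of cluster counts. Defaults 2 and 8.
#' @param replicates,max_iter Per-`k` clustering settings (defaults 10, 200).
#' @param seed Optional integer seed.
#' @return List of class `elbow_selection`: `k` (chosen), `curve` (tibble of
#'   k, dispersion, cluster_index, chord_distance), `fits` (the `kmeans_l1`
#'   objects, named by k).
#' @export
select_k_elbow <- function(x, k_min = 2, k_max = 8, replicates = 10,
                           max_iter = 200, seed = NULL) {
  if (k_max <= k_min) abort("`k_max` must exceed `k_min`")
  if (!is.null(seed)) set.seed(seed)
  ks <- k_min:k_max
  k_seeds <- sample.int(2147483647L, length(ks))
  fits <- vector("list", length(ks))
  index <- disp <- numeric(length(ks))
  for (i in seq_along(ks)) {
    fit <- kmeans_l1(x, ks[i], replicates = replicates, max_iter = max_iter,
                     seed = k_seeds[i])
    fits[[i]] <- fit
    disp[i] <- fit$dispersion
    within <- fit$dispersion / nrow(x)
    cd <- as.matrix(stats::dist(fit$centroids, method = "manhattan"))
    between <- mean(cd[upper.tri(cd)])
    index[i] <- within / between
  }
  chord <- chord_distance(ks, index)
  k_best <- ks[which.max(chord)]   # which.max ties -> first, i.e. smaller k
  structure(
    list(k = k_best,
         curve = tibble::tibble(k = ks, dispersion = disp,
                                cluster_index = index,
                                chord_distance = chord),
         fits = setNames(fits, ks)),
    class = "elbow_selection"
  )
}

# perpendicular distance of each (x, y) point to the chord through endpoints
chord_distance <- function(x, y) {
  x1 <- x[1]; y1 <- y[1]
  x2 <- x[length(x)]; y2 <- y[length(y)]
  abs((y2 - y1) * x - (x2 - x1) * y + x2 * y1 - y2 * x1) /
    sqrt((y2 - y1)^2 + (x2 - x1)^2)
}

#' Partition a pooled clustering back into per-subject state assignments
#'
#' @param fit A `kmeans_l1` result on pooled windows.
#' @param pooled The [pool_windows()] structure the fit was run on.
#' @return List of class `state_partition`: `k`, `centroids`, `assignments`
#'   (named list of per-subject label vectors in window order),
#'   `dispersion`, `replicate_seeds`.
#' @export
state_partition <- function(fit, pooled) {
  stopifnot(inherits(fit, "kmeans_l1"))
  assignments <- split(fit$cluster, factor(pooled$subject, levels = unique(pooled$subject)))
  structure(
    list(k = nrow(fit$centroids), centroids = fit$centroids,
         assignments = assignments, dispersion = fit$dispersion,
         replicate_seeds = fit$replicate_seeds),
    class = "state_partition"
  )
}

#' Per-subject state occupancy metrics
#'
#' From each subject's window-to-state assignment sequence: fraction time
#' (FT, share of windows per state), mean dwell time (MDT, mean maximal run
#' length per state, in windows; 0 for states never entered) and number of
#' transitions (NT, adjacent label changes).
#'
#' @param partition A [state_partition()].
#' @param tr_seconds,step If both supplied, `mdt_seconds_*` columns
#'   (`MDT * step * tr_seconds`) are appended.
#' @return Tibble: `subject_id`, `ft_state*`, `mdt_state*`, `nt`,
#'   `entered_state*` (and optionally `mdt_seconds_state*`).
#' @export
#' @examples
#' p <- structure(list(k = 2, assignments = list(a = c(1, 1, 2, 2, 2, 1))),
#'                class = "state_partition")
#' compute_state_metrics(p)
compute_state_metrics <- function(partition, tr_seconds = NULL, step = NULL) {
  stopifnot(inherits(partition, "state_partition"))
  k <- partition$k
  rows <- lapply(names(partition$assignments), function(id) {
    s <- partition$assignments[[id]]
    W <- length(s)
    r <- rle(s)
    ft <- tabulate(s, nbins = k) / W
    mdt <- vapply(seq_len(k), function(j) {
      runs <- r$lengths[r$values == j]
      if (length(runs) == 0) 0 else mean(runs)
    }, numeric(1))
    nt <- sum(s[-1] != s[-W])
    out <- c(list(subject_id = id, n_windows = W),
             setNames(as.list(ft), paste0("ft_state", seq_len(k))),
             setNames(as.list(mdt), paste0("mdt_state", seq_len(k))),
             list(nt = nt),
             setNames(as.list(ft > 0), paste0("entered_state", seq_len(k))))
    if (!is.null(tr_seconds) && !is.null(step)) {
      out <- c(out, setNames(as.list(mdt * step * tr_seconds),
                             paste0("mdt_seconds_state", seq_len(k))))
    }
    tibble::as_tibble(out)
  })
  dplyr::bind_rows(rows)
}

#' Per-subject, per-state median connectivity
#'
#' For every subject and every state the subject entered, the elementwise
#' median over that subject's windows assigned to the state. Subjects who
#' never entered a state contribute no row for it.
#'
#' @param partition A [state_partition()].
#' @param series_list The per-subject `windowed_fnc` list the partition was
#'   derived from (same subjects, same window order).
#' @return Tibble: `subject_id`, `state`, then one column per pair.
#' @export
subject_state_fnc <- function(partition, series_list) {
  stopifnot(inherits(partition, "state_partition"))
  rows <- list()
  for (id in names(partition$assignments)) {
    s <- partition$assignments[[id]]
    vecs <- series_list[[id]]$vectors
    if (length(s) != nrow(vecs)) {
      abort(sprintf("assignment length mismatch for subject %s", id))
    }
    if (is.null(colnames(vecs))) {
      colnames(vecs) <- paste0("pair", seq_len(ncol(vecs)))
    }
    for (j in sort(unique(s))) {
      med <- apply(vecs[s == j, , drop = FALSE], 2, median)
      rows[[length(rows) + 1]] <- tibble::as_tibble(
        c(list(subject_id = id, state = j), as.list(med))
      )
    }
  }
  dplyr::bind_rows(rows)
}
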