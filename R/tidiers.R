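#' Tidy a state partition into a long centroid table
#'
#' @param x A `state_partition`.
#' @param ... Unused.
#' @return Tibble: `state`, `pair`, `value` (centroid connectivity).
#' @method tidy state_partition
#' @export
tidy.state_partition <- function(x, ...) {
  cn <- colnames(x$centroids)
  if (is.null(cn)) cn <- paste0("pair", seq_len(ncol(x$centroids)))
  tibble::tibble(
    state = rep(seq_len(x$k), each = ncol(x$centroids)),
    pair = rep(cn, times = x$k),
    value = as.vector(t(x$centroids))
  )
}

#' @rdname tidy.state_partition
#' @method glance state_partition
#' @export
glance.state_partition <- function(x, ...) {
  tibble::tibble(
    k = x$k,
    n_subjects = length(x$assignments),
    n_windows = sum(lengths(x$assignments)),
    dispersion = x$dispersion
  )
}

#' Tidy meta-state patterns into a long table
#'
#' @param x A `metastate_patterns`.
#' @param ... Unused.
#' @return Tibble: `pattern`, `pair`, `loading`.
#' @method tidy metastate_patterns
#' @export
tidy.metastate_patterns <- function(x, ...) {
  cn <- colnames(x$patterns)
  tibble::tibble(
    pattern = rep(seq_len(x$m), each = ncol(x$patterns)),
    pair = rep(cn, times = x$m),
    loading = as.vector(t(x$patterns))
  )
}

#' @rdname tidy.metastate_patterns
#' @method glance metastate_patterns
#' @export
glance.metastate_patterns <- function(x, ...) {
  tibble::tibble(
    m = x$m,
    n_subjects = length(x$weights),
    n_windows = sum(vapply(x$weights, nrow, integer(1)))
  )
}

#' Tidy an elbow selection into its cluster-index curve
#'
#' @param x An `elbow_selection`.
#' @param ... Unused.
#' @method tidy elbow_selection
#' @export
tidy.elbow_selection <- function(x, ...) x$curve

#' @rdname tidy.elbow_selection
#' @method glance elbow_selection
#' @export
glance.elbow_selection <- function(x, ...) {
  tibble::tibble(k = x$k, k_min = min(x$curve$k), k_max = max(x$curve$k))
}
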