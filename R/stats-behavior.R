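#' Pearson correlation with a two-sided t-test p-value
#'
#' @param x,y Paired numeric vectors; pairs with missing values are dropped.
#'   Needs n >= 3 complete pairs and nonzero variance in both.
#' @return List: `r`, `p` (two-sided, t distribution with n - 2 df), `n`.
#' @export
pearson_r_p <- function(x, y) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3) abort("need at least 3 complete pairs")
  if (sd(x) == 0 || sd(y) == 0) abort("zero variance in x or y")
  ct <- cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), p = ct$p.value, n = n)
}

#' Benjamini-Hochberg false discovery rate correction
#'
#' Step-up adjustment: with p-values sorted ascending, adjusted
#' `p_(i) = min over j >= i of m * p_(j) / j`, capped at 1; reject where the
#' adjusted value is at most `q`. `m` defaults to the number of p-values but
#' can be set larger to correct against a declared family size.
#'
#' @param pvalues Numeric vector in `[0, 1]` (may be empty).
#' @param q FDR threshold. Default 0.05.
#' @param family_size Family size `m` used for adjustment; default
#'   `length(pvalues)`.
#' @return Tibble: `p`, `q_value` (adjusted), `significant`.
#' @export
bh_fdr <- function(pvalues, q = 0.05, family_size = length(pvalues)) {
  if (length(pvalues) == 0) {
    return(tibble::tibble(p = numeric(0), q_value = numeric(0),
                          significant = logical(0)))
  }
  if (any(pvalues < 0 | pvalues > 1, na.rm = TRUE)) {
    abort("p-values must lie in [0, 1]")
  }
  if (family_size < length(pvalues)) {
    abort("`family_size` cannot be smaller than the number of tests")
  }
  adj <- p.adjust(pvalues, method = "BH", n = family_size)
  tibble::tibble(p = pvalues, q_value = adj, significant = adj <= q)
}

#' Correlate connectivity features with behavioural measures under FDR
#'
#' Runs a Pearson correlation (optionally a partial correlation given
#' covariates) between every feature column and every behavioural measure,
#' using the subjects with data for both (so per-state features
#' automatically restrict to subjects who entered the state), then applies
#' Benjamini-Hochberg FDR across the declared family.
#'
#' @param features Tibble with `subject_id` plus numeric feature columns.
#' @param behavior Tibble with `subject_id` plus measure columns; columns
#'   named in `covariates` are treated as nuisance covariates, not measures.
#' @param family Label for the correction family. Default `"features"`.
#' @param q FDR threshold. Default 0.05.
#' @param covariates Optional character vector of covariate columns in
#'   `behavior`; when given, both sides are residualised on the covariates
#'   and the p-value uses n - 2 - (number of covariates) df.
#' @param family_size Family size for the FDR adjustment; defaults to the
#'   number of tests actually run, but can be set to a declared family
#'   (e.g. 360 for 15 pairs x 4 states x 6 measures).
#' @param measures Optional character vector restricting which behaviour
#'   columns are tested.
#' @return Tibble of class `dfnc_correlations`: `feature`, `behavior`, `n`,
#'   `r`, `p`, `q_value`, `significant`, `family`, `family_size`.
#' @export
correlate_features_behavior <- function(features, behavior,
                                        family = "features", q = 0.05,
                                        covariates = NULL, family_size = NULL,
                                        measures = NULL) {
  stopifnot("subject_id" %in% names(features), "subject_id" %in% names(behavior))
  joined <- dplyr::inner_join(features, behavior, by = "subject_id",
                              suffix = c(".feat", ".beh"))
  if (nrow(joined) == 0) abort("no subjects shared between features and behaviour")
  feat_cols <- setdiff(names(features), "subject_id")
  beh_cols <- setdiff(names(behavior), c("subject_id", covariates))
  if (!is.null(measures)) beh_cols <- intersect(beh_cols, measures)
  # resolve suffixed names after the join
  col_of <- function(nm, side) {
    if (nm %in% names(joined)) nm else paste0(nm, side)
  }
  n_cov <- length(covariates)
  rows <- list()
  for (f in feat_cols) {
    for (b in beh_cols) {
      xv <- joined[[col_of(f, ".feat")]]
      yv <- joined[[col_of(b, ".beh")]]
      keep <- is.finite(xv) & is.finite(yv)
      if (n_cov > 0) {
        cv <- as.matrix(joined[, covariates, drop = FALSE])
        keep <- keep & apply(is.finite(cv), 1, all)
      }
      n <- sum(keep)
      if (n < 3 + n_cov || sd(xv[keep]) == 0 || sd(yv[keep]) == 0) {
        rows[[length(rows) + 1]] <- tibble::tibble(
          feature = f, behavior = b, n = n, r = NA_real_, p = NA_real_)
        next
      }
      if (n_cov > 0) {
        cvk <- cv[keep, , drop = FALSE]
        xr <- resid(lm(xv[keep] ~ cvk))
        yr <- resid(lm(yv[keep] ~ cvk))
        r <- cor(xr, yr)
        df <- n - 2 - n_cov
        tstat <- r * sqrt(df) / sqrt(max(1 - r^2, .Machine$double.eps))
        p <- 2 * pt(-abs(tstat), df)
      } else {
        ct <- pearson_r_p(xv[keep], yv[keep])
        r <- ct$r; p <- ct$p
      }
      rows[[length(rows) + 1]] <- tibble::tibble(
        feature = f, behavior = b, n = n, r = r, p = p)
    }
  }
  out <- dplyr::bind_rows(rows)
  m <- if (is.null(family_size)) sum(!is.na(out$p)) else family_size
  adj <- rep(NA_real_, nrow(out))
  ok <- !is.na(out$p)
  if (any(ok)) {
    adj[ok] <- bh_fdr(out$p[ok], q = q, family_size = max(m, sum(ok)))$q_value
  }
  out$q_value <- adj
  out$significant <- !is.na(adj) & adj <= q
  out$family <- family
  out$family_size <- m
  class(out) <- c("dfnc_correlations", class(out))
  out
}

#' Per-state FNC vs behaviour correlation screen
#'
#' Fisher-z transforms the per-subject, per-state median connectivity from
#' [subject_state_fnc()] and correlates every (pair, state) feature with
#' every behavioural measure, FDR-corrected across the full family
#' (pairs x states x measures; 15 x 4 x 6 = 360 with the defaults).
#'
#' @param state_fnc Output of [subject_state_fnc()].
#' @param behavior Behaviour tibble (`subject_id` + measures).
#' @param q,covariates Passed to [correlate_features_behavior()].
#' @param n_states Number of states in the family; default the states
#'   present in `state_fnc`.
#' @return A `dfnc_correlations` tibble; `feature` is `"<pair>@state<k>"`.
#' @export
state_fnc_behavior <- function(state_fnc, behavior, q = 0.05,
                               covariates = NULL, n_states = NULL) {
  pair_cols <- setdiff(names(state_fnc), c("subject_id", "state"))
  states <- sort(unique(state_fnc$state))
  if (is.null(n_states)) n_states <- length(states)
  wide <- list()
  for (k in states) {
    sub <- state_fnc[state_fnc$state == k, c("subject_id", pair_cols)]
    zs <- lapply(pair_cols, function(pc) {
      r <- pmin(pmax(sub[[pc]], -1 + 1e-12), 1 - 1e-12)
      fisher_z(r)
    })
    names(zs) <- paste0(pair_cols, "@state", k)
    wide[[as.character(k)]] <- dplyr::bind_cols(
      tibble::tibble(subject_id = sub$subject_id), tibble::as_tibble(zs))
  }
  features <- Reduce(function(a, b) dplyr::full_join(a, b, by = "subject_id"),
                     wide)
  fam_size <- length(pair_cols) * n_states *
    length(setdiff(names(behavior), c("subject_id", covariates)))
  correlate_features_behavior(features, behavior, family = "state_fnc",
                              q = q, covariates = covariates,
                              family_size = fam_size)
}

#' Motion quality-control screen: state occurrence vs head motion
#'
#' Raw (uncorrected) Pearson correlations between each state's fraction
#' time and the per-subject mean framewise displacement, reported as a QC
#' screen with a flag at p < 0.05.
#'
#' @param metrics Output of [compute_state_metrics()] (needs `ft_state*`).
#' @param mean_fd Tibble with `subject_id` and `mean_fd` columns.
#' @return Tibble: `state`, `n`, `r`, `p`, `flagged`.
#' @export
motion_state_qc <- function(metrics, mean_fd) {
  stopifnot("subject_id" %in% names(metrics), "subject_id" %in% names(mean_fd),
            "mean_fd" %in% names(mean_fd))
  joined <- dplyr::inner_join(metrics, mean_fd, by = "subject_id")
  ft_cols <- grep("^ft_state", names(metrics), value = TRUE)
  rows <- lapply(seq_along(ft_cols), function(k) {
    ct <- pearson_r_p(joined[[ft_cols[k]]], joined$mean_fd)
    tibble::tibble(state = k, n = ct$n, r = ct$r, p = ct$p,
                   flagged = ct$p < 0.05)
  })
  dplyr::bind_rows(rows)
}
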