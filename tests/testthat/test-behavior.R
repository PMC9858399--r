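test_that("pearson_r_p matches the hand-computed t formula", {
  x <- c(1, 2, 3, 4, 5)
  y <- c(2, 1, 4, 3, 5)
  out <- pearson_r_p(x, y)
  expect_equal(out$r, 0.8)
  tstat <- 0.8 * sqrt(3) / sqrt(1 - 0.64)
  expect_equal(out$p, 2 * pt(-abs(tstat), 3))
  expect_equal(out$n, 5)

  # symmetry and the perfect-fit limit
  expect_equal(pearson_r_p(y, x)$r, out$r)
  expect_equal(pearson_r_p(x, 2 * x + 1)$r, 1)

  expect_error(pearson_r_p(1:2, 2:3), "at least 3")
  expect_error(pearson_r_p(rep(1, 5), 1:5), "zero variance")
})

test_that("BH step-up matches the by-hand adjustment", {
  out <- bh_fdr(c(0.01, 0.02, 0.03, 0.04), q = 0.05)
  expect_true(all(out$significant))  # max criterion: 4 * 0.04 / 4 = 0.04
  expect_equal(out$q_value, c(0.04, 0.04, 0.04, 0.04))

  out2 <- bh_fdr(c(0.2, 0.5), q = 0.05)
  expect_false(any(out2$significant))
  expect_equal(out2$q_value, c(0.4, 0.5))

  empty <- bh_fdr(numeric(0))
  expect_equal(nrow(empty), 0)

  # independent step-up oracle on random p-values
  set.seed(41)
  p <- runif(25)^2
  ord <- order(p)
  m <- 25
  adj_oracle <- numeric(m)
  sorted <- p[ord]
  run <- m * sorted / seq_len(m)
  adj_oracle[ord] <- pmin(rev(cummin(rev(run))), 1)
  expect_equal(bh_fdr(p)$q_value, adj_oracle)
  # monotone in raw p
  expect_true(all(diff(bh_fdr(sort(p))$q_value) >= 0))
})

test_that("feature-behaviour screen records the declared family", {
  coh <- tiny_cohort(n = 12, T_len = 60, seed = 42)
  feats <- coh$features[, c("subject_id", "nt", "mdt_state1")]
  res <- correlate_features_behavior(feats, coh$behavior, family = "demo")
  expect_s3_class(res, "dfnc_correlations")
  expect_equal(nrow(res), 2 * 6)
  expect_true(all(res$family == "demo"))
  expect_true(all(res$q_value >= res$p, na.rm = TRUE))
  expect_true(all(abs(res$r) <= 1, na.rm = TRUE))

  # family can be declared larger than the tests actually run
  res360 <- correlate_features_behavior(feats, coh$behavior,
                                        family_size = 360)
  expect_equal(unique(res360$family_size), 360)
  expect_true(all(res360$q_value >= res$q_value, na.rm = TRUE))

  expect_error(correlate_features_behavior(
    tibble::tibble(subject_id = "zzz", f = 1), coh$behavior),
    "no subjects shared")
})

test_that("per-state family size is pairs x states x measures", {
  coh <- tiny_cohort(n = 10, T_len = 70, seed = 43)
  wl <- cohort_windowed_fnc(coh, taper = short_taper(), condition = FALSE)
  pooled <- pool_windows(wl)
  fit <- kmeans_l1(pooled$vectors, 4, replicates = 3, seed = 2)
  part <- state_partition(fit, pooled)
  sfnc <- subject_state_fnc(part, wl)
  res <- state_fnc_behavior(sfnc, coh$behavior, n_states = 4)
  expect_equal(unique(res$family_size), 15 * 4 * 6)
})

test_that("null features produce calibrated raw p-values", {
  # fraction of p < 0.05 within binomial 99% bounds around 0.05
  set.seed(44)
  n_tests <- 1200
  hits <- 0
  for (b in 1:12) {
    feats <- tibble::tibble(subject_id = as.character(1:50),
                            !!!setNames(replicate(
                              100, rnorm(50), simplify = FALSE),
                              paste0("f", 1:100)))
    beh <- tibble::tibble(subject_id = as.character(1:50), y = rnorm(50))
    res <- correlate_features_behavior(feats, beh)
    hits <- hits + sum(res$p < 0.05)
  }
  bound <- qbinom(c(0.005, 0.995), 12 * 100, 0.05)
  expect_gte(hits, bound[1])
  expect_lte(hits, bound[2])
})

test_that("a planted effect at n = 80 tops its behavioural screen", {
  # one feature screened against the 6-measure battery, rho = 0.35 on one
  # measure and all others null: the planted pair should rank first
  top_rank <- vapply(1:60, function(r) {
    set.seed(500 + r)
    feats <- tibble::tibble(subject_id = as.character(1:80),
                            planted = rnorm(80))
    beh <- simulate_behavior_table(
      feats, tibble::tibble(feature = "planted", behavior = "ysr_adhd",
                            rho = 0.35),
      seed = 9000 + r)
    res <- correlate_features_behavior(feats, beh)
    res$behavior[which.min(res$p)] == "ysr_adhd"
  }, logical(1))
  expect_gte(mean(top_rank), 0.9)
})

test_that("partial correlations remove a shared covariate", {
  set.seed(46)
  n <- 200
  z <- rnorm(n)
  feats <- tibble::tibble(subject_id = as.character(1:n), f = z + rnorm(n, sd = 0.2))
  beh <- tibble::tibble(subject_id = as.character(1:n),
                        y = z + rnorm(n, sd = 0.2), age = z)
  raw <- correlate_features_behavior(feats, beh, measures = "y")
  adj <- correlate_features_behavior(feats, beh, measures = "y",
                                     covariates = "age")
  expect_gt(raw$r, 0.8)
  expect_lt(abs(adj$r), 0.2)
})

test_that("motion QC screen behaves at its limits", {
  coh <- tiny_cohort(n = 10, T_len = 70, seed = 47)
  wl <- cohort_windowed_fnc(coh, taper = short_taper(), condition = FALSE)
  pooled <- pool_windows(wl)
  part <- state_partition(kmeans_l1(pooled$vectors, 3, replicates = 3,
                                    seed = 3), pooled)
  metrics <- compute_state_metrics(part)

  # FD equal to state-1 fraction time -> r = 1 for state 1
  fd <- tibble::tibble(subject_id = metrics$subject_id,
                       mean_fd = metrics$ft_state1)
  qc <- motion_state_qc(metrics, fd)
  expect_equal(qc$r[qc$state == 1], 1)

  # constant FD -> zero variance failure
  fd0 <- tibble::tibble(subject_id = metrics$subject_id, mean_fd = 0.2)
  expect_error(motion_state_qc(metrics, fd0), "zero variance")
})

test_that("independent motion rarely correlates with state occurrence", {
  set.seed(48)
  ok <- vapply(1:20, function(r) {
    n <- 40
    ft <- tibble::tibble(subject_id = as.character(1:n),
                         ft_state1 = runif(n), ft_state2 = runif(n))
    fd <- tibble::tibble(subject_id = as.character(1:n), mean_fd = rnorm(n))
    qc <- motion_state_qc(ft, fd)
    all(abs(qc$r) < 2 / sqrt(n))
  }, logical(1))
  expect_gte(mean(ok), 0.8)
})
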