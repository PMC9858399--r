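test_that("default state set reproduces the qualitative connectivity repertoire", {
  st <- make_default_states(C = 6, K = 4, separation = 0.6)
  expect_length(st$covariances, 4)
  for (m in st$covariances) {
    expect_equal(diag(m), setNames(rep(1, 6), triple_network_components()))
    expect_equal(m, t(m))
    expect_gt(min(eigen(m, symmetric = TRUE, only.values = TRUE)$values), 0)
    off <- vectorize_fnc(m)
    expect_true(all(off > -1 & off < 1))
  }
  # state 3 is globally hyperconnected
  expect_true(all(vectorize_fnc(st$covariances[[3]]) > 0))
  # state 1: SN row ~ 0, posterior-DMN/ECN coupling positive
  s1 <- st$covariances[[1]]
  expect_true(all(abs(s1["SN", setdiff(colnames(s1), "SN")]) < 0.05))
  expect_gt(s1["pvDMN", "pdDMN"], 0.3)
  expect_gt(s1["rECN", "lECN"], 0.2)
  # state 2: DMN-ECN anticorrelated, DMN block positive
  s2 <- st$covariances[[2]]
  expect_lt(s2["dDMN", "rECN"], 0)
  expect_gt(s2["dDMN", "pvDMN"], 0)
  # state 4: pvDMN-SN synchrony dominates both rows
  s4 <- st$covariances[[4]]
  expect_gt(s4["pvDMN", "SN"], 0.4)
  expect_true(all(s4["SN", c("dDMN", "pdDMN", "rECN", "lECN")] <= 0))
})

test_that("zero separation collapses states to identity", {
  st <- make_default_states(C = 2, K = 1, separation = 0)
  expect_equal(unname(st$covariances[[1]]), diag(2))
})

test_that("markov chain simulation honours absorbing and alternating limits", {
  m_abs <- markov_model(3, self_transition = 1)
  s <- simulate_state_sequence(m_abs, 50, seed = 1)
  expect_length(unique(s), 1)

  m_alt <- markov_model(2, self_transition = 0)
  s <- simulate_state_sequence(m_alt, 100, seed = 2)
  expect_true(all(s[-1] != s[-100]))
})

test_that("markov dwell lengths match the geometric mean 1/(1-p)", {
  for (p in c(0.8, 0.9)) {
    s <- simulate_state_sequence(markov_model(4, self_transition = p), 1e5,
                                 seed = 7)
    runs <- rle(s)$lengths
    # drop the final (censored) run
    expect_lt(abs(mean(head(runs, -1)) * (1 - p) - 1), 0.05)
  }
})

test_that("invalid markov models are rejected", {
  expect_error(markov_model(2, transition = matrix(c(0.5, 0.4, 0.2, 0.6), 2)),
               "sum to 1")
  expect_error(markov_model(2, transition = matrix(c(1.5, -0.5, 0, 1), 2,
                                                   byrow = TRUE)), ">= 0")
})

test_that("single-state emissions recover the generating covariance", {
  st <- make_default_states()
  for (k in c(1, 3)) {
    tc <- simulate_subject_timecourse(st, rep(k, 1e5), seed = 40 + k)
    expect_lt(max(abs(cor(tc$values) - st$covariances[[k]])), 0.02)
  }
})

test_that("timecourse simulation is seed-deterministic and supports T = 1", {
  st <- make_default_states()
  sq <- rep(c(1, 2), each = 10)
  a <- simulate_subject_timecourse(st, sq, seed = 5)
  b <- simulate_subject_timecourse(st, sq, seed = 5)
  expect_identical(a$values, b$values)
  one <- simulate_subject_timecourse(st, 2, seed = 5)
  expect_equal(dim(one$values), c(1L, 6L))
})

test_that("behaviour generator plants the requested correlations", {
  set.seed(3)
  feats <- tibble::tibble(subject_id = as.character(1:1e4),
                          f1 = rnorm(1e4), f2 = rnorm(1e4))
  # null effect
  beh0 <- simulate_behavior_table(feats, effects = tibble::tibble(
    feature = character(0), behavior = character(0), rho = numeric(0)),
    seed = 4)
  expect_lt(abs(cor(feats$f1, beh0$ysr_adhd)), 0.03)
  # planted rho = 0.35
  eff <- tibble::tibble(feature = "f1", behavior = "ysr_adhd", rho = 0.35)
  beh <- simulate_behavior_table(feats, effects = eff, seed = 4)
  expect_lt(abs(cor(feats$f1, beh$ysr_adhd) - 0.35), 0.03)
  # cohort-level location/scale
  expect_lt(abs(mean(beh$ysr_attention_problems) - 57.19), 0.2)
  expect_lt(abs(sd(beh$ysr_attention_problems) - 6.85), 0.2)
})

test_that("behaviour generator validates effects", {
  feats <- tibble::tibble(subject_id = "a", f1 = 1)
  expect_error(simulate_behavior_table(
    feats, tibble::tibble(feature = "f1", behavior = "ysr_adhd", rho = 1.2)),
    "rho")
  expect_error(simulate_behavior_table(
    feats, tibble::tibble(feature = "nope", behavior = "ysr_adhd", rho = 0.2)),
    "unknown planted feature")
})

test_that("planted correlations are recovered at cohort size n = 80", {
  # sampling-error bound 2/sqrt(80) ~ 0.22 should hold in >= 95% of replicates
  for (rho in c(0.24, 0.30, 0.35)) {
    hits <- vapply(1:200, function(r) {
      set.seed(r)
      feats <- tibble::tibble(subject_id = as.character(1:80), f = rnorm(80))
      beh <- simulate_behavior_table(
        feats, tibble::tibble(feature = "f", behavior = "ysr_adhd", rho = rho),
        seed = 10000 + r)
      abs(cor(feats$f, beh$ysr_adhd) - rho) <= 2 / sqrt(80)
    }, logical(1))
    # the claim is about the underlying coverage probability; allow one-sided
    # Monte-Carlo error at 95% confidence for 200 replicates
    expect_gte(mean(hits), 0.95 - 1.64 * sqrt(0.95 * 0.05 / 200))
  }
})

test_that("cohorts have the documented shape, ground truth and determinism", {
  coh <- tiny_cohort(n = 4, T_len = 50, seed = 9)
  expect_length(coh$subjects, 4)
  expect_equal(dim(coh$subjects[[1]]$values), c(50L, 6L))
  expect_equal(lengths(coh$true_states), setNames(rep(50L, 4),
                                                  names(coh$subjects)))
  expect_setequal(coh$behavior$subject_id, names(coh$subjects))

  coh2 <- tiny_cohort(n = 4, T_len = 50, seed = 9)
  expect_identical(coh$subjects[[3]]$values, coh2$subjects[[3]]$values)
  expect_identical(coh$behavior, coh2$behavior)

  coh3 <- tiny_cohort(n = 4, T_len = 50, seed = 10)
  expect_false(identical(coh$subjects[[1]]$values, coh3$subjects[[1]]$values))

  one <- generate_cohort(cohort_config(n_subjects = 1, n_timepoints = 40),
                         seed = 1)
  expect_length(one$subjects, 1)
})
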