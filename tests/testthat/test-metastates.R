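test_that("planted independent mixtures are recovered by the decomposition", {
  # ground truth: 3 sparse orthogonal-ish patterns mixed by heavy-tailed
  # independent weights plus 1% noise
  set.seed(31)
  m <- 3; P <- 15; N <- 2000
  truth <- matrix(0, m, P)
  truth[1, 1:5] <- c(1, 0.8, -0.6, 0.4, 0.9)
  truth[2, 6:10] <- c(-0.7, 1, 0.5, -0.9, 0.6)
  truth[3, 11:15] <- c(0.9, -0.5, 1, 0.7, -0.8)
  w <- matrix(rt(N * m, df = 4), N, m)
  x <- w %*% truth + matrix(rnorm(N * P, sd = 0.01), N, P)
  fit <- fit_connectivity_patterns(x, m = m, seed = 5)
  # optimal |corr| matching between recovered and true patterns
  cors <- abs(cor(t(fit$patterns), t(truth)))
  best <- apply(cors, 2, max)
  expect_true(all(best > 0.95))
  # and the match is a one-to-one assignment
  expect_equal(sort(apply(cors, 2, which.max)), 1:3)
})

test_that("the decomposition is deterministic given a seed and oriented", {
  set.seed(32)
  x <- matrix(rnorm(500 * 10), 500, 10)
  a <- fit_connectivity_patterns(x, m = 4, seed = 7)
  b <- fit_connectivity_patterns(x, m = 4, seed = 7)
  expect_identical(a$patterns, b$patterns)
  expect_identical(a$weights, b$weights)
  for (i in 1:4) {
    peak <- which.max(abs(a$patterns[i, ]))
    expect_gt(a$patterns[i, peak], 0)
  }
  # ordered by explained variance
  ev <- rowSums(a$patterns^2)
  expect_true(all(diff(ev) <= 1e-12))
})

test_that("weights x patterns reconstructs the top-m reduction", {
  set.seed(33)
  x <- matrix(rnorm(300 * 8), 300, 8)
  m <- 3
  fit <- fit_connectivity_patterns(x, m = m, seed = 1)
  xc <- sweep(x, 2, fit$center)
  recon <- do.call(rbind, fit$weights) %*% fit$patterns
  sv <- svd(xc)
  topm <- sv$u[, 1:m] %*% diag(sv$d[1:m]) %*% t(sv$v[, 1:m])
  expect_lt(max(abs(recon - topm)), 1e-8)
  expect_error(fit_connectivity_patterns(x, m = 9), "more patterns")
})

test_that("signed quartile discretisation follows the percentile rule", {
  fake <- structure(
    list(m = 1, patterns = matrix(1, 1, 2),
         weights = list(s1 = matrix(c(1, 2, 3, 4), 4, 1))),
    class = "metastate_patterns")
  tr <- discretize_weights(fake)
  expect_equal(as.vector(tr$codes$s1), c(1L, 2L, 3L, 4L))

  # sign symmetry: -w maps to the negative of +w's code
  fake$weights <- list(s1 = matrix(c(1, 2, 3, 4, -1, -2, -3, -4), 8, 1))
  tr <- discretize_weights(fake)
  codes <- as.vector(tr$codes$s1)
  expect_equal(codes[5:8], -codes[1:4])
  expect_true(all(codes %in% c(-4:-1, 1:4)))

  # boundary ties go to the lower quartile; zero codes as +1
  fake$weights <- list(s1 = matrix(c(0, 1, 1, 2), 4, 1))
  tr <- discretize_weights(fake)
  expect_true(all(as.vector(tr$codes$s1) != 0))
})

test_that("quartile occupancy is ~25% per level for continuous weights", {
  set.seed(34)
  fake <- structure(
    list(m = 2, patterns = matrix(1, 2, 3),
         weights = list(s1 = matrix(rnorm(4000), 2000, 2))),
    class = "metastate_patterns")
  tr <- discretize_weights(fake)
  for (j in 1:2) {
    occ <- table(abs(tr$codes$s1[, j])) / 2000
    expect_true(all(abs(occ - 0.25) < 0.02))
  }
})

test_that("meta-state indices match hand-computed trajectories", {
  mk <- function(rows) structure(list(codes = list(a = rows), m = ncol(rows)),
                                 class = "metastate_trajectory")
  one <- metastate_metrics(mk(matrix(rep(c(1, 1, 1, 1), 5), 5, 4, byrow = TRUE)))
  expect_equal(one$number, 1)
  expect_equal(one$changes, 0)
  expect_equal(one$span, 0)
  expect_equal(one$total_distance, 0)

  two <- metastate_metrics(mk(rbind(c(-4, -4, -4, -4), c(4, 4, 4, 4))))
  expect_equal(two$number, 2)
  expect_equal(two$changes, 1)
  expect_equal(two$span, 32)
  expect_equal(two$total_distance, 32)

  tri <- metastate_metrics(mk(rbind(c(1, 1, 1, 1), c(2, 1, 1, 1),
                                    c(1, 1, 1, 1))))
  expect_equal(tri$number, 2)
  expect_equal(tri$changes, 2)
  expect_equal(tri$span, 1)
  expect_equal(tri$total_distance, 2)
})

test_that("meta-state index invariants hold on random trajectories", {
  set.seed(35)
  for (r in 1:30) {
    W <- sample(2:80, 1)
    m <- sample(2:5, 1)
    codes <- matrix(sample(c(-4:-1, 1:4), W * m, replace = TRUE), W, m)
    tr <- structure(list(codes = list(x = codes), m = m),
                    class = "metastate_trajectory")
    idx <- metastate_metrics(tr)
    expect_lte(idx$number, idx$changes + 1)
    expect_lte(idx$number, W)
    expect_lte(idx$changes, W - 1)
    expect_lte(idx$span, 8 * m)
    if (idx$changes >= 1) expect_gte(idx$total_distance, idx$span)
    expect_equal(idx$total_distance == 0, idx$changes == 0)
  }
})
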