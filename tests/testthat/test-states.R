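test_that("L1 k-means solves the enumerable 1-D problem exactly", {
  # oracle: exhaustive enumeration of all 2-cluster partitions of 4 points
  pts <- c(0, 1, 10, 11)
  best <- list(disp = Inf)
  for (mask in 1:(2^4 - 2)) {
    g <- as.logical(bitwAnd(mask, 2^(0:3)))
    if (all(g) || !any(g)) next
    c1 <- median(pts[g]); c2 <- median(pts[!g])
    d <- sum(abs(pts[g] - c1)) + sum(abs(pts[!g] - c2))
    if (d < best$disp) best <- list(disp = d, cents = sort(c(c1, c2)))
  }
  expect_equal(best$disp, 2)
  expect_equal(best$cents, c(0.5, 10.5))

  km <- kmeans_l1(matrix(pts, ncol = 1), 2, seed = 1)
  expect_equal(sort(as.vector(km$centroids)), best$cents)
  expect_equal(km$dispersion, best$disp)
})

test_that("identical points collapse to zero dispersion and k is bounded", {
  x <- matrix(1, 10, 3)
  km <- kmeans_l1(x, 1, seed = 1)
  expect_equal(km$dispersion, 0)
  expect_error(kmeans_l1(x, 2, seed = 1), "distinct")
})

test_that("converged centroids are the componentwise medians of their members", {
  set.seed(12)
  x <- rbind(matrix(rnorm(60 * 3), 60, 3),
             matrix(rnorm(60 * 3, mean = 6), 60, 3))
  km <- kmeans_l1(x, 2, replicates = 5, seed = 2)
  for (j in 1:2) {
    members <- x[km$cluster == j, , drop = FALSE]
    expect_equal(as.vector(km$centroids[j, ]),
                 apply(members, 2, median), tolerance = 1e-12)
  }
  # dispersion is recomputable from assignments
  d <- sum(vapply(seq_len(nrow(x)), function(i) {
    sum(abs(x[i, ] - km$centroids[km$cluster[i], ]))
  }, numeric(1)))
  expect_equal(km$dispersion, d)
})

test_that("k-means is seed-deterministic", {
  set.seed(3)
  x <- matrix(rnorm(200 * 5), 200, 5)
  a <- kmeans_l1(x, 3, seed = 9)
  b <- kmeans_l1(x, 3, seed = 9)
  expect_identical(a$centroids, b$centroids)
  expect_identical(a$cluster, b$cluster)
})

test_that("dispersion is non-increasing in k for best-of-replicates runs", {
  set.seed(4)
  x <- matrix(rnorm(300 * 4), 300, 4)
  disp <- vapply(2:6, function(k) {
    kmeans_l1(x, k, replicates = 8, seed = 5)$dispersion
  }, numeric(1))
  expect_true(all(diff(disp) <= 1e-9))
})

test_that("the elbow finds well-separated planted blobs", {
  # the chord criterion is zero at the search-range endpoints by
  # construction, so the planted count must be interior to be recoverable;
  # four blobs over k = 2..8 probe the rule at the pipeline's own geometry
  set.seed(6)
  x <- matrix(c(rnorm(100, 0, 0.3), rnorm(100, 10, 0.3),
                rnorm(100, 20, 0.3), rnorm(100, 30, 0.3)), ncol = 1)
  el <- select_k_elbow(x, k_min = 2, k_max = 8, replicates = 5, seed = 7)
  expect_equal(el$k, 4)
  expect_equal(el$curve$k, 2:8)
})

test_that("state metrics follow their run-length definitions", {
  p <- structure(list(k = 2, centroids = matrix(0, 2, 1),
                      assignments = list(a = c(1, 1, 2, 2, 2, 1)),
                      dispersion = 0, replicate_seeds = 1L),
                 class = "state_partition")
  m <- compute_state_metrics(p)
  expect_equal(m$nt, 2)
  expect_equal(m$ft_state1, 0.5)
  expect_equal(m$ft_state2, 0.5)
  expect_equal(m$mdt_state1, 1.5)
  expect_equal(m$mdt_state2, 3)
  expect_true(m$entered_state1 && m$entered_state2)

  # constant sequence
  p$assignments <- list(a = rep(1L, 20))
  m <- compute_state_metrics(p)
  expect_equal(m$nt, 0)
  expect_equal(m$ft_state1, 1)
  expect_equal(m$mdt_state1, 20)
  expect_equal(m$ft_state2, 0)
  expect_equal(m$mdt_state2, 0)
  expect_false(m$entered_state2)

  # strict alternation over 160 windows
  p$assignments <- list(a = rep(c(1L, 2L), 80))
  expect_equal(compute_state_metrics(p)$nt, 159)

  # seconds conversion
  p$assignments <- list(a = c(1, 1, 2, 2, 2, 1))
  ms <- compute_state_metrics(p, tr_seconds = 2.4, step = 1)
  expect_equal(ms$mdt_seconds_state2, 3 * 2.4)
})

test_that("state metric invariants hold on random assignment sequences", {
  set.seed(8)
  for (r in 1:25) {
    k <- sample(2:5, 1)
    W <- sample(10:160, 1)
    s <- sample.int(k, W, replace = TRUE)
    p <- structure(list(k = k, centroids = matrix(0, k, 1),
                        assignments = list(x = s), dispersion = 0,
                        replicate_seeds = 1L),
                   class = "state_partition")
    m <- compute_state_metrics(p)
    ft <- as.numeric(m[paste0("ft_state", 1:k)])
    mdt <- as.numeric(m[paste0("mdt_state", 1:k)])
    expect_equal(sum(ft), 1, tolerance = 1e-12)
    expect_lte(m$nt, W - 1)
    # run-length conservation: sum over states of (#runs x MDT) = W
    runs <- rle(s)
    nruns <- vapply(1:k, function(j) sum(runs$values == j), numeric(1))
    expect_equal(sum(nruns * mdt), W, tolerance = 1e-9)
    expect_equal(m$nt == 0, length(unique(s)) == 1)
    expect_equal(ft == 0, mdt == 0)
  }
})

test_that("per-state median connectivity honours the occupancy rule", {
  vecs <- rbind(c(0.1, 0), c(0.2, 0), c(0.9, 0), c(0.4, 0.5))
  series <- list(s1 = list(vectors = vecs))
  p <- structure(list(k = 3, centroids = matrix(0, 3, 2),
                      assignments = list(s1 = c(1, 1, 1, 2)),
                      dispersion = 0, replicate_seeds = 1L),
                 class = "state_partition")
  tab <- subject_state_fnc(p, series)
  expect_equal(nrow(tab), 2)               # state 3 never entered -> absent
  expect_setequal(tab$state, c(1, 2))
  expect_equal(tab[[3]][tab$state == 1], 0.2)   # median of .1 .2 .9
  expect_equal(tab[[3]][tab$state == 2], 0.4)   # single window -> itself
})

test_that("window-to-state assignment is accurate for well-separated states", {
  # planted clusters far apart relative to spread -> near-perfect recovery
  set.seed(9)
  k <- 3; P <- 15
  cents <- matrix(rnorm(k * P, sd = 2), k, P)
  truth <- sample.int(k, 600, replace = TRUE)
  x <- cents[truth, ] + matrix(rnorm(600 * P, sd = 0.15), 600, P)
  km <- kmeans_l1(x, k, replicates = 5, seed = 10)
  # optimal label matching over all permutations of 3 labels
  perms <- list(1:3, c(1, 3, 2), c(2, 1, 3), c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  acc <- max(vapply(perms, function(pm) mean(pm[km$cluster] == truth),
                    numeric(1)))
  expect_gte(acc, 0.95)
})
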