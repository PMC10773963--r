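# Circular ordering, rank-to-time conversion, Kalman smoothing,
# truth-correlation scoring.

test_that("feature transform is scale invariant and invertible", {
  tab <- data.frame(cell_id = paste0("c", 1:50),
                    f1 = runif(50, 1, 5), f2 = rep(2.5, 50))
  tr <- transform_features(tab)
  expect_true(all(tr$f2 == log2(1e4 + 1)))   # constant feature
  tab2 <- tab; tab2$f1 <- tab$f1 * 2         # doubling raw values: no effect
  expect_equal(transform_features(tab2)$f1, tr$f1)
  # inverse transform recovers v / mean(v)
  v_rel <- (2^tr$f1 - 1) / 1e4
  expect_lt(max(abs(v_rel - tab$f1 / mean(tab$f1))), 1e-10)
  tab$f1[1] <- -1
  expect_error(transform_features(tab), "non-negative")
  tab$f1 <- 0
  expect_error(transform_features(tab), "identically zero")
})

test_that("points on a circle are recovered in angular order", {
  set.seed(4)
  n <- 120
  theta <- sort(runif(n, 0, 2 * pi))
  tab <- data.frame(cell_id = paste0("c", 1:n),
                    f1 = 10 + 5 * cos(theta), f2 = 10 + 5 * sin(theta))
  ord <- reconstruct_order(tab, k_clusters = 8, seed = 1, transform = FALSE,
                           n_pcs = NULL)
  # circular order must match angular order up to rotation/reflection
  pos <- order(ord$order)             # position of each cell along the cycle
  d <- diff(pos[order(theta)])
  d <- ((d + n / 2) %% n) - n / 2     # circular differences
  expect_true(all(d == 1) || all(d == -1))
})

test_that("exact tour beats random tours on the same centers", {
  set.seed(5)
  centers <- matrix(runif(16), 8, 2)
  best <- mitotime:::shortest_circular_tour(centers)
  for (i in 1:1000) {
    rnd <- c(1, sample(2:8))
    expect_lte(best$length, mitotime:::tour_length(centers, rnd) + 1e-12)
  }
})

test_that("rank-to-time conversion inverts the asynchronous rank function", {
  expect_equal(rank_to_time(0, 300, 1140), 0)
  expect_equal(rank_to_time(300, 300, 1140), 1140)  # r = N -> one doubling
  r <- 0:300
  t <- rank_to_time(r, 300, 1140)
  expect_true(all(diff(t) > 0))
  # round trip through the rank function r(t) = 2N(1 - 2^(-t/T))
  expect_equal(2 * 300 * (1 - 2^(-t / 1140)), r, tolerance = 1e-9)
  expect_error(rank_to_time(301, 300, 1140), "\\[0, N\\]")
})

test_that("orientation is an involution and accepts explicit overrides", {
  snap <- core_snapshot()
  tab <- snap$table
  ord <- reconstruct_order(tab, seed = 1)
  o1 <- orient_cycle(ord, tab)
  # reversing the input order flips the orientation flag but yields the
  # same final ranks
  ord_rev <- ord
  ord_rev$order <- rev(ord$order)
  o2 <- orient_cycle(ord_rev, tab)
  expect_equal(o2$ranks, o1$ranks)
  expect_equal(o1$orientation * o2$orientation, -1L)
  # explicit override applied verbatim
  o3 <- orient_cycle(ord, tab, start = 17, direction = -1L)
  expect_equal(o3$start, 17)
  expect_equal(o3$orientation, -1L)
  expect_equal(o3$order[1], rev(ord$order)[17])
  # start lands near the true division event
  start_age <- tab$truth_age[o1$order[1]]
  period <- snap$period
  dist_to_division <- min(start_age, period - start_age)
  expect_lt(dist_to_division, period * 0.1)
  # missing hints on anonymous features
  anon <- tab
  names(anon) <- sub("^CycA$", "v1", names(anon))
  names(anon) <- sub("^Cb$", "v2", names(anon))
  names(anon) <- sub("^pCb$", "v3", names(anon))
  names(anon) <- sub("^CCN.*", "v4", names(anon))
  anon2 <- anon[, c("cell_id", "v1", "v2", "v3", "CycE", "truth_age", "truth_index")]
  expect_error(orient_cycle(reconstruct_order(anon2, seed = 1), anon2),
               "hints")
})

test_that("reconstruction is invariant to row shuffling", {
  snap <- core_snapshot()
  tab <- snap$table
  set.seed(21)
  perm <- sample(nrow(tab))
  tab2 <- tab[perm, ]
  r1 <- reconstruction_R(tab, snap$period, seed = 1)
  r2 <- reconstruction_R(tab2, snap$period, seed = 1)
  expect_equal(r1, r2, tolerance = 1e-6)
})

test_that("local-level smoothing reduces noise and has exact noise-free limit", {
  x <- sin(seq(0, 4 * pi, length.out = 200))
  # noise-free series: smoother returns the input (sigma_y -> 0)
  ks0 <- kalman_smooth(x, pad = 0)
  expect_lt(max(abs(ks0$smoothed - x)), 1e-8)
  set.seed(31)
  truth <- rep(1, 500)
  y <- truth + rnorm(500, 0, 0.3)
  ks <- kalman_smooth(y)
  expect_lt(mean((ks$smoothed - truth)^2), mean((y - truth)^2))
  expect_error(kalman_smooth(c(1, NA, 3, rep(1, 20))), "non-finite")
  expect_error(kalman_smooth(1:5), "too short")
})

test_that("level-model variances are recovered by maximum likelihood", {
  est <- sapply(1:5, function(s) {
    set.seed(s)
    x <- cumsum(rnorm(2000, 0, 0.05))
    y <- x + rnorm(2000, 0, 0.5)
    kalman_smooth(y, pad = 0)$variances
  })
  m <- rowMeans(est)
  expect_lt(abs(m["sigma_x2"] - 0.05^2) / 0.05^2, 0.20)
  expect_lt(abs(m["sigma_y2"] - 0.5^2) / 0.5^2, 0.20)
})

test_that("truth correlation handles perfect, reversed and random orders", {
  set.seed(41)
  T <- 60; N <- 300
  ages <- sample_ages(age_distribution(T, N), N, seed = 2)
  true_rank <- rank(ages, ties.method = "first") - 1
  perfect <- correlation_with_truth(as.integer(true_rank), ages, T = T)
  expect_gt(perfect$R, 0.995)
  reversed <- correlation_with_truth(as.integer(N - 1 - true_rank), ages, T = T)
  expect_equal(reversed$R, perfect$R, tolerance = 1e-9)
  # random permutations have near-zero best-aligned correlation
  rs <- replicate(20, correlation_with_truth(
    sample(0:(N - 1)), ages, T = T)$R)
  expect_lt(max(abs(rs)), 0.35)
  expect_lt(stats::median(abs(rs)), 0.2)
})
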