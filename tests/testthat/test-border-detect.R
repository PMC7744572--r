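test_that("near-identical feature sequences yield no significant border", {
  withr::with_seed(1, X <- matrix(1, 60, 6) + rnorm(360, sd = 1e-6))
  dfun <- sliding_distance(X, b = 12)
  expect_true(all(dfun$d2 >= 0))
  expect_false(any(dfun$significant))
  expect_lt(stats::median(dfun$d2), 5)
  br <- find_borders(X, window_sizes = c(12, 15), confirm_fraction = 0.8)
  expect_identical(nrow(br$confirmed), 0L)
})

test_that("the scalar case equals the pooled two-sample statistic squared", {
  withr::with_seed(2, x <- matrix(rnorm(30, mean = rep(c(0, 2), each = 15)), 30, 1))
  dfun <- sliding_distance(x, b = 5)
  for (k in seq_len(nrow(dfun))) {
    i <- dfun$position[k]
    L <- x[(i - 5):(i - 1), 1]
    R <- x[i:(i + 4), 1]
    s2 <- (4 * var(L) + 4 * var(R)) / 8
    expect_equal(dfun$d2[k], (mean(L) - mean(R))^2 / s2, tolerance = 1e-12)
  }
})

test_that("multivariate D2 matches the hand-rolled two-block oracle", {
  withr::with_seed(3, X <- step_sequence(50, p = 6, steps = 25, magnitudes = 1.5))
  dfun <- sliding_distance(X, b = 10)
  for (i in c(11, 25, 35)) {
    expect_equal(dfun$d2[dfun$position == i],
                 oracle_d2(X[(i - 10):(i - 1), ], X[i:(i + 9), ]),
                 tolerance = 1e-10)
  }
})

test_that("an abrupt mean shift is located within one position", {
  for (seed in 1:3) {
    X <- step_sequence(70, steps = 31, magnitudes = 2, seed = seed)
    dfun <- sliding_distance(X, b = 19)
    expect_lte(abs(dfun$position[which.max(dfun$d2)] - 31), 1)
  }
})

test_that("D2 is invariant under invertible affine feature transforms", {
  withr::with_seed(4, {
    X <- step_sequence(50, p = 8, steps = 24, magnitudes = 1)
    A <- matrix(rnorm(64), 8, 8) + 4 * diag(8)
    cc <- rnorm(8)
  })
  d1 <- sliding_distance(X, b = 12)
  d2 <- sliding_distance(sweep(X %*% A, 2, cc, "+"), b = 12)
  expect_equal(d1$d2, d2$d2, tolerance = 1e-6)
})

test_that("doubling a step's magnitude never decreases the peak D2", {
  for (seed in 1:3) {
    X1 <- step_sequence(60, steps = 29, magnitudes = 1, seed = seed)
    X2 <- step_sequence(60, steps = 29, magnitudes = 2, seed = seed)
    p1 <- max(sliding_distance(X1, b = 15)$d2)
    p2 <- max(sliding_distance(X2, b = 15)$d2)
    expect_gte(p2, p1)
  }
})

test_that("window confirmation finds a constructed step once", {
  X <- step_sequence(80, steps = 41, magnitudes = 2.5, seed = 5)
  br <- find_borders(X, window_sizes = 12:24, confirm_fraction = 0.8)
  expect_identical(nrow(br$confirmed), 1L)
  expect_lte(abs(br$confirmed$position - 41), 1)
  expect_gte(br$confirmed$fraction, 0.8)
})

test_that("two well-separated steps are both recovered", {
  X <- step_sequence(220, steps = c(70, 160), magnitudes = c(2.5, 3),
                     seed = 6)
  br <- find_borders(X, window_sizes = 12:24, confirm_fraction = 0.8)
  expect_identical(nrow(br$confirmed), 2L)
  expect_lte(abs(br$confirmed$position[1] - 70), 1)
  expect_lte(abs(br$confirmed$position[2] - 160), 1)
})

test_that("detection errors are informative", {
  X <- step_sequence(30, steps = 15, seed = 7)
  expect_error(sliding_distance(X, b = 1), "at least 2")
  expect_error(sliding_distance(X, b = 16), "too short")
  expect_error(sliding_distance(X[, 1:3] * 0 + 1, b = 6), "[Ss]ingular")
  expect_error(find_borders(X, window_sizes = integer()), "empty")
  expect_error(find_borders(X, window_sizes = 16), "too large")
})

test_that("shrinkage rescues a singular pooled covariance", {
  withr::with_seed(8, {
    X <- cbind(rnorm(40), rnorm(40))
    X <- cbind(X, X[, 1] + X[, 2])   # exactly collinear feature
  })
  expect_error(sliding_distance(X, b = 8), "shrinkage")
  dfun <- sliding_distance(X, b = 8, shrinkage = 0.1)
  expect_true(all(is.finite(dfun$d2)))
})

test_that("border agreement distances follow the contour arc length", {
  same <- border_agreement(c(10, 40), c(10, 40), 40)
  expect_true(all(same$distance_um == 0))
  one <- border_agreement(20, 25, 40)
  expect_equal(one$distance_um, 200)
  # oracle on a non-uniform arc mapping
  arc <- cumsum(runif(50, 30, 50))
  res <- border_agreement(c(5, 30), c(8, 29), arc)
  expect_equal(sort(res$distance_um),
               sort(c(abs(arc[5] - arc[8]), abs(arc[30] - arc[29]))))
  miss <- border_agreement(c(10, 20), 11, 40)
  expect_identical(sum(miss$matched), 1L)
  expect_identical(sum(!miss$matched), 1L)
  empty <- border_agreement(integer(), c(3, 4), 40)
  expect_true(all(!empty$matched))
})

test_that("border_result tidiers expose confirmed positions", {
  X <- step_sequence(80, steps = 41, magnitudes = 2.5, seed = 5)
  br <- find_borders(X)
  expect_identical(tidy(br), br$confirmed)
  g <- glance(br)
  expect_identical(g$n_confirmed, 1L)
  expect_identical(g$n_windows, 13L)
})
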