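test_that("Harrell-Davis weights sum to one and estimates are sane", {
  for (n in c(2, 5, 11, 40)) {
    for (q in c(0.1, 0.5, 0.9)) {
      expect_lt(abs(sum(hd_weights(n, q)) - 1), 1e-12)
    }
  }
  expect_equal(hd_quantile(rep(3.2, 10), c(0.1, 0.5, 0.9)), rep(3.2, 3))
  # symmetric sample: the median estimate sits at the center of symmetry
  x <- c(-2, -1, 0, 1, 2)
  expect_equal(hd_quantile(x, 0.5), 0, tolerance = 1e-12)
  expect_error(hd_quantile(1, 0.5), "n >= 2")
})

test_that("HD deciles match direct beta-weight integration", {
  expect_equal(hd_quantile(1:5, 0.5), hd_oracle(1:5, 0.5), tolerance = 1e-10)
  set.seed(14)
  for (rep in 1:5) {
    x <- rnorm(sample(8:30, 1))
    for (q in c(0.2, 0.5, 0.8)) {
      expect_equal(hd_quantile(x, q), hd_oracle(x, q), tolerance = 1e-10)
    }
  }
})

test_that("HD estimates are monotone in the quantile", {
  set.seed(15)
  for (rep in 1:10) {
    x <- rnorm(20)
    d <- hd_quantile(x, seq(0.05, 0.95, by = 0.05))
    expect_true(all(diff(d) >= -1e-12))
  }
})

test_that("the shift function of identical samples is null everywhere", {
  set.seed(16)
  a <- rnorm(40)
  sf <- shift_function(a, a, n_boot = 300, seed = 1)
  expect_equal(sf$difference, rep(0, 9))
  expect_false(any(sf$significant))
  expect_true(all(sf$ci_low <= sf$difference & sf$difference <= sf$ci_high))
})

test_that("a pure location shift appears at every decile", {
  set.seed(17)
  a <- rnorm(100)
  sf <- shift_function(a, a + 3, n_boot = 500, seed = 2)
  expect_equal(sf$difference, rep(3, 9), tolerance = 1e-12)
  expect_true(all(sf$ci_low > 0))
  expect_true(all(sf$significant))
})

test_that("shift functions are antisymmetric in their arguments", {
  set.seed(18)
  a <- rnorm(30)
  b <- rexp(30)
  expect_equal(shift_function(a, b, n_boot = 100, seed = 3)$difference,
               -shift_function(b, a, n_boot = 100, seed = 3)$difference)
})

test_that("bootstrap CIs cover a pure location shift at nominal rate", {
  n_sims <- 500
  covered <- matrix(FALSE, n_sims, 9)
  set.seed(19)
  for (i in seq_len(n_sims)) {
    a <- rnorm(100)
    b <- rnorm(100) + 3
    sf <- shift_function(a, b, n_boot = 2000, seed = 5000 + i)
    covered[i, ] <- sf$ci_low <= 3 & 3 <= sf$ci_high
  }
  cov_rate <- colMeans(covered)
  expect_true(all(cov_rate >= 0.92 & cov_rate <= 0.98))
})

test_that("Hedges g matches its closed form and flips sign on swap", {
  a <- c(1, 2, 3, 4, 5)
  b <- c(2, 4, 4, 5, 7)
  na <- 5; nb <- 5
  sp <- sqrt(((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2))
  J <- 1 - 3 / (4 * (na + nb - 2) - 1)
  expect_equal(hedges_g(a, b), (mean(a) - mean(b)) / sp * J)
  expect_equal(hedges_g(b, a), -hedges_g(a, b))
  expect_equal(hedges_g(a, a), 0)
  expect_error(hedges_g(c(1, 1), c(1, 1)), "pooled SD")
})

test_that("eta- and epsilon-squared match hand computation", {
  y <- c(1.2, 1.9, 1.4, 2.1,  4.5, 5.1, 4.2, 5.6,  8.3, 7.9, 9.1, 8.7)
  g <- rep(c("a", "b", "c"), each = 4)
  es <- eta_sq_epsilon_sq(y, g)
  grand <- mean(y)
  ssb <- sum(tapply(y, g, function(v) length(v) * (mean(v) - grand)^2))
  sst <- sum((y - grand)^2)
  expect_equal(es$eta_squared, ssb / sst, tolerance = 1e-12)
  # rank-based H without ties, computed from the definition
  r <- rank(y)
  n <- length(y)
  H <- 12 / (n * (n + 1)) * sum(tapply(r, g, function(v) sum(v)^2 / length(v))) -
    3 * (n + 1)
  expect_equal(es$epsilon_squared, H / ((n^2 - 1) / (n + 1)),
               tolerance = 1e-12)

  # null and degenerate guards
  same <- eta_sq_epsilon_sq(rep(c(1, 2), 6), rep(c("a", "b", "c"), each = 4))
  expect_lt(same$eta_squared, 0.1)
  expect_warning(zero <- eta_sq_epsilon_sq(rep(1, 8), rep(c("a", "b"), 4)),
                 "identical")
  expect_equal(zero$eta_squared, 0)
})

test_that("learning slopes are OLS on the square root of practice hours", {
  h <- c(0, 50, 100)
  expect_equal(learning_slope(h, 1 + 2 * sqrt(h))$slope, 2, tolerance = 1e-12)
  expect_equal(learning_slope(h, rep(4, 3))$slope, 0, tolerance = 1e-12)
  expect_error(learning_slope(c(10, 10), c(1, 2)), "distinct hour")

  # normal-equations oracle on noisy data
  set.seed(21)
  score <- 3 + 0.8 * sqrt(h) + rnorm(3, 0, 0.1)
  X <- cbind(1, sqrt(h))
  beta <- solve(t(X) %*% X, t(X) %*% score)
  expect_equal(learning_slope(h, score)$slope, beta[2], tolerance = 1e-10)

  perf <- data.frame(subject = rep(c("a", "b"), each = 3),
                     hours = rep(h, 2),
                     handaxe_score = c(1 + sqrt(h), 2 + 3 * sqrt(h)))
  sl <- learning_slopes(perf)
  expect_equal(sl$learning_slope, c(1, 3), tolerance = 1e-10)
})

test_that("within-condition permutation preserves session distributions", {
  tab <- expand.grid(subject = c("s1", "s2", "s3"),
                     session = c("Pre", "Post1"),
                     window = 1:2, stringsAsFactors = FALSE)
  tab$v <- seq_len(nrow(tab)) / 10
  res <- permute_within_condition(tab, measures = "v", seed = 6)
  # session-wise grand means survive any relabeling
  expect_equal(tapply(res$permuted$v, res$permuted$session, mean),
               tapply(tab$v, tab$session, mean))
  expect_equal(tapply(res$session_means$v, res$session_means$session, mean),
               tapply(tab$v, tab$session, mean))
  # one mean per subject and session
  expect_equal(nrow(res$session_means), 6L)

  # fixed-seed oracle: replicate the per-session relabeling directly
  oracle <- withr::with_seed(6, {
    out <- tab
    for (sess in unique(out$session)) {
      rows <- out$session == sess
      subj <- sort(unique(out$subject[rows]))
      new <- setNames(sample(subj), subj)
      out$subject[rows] <- unname(new[out$subject[rows]])
    }
    out
  })
  expect_equal(res$permuted, oracle)

  # missing cells are refused with a pointer to the hole
  expect_error(permute_within_condition(tab[-1, ], measures = "v"),
               "incomplete")
})
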