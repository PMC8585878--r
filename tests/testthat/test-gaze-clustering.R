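make_gaze_df <- function(subjects, t, xfun) {
  do.call(rbind, lapply(seq_along(subjects), function(i) {
    data.frame(subject = subjects[i], t_s = t, x = xfun(i, t),
               y = 0.5, valid = TRUE)
  }))
}

test_that("window matrices are extracted on a common 60 Hz grid", {
  t <- (0:899) / 60
  g <- make_gaze_df(c("A", "B"), t, function(i, t) rep(0.5, length(t)))
  m <- extract_window_matrix(g, 2, 12)
  expect_equal(dim(m), c(600L, 2L))
  expect_true(all(m == 0.5))
  expect_equal(attr(m, "t_s")[1], 2)

  # a single invalid sample between 0.4 and 0.6 interpolates to 0.5
  g2 <- data.frame(subject = "A", t_s = c(0, 1, 2) / 60,
                   x = c(0.4, 99, 0.6), y = 0.5,
                   valid = c(TRUE, FALSE, TRUE))
  m2 <- extract_window_matrix(g2, 0, 3 / 60)
  expect_equal(unname(m2[2, 1]), 0.5)

  # mostly-invalid subjects are dropped with a warning
  g3 <- rbind(g2, data.frame(subject = "B", t_s = c(0, 1, 2) / 60,
                             x = 0.3, y = 0.5,
                             valid = c(FALSE, FALSE, TRUE)))
  expect_warning(m3 <- extract_window_matrix(g3, 0, 3 / 60), "excluded")
  expect_equal(colnames(m3), "A")
})

test_that("gaze CV matches its closed form and is scale invariant", {
  expect_equal(gaze_cv(c(0.5, 0.5, 0.5)), 0)
  x <- c(0.4, 0.6)
  expect_equal(gaze_cv(x), sd(x) / mean(x))
  set.seed(1)
  y <- runif(50, 0.3, 0.8)
  expect_equal(gaze_cv(3 * y), gaze_cv(y))
  expect_error(gaze_cv(c(0.5)), "2 valid samples")
  expect_error(gaze_cv(c(-1, 1)), "CV undefined")
})

test_that("Ward linkage matches the Lance-Williams recursion", {
  set.seed(20)
  for (rep in 1:5) {
    X <- matrix(rnorm(32), 8, 4)
    res <- ward_cluster(X, k = 3)
    oracle <- lw_ward(X, k_cut = 3)
    expect_equal(res$heights, oracle$heights, tolerance = 1e-12)
    expect_true(same_partition(res$assignments, oracle$partition))
  }
})

test_that("merge heights are non-decreasing and k = n gives pure between", {
  set.seed(3)
  X <- matrix(rnorm(40), 10, 4)
  res <- ward_cluster(X, k = 2)
  expect_true(all(diff(res$heights) >= -1e-12))
  singles <- ward_cluster(X, k = 10)
  expect_equal(singles$within_class_pct, 0)
  expect_equal(singles$between_class_pct, 100)
  expect_error(ward_cluster(X, k = 11), "exceeds")
})

test_that("two separated row blocks are recovered exactly", {
  set.seed(8)
  X <- rbind(matrix(rnorm(40, 0, 0.05), 10, 4),
             matrix(rnorm(40, 3, 0.05), 10, 4))
  res <- ward_cluster(X, k = 2)
  expect_true(same_partition(res$assignments, rep(1:2, each = 10)))
})

test_that("variance decomposition is an exact percentage partition", {
  set.seed(5)
  for (rep in 1:5) {
    X <- matrix(rnorm(60), 12, 5)
    asg <- sample(1:3, 12, replace = TRUE)
    vd <- variance_decomposition(X, asg)
    expect_equal(vd$within_class_pct + vd$between_class_pct, 100,
                 tolerance = 1e-9)
  }
  one <- variance_decomposition(matrix(rnorm(20), 5, 4), rep(1, 5))
  expect_equal(one$within_class_pct, 100)
  expect_equal(one$between_class_pct, 0)

  # brute-force sums of squares on a 6-row toy matrix
  X <- matrix(c(1, 1, 2, 5, 6, 7,
                0, 1, 1, 4, 4, 5), 6, 2)
  asg <- c(1, 1, 1, 2, 2, 2)
  grand <- colMeans(X)
  tot <- sum(sweep(X, 2, grand)^2)
  w <- sum(sweep(X[1:3, ], 2, colMeans(X[1:3, ]))^2) +
    sum(sweep(X[4:6, ], 2, colMeans(X[4:6, ]))^2)
  vd2 <- variance_decomposition(X, asg)
  expect_equal(vd2$within_class_pct, 100 * w / tot)

  deg <- variance_decomposition(matrix(1, 4, 2), c(1, 1, 2, 2))
  expect_true(deg$degenerate)
  expect_equal(deg$within_class_pct, 0)
})

test_that("central objects are the rows nearest their cluster mean", {
  # symmetric 3-row cluster: the middle row is at the mean
  X <- matrix(c(0, 1, 2, 0, 1, 2), 3, 2)
  co <- central_objects(X, rep(1, 3))
  expect_equal(co$row, 2L)

  set.seed(12)
  X2 <- matrix(rnorm(80), 20, 4)
  co2 <- central_objects(X2, rep(1, 20))
  mu <- colMeans(X2)
  d2 <- rowSums(sweep(X2, 2, mu)^2)
  expect_equal(co2$row, which.min(d2))

  # ties break toward the earliest timestamp
  X3 <- matrix(c(1, 0, 1, 1, 0, 1), 3, 2)  # rows 1 and 3 equidistant
  co3 <- central_objects(X3, rep(1, 3))
  expect_equal(co3$row, 1L)
})

test_that("dissimilarity is the mean pairwise centroid distance", {
  X <- rbind(matrix(0, 5, 2), matrix(1, 5, 2))
  asg <- rep(1:2, each = 5)
  expect_equal(dissimilarity_summary(X, asg), sqrt(2))
  expect_warning(d1 <- dissimilarity_summary(X, rep(1, 10)), "single cluster")
  expect_true(is.na(d1))

  set.seed(2)
  X3 <- matrix(rnorm(36), 12, 3)
  asg3 <- rep(1:3, each = 4)
  cents <- t(sapply(1:3, function(cl) colMeans(X3[asg3 == cl, ])))
  hand <- mean(c(sqrt(sum((cents[1, ] - cents[2, ])^2)),
                 sqrt(sum((cents[1, ] - cents[3, ])^2)),
                 sqrt(sum((cents[2, ] - cents[3, ])^2))))
  expect_equal(dissimilarity_summary(X3, asg3), hand)
})

test_that("results are equivariant under subject-column permutation", {
  set.seed(30)
  X <- matrix(rnorm(300), 60, 5)
  res <- ward_cluster(X, k = 3)
  perm <- c(4, 1, 5, 2, 3)
  res_p <- ward_cluster(X[, perm], k = 3)
  expect_true(same_partition(res$assignments, res_p$assignments))
  expect_equal(res$heights, res_p$heights)
  expect_equal(res$within_class_pct, res_p$within_class_pct)
})

test_that("auto-truncation recovers three planted gaze regimes", {
  cfg <- synth_config(n_subjects = 11, video_duration_s = 140,
                      edge_level_values = c(0.52, 0.64, 0.76), seed = 33)
  ds <- generate_dataset(cfg)
  ks <- c()
  for (sess in cfg$sessions) {
    gz <- ds$gaze[ds$gaze$session == sess, ]
    for (w0 in seq(0, 120, by = 15)) {
      m <- extract_window_matrix(gz, w0, w0 + 15)
      ks <- c(ks, ward_cluster(m)$k)
    }
  }
  expect_gte(mean(ks == 3), 0.8)
})
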