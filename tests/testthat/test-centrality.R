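test_that("the complete unweighted 24-node graph is the uniform baseline", {
  A <- matrix(1, 24, 24)
  diag(A) <- 0
  ev <- eigenvector_centrality(A)
  expect_true(ev$converged)
  expect_equal(ev$c, rep(1 / 24, 24), tolerance = 1e-10)
  expect_equal(ev$lambda, 23, tolerance = 1e-8)
})

test_that("the star graph matches its closed-form centrality", {
  A <- matrix(0, 4, 4)
  A[1, 2:4] <- A[2:4, 1] <- 1
  ev <- eigenvector_centrality(A)
  s3 <- sqrt(3)
  expect_equal(ev$c[1], s3 / (3 + s3), tolerance = 1e-9)   # hub ~0.36603
  expect_equal(ev$c[2], 1 / (3 + s3), tolerance = 1e-9)    # leaf ~0.21132
  expect_equal(ev$lambda, s3, tolerance = 1e-8)
})

test_that("power iteration agrees with a dense symmetric eigensolver", {
  set.seed(123)
  worst <- 0
  for (k in 1:100) {
    W <- matrix(runif(24 * 24), 24)
    W <- W + t(W)
    diag(W) <- 0
    ev <- eigenvector_centrality(W)
    ref <- eigen(W, symmetric = TRUE)
    v <- abs(ref$vectors[, 1])
    v <- v / sum(v)
    worst <- max(worst, max(abs(ev$c - v)))
    expect_equal(ev$lambda, ref$values[1], tolerance = 1e-8)
  }
  expect_lt(worst, 1e-8)
})

test_that("centrality is scale-invariant and permutation-equivariant", {
  set.seed(5)
  W <- matrix(runif(100), 10)
  W <- W + t(W)
  diag(W) <- 0
  e1 <- eigenvector_centrality(W)
  e2 <- eigenvector_centrality(7.3 * W)
  expect_equal(e1$c, e2$c, tolerance = 1e-10)
  expect_equal(e2$lambda, 7.3 * e1$lambda, tolerance = 1e-8)
  p <- sample(10)
  e3 <- eigenvector_centrality(W[p, p])
  expect_equal(e3$c, e1$c[p], tolerance = 1e-8)
})

test_that("degenerate inputs are handled as documented", {
  Z <- matrix(0, 5, 5)
  ev <- eigenvector_centrality(Z)
  expect_false(ev$converged)
  expect_true(all(is.na(ev$c)))
  # adding an isolated node sends its centrality to ~0
  set.seed(9)
  W <- matrix(runif(16), 4)
  W <- W + t(W)
  diag(W) <- 0
  W2 <- rbind(cbind(W, 0), 0)
  ev2 <- eigenvector_centrality(W2)
  expect_lt(ev2$c[5], 1e-9)
  expect_equal(ev2$c[1:4] / sum(ev2$c[1:4]),
               eigenvector_centrality(W)$c, tolerance = 1e-8)
  expect_error(eigenvector_centrality(matrix(c(0, 1, -1, 0), 2)), "negative")
})

test_that("classification against 1/n is strict", {
  expect_identical(classify_centrality(0.09), "high")
  expect_identical(classify_centrality(1 / 24), "low")   # tie -> low
  expect_identical(classify_centrality(0.002), "low")
  expect_identical(classify_centrality(c(NA, 0.5)), c(NA, "high"))
})

test_that("weekly aggregation uses ISO weeks and recomputes the ratio", {
  expect_identical(iso_week_label(as.Date("2018-01-01")), "2018-W01")
  expect_identical(iso_week_label(as.Date("2021-01-01")), "2020-W53")

  win <- study_window("2018-01-01", "2018-01-14")
  reg <- make_registry("P1", "N06AB06",
                       as.character(as.Date("2018-01-01") + 0:13))
  daily <- daily_metrics(reg, win)
  expect_identical(daily$n_dispensings, rep(1L, 14))
  cen <- data.table(day = rep(0:13, each = 2),
                    class_label = rep(c("A", "B"), 14),
                    centrality = rep(c(0.6, 0.4), 14),
                    lambda = 1, converged = TRUE)
  wk <- weekly_aggregate(daily, cen, win)
  expect_identical(sort(unique(wk$week)), c("2018-W01", "2018-W02"))
  # constant daily centrality stays constant weekly; counts are summed
  expect_equal(wk[class_label == "A"]$mean_centrality, c(0.6, 0.6))
  expect_identical(unique(wk$n_dispensings), 7L)
  expect_equal(unique(wk$ratio), 1)
  # hand-summed mean over a week with varying centrality
  cen2 <- data.table(day = 0:6, class_label = "A",
                     centrality = c(1, 2, 3, 4, 5, 6, 8) / 10,
                     lambda = 1, converged = TRUE)
  wk2 <- weekly_aggregate(daily, cen2, win)
  expect_equal(wk2[week == "2018-W01" & class_label == "A"]$mean_centrality,
               mean(c(1, 2, 3, 4, 5, 6, 8) / 10))
  # a week with no converged day yields NA centrality
  cen3 <- data.table::copy(cen2)[, converged := FALSE]
  wk3 <- weekly_aggregate(daily, cen3, win)
  expect_true(all(is.na(wk3[week == "2018-W01"]$mean_centrality)))
})
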