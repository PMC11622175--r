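test_that("curves identical to chance produce a zero t field and no clusters", {
  X <- matrix(0.5, 12, 40)
  res <- signflip_maxt(X, n_perm = 200, seed = 1)
  expect_equal(unname(res$t_obs), rep(0, 40))
  expect_equal(nrow(res$clusters), 0)
})

test_that("a strong effect over a known window is covered by one cluster", {
  set.seed(2)
  X <- matrix(rnorm(20 * 100, 0.5, 0.02), 20, 100)
  X[, 40:60] <- X[, 40:60] + 0.15
  res <- signflip_maxt(X, n_perm = 1000, times = seq_len(100), seed = 3)
  expect_equal(nrow(res$clusters), 1)
  expect_lte(res$clusters$onset, 41)
  expect_gte(res$clusters$offset, 59)
})

test_that("the max-t threshold is non-increasing in alpha", {
  set.seed(4)
  X <- matrix(rnorm(15 * 60, 0.5, 0.05), 15, 60)
  th <- vapply(c(0.01, 0.05, 0.2, 0.5),
               function(a) signflip_maxt(X, alpha = a, n_perm = 500,
                                         seed = 7)$threshold_t,
               numeric(1))
  expect_true(all(diff(th) <= 0))
})

test_that("degenerate inputs are handled as documented", {
  expect_error(signflip_maxt(matrix(0.6, 10, 5), n_perm = 200, seed = 1),
               "undefined t")
  expect_error(signflip_maxt(matrix(0.5, 2, 5)), "3 participants")
  expect_warning(signflip_maxt(matrix(rnorm(50, 0.5, 0.1), 10, 5),
                               n_perm = 50, seed = 1),
                 "too small")
})

test_that("two-condition permutation is null for identical conditions", {
  set.seed(5)
  A <- matrix(rnorm(10 * 30, 0.6, 0.05), 10, 30)
  res <- two_condition_perm(A, A + 0, n_perm = 200, seed = 1)
  expect_equal(nrow(res$clusters), 0)

  # an offset over a window is detected
  B <- A
  B[, 10:20] <- B[, 10:20] - rnorm(10, 0.12, 0.03)
  res2 <- two_condition_perm(A, B, n_perm = 800, times = 1:30, seed = 2)
  expect_gte(nrow(res2$clusters), 1)
  expect_lte(min(res2$clusters$onset), 11)

  # swapping conditions mirrors the t field exactly
  res3 <- two_condition_perm(B, A, n_perm = 800, times = 1:30, seed = 2)
  expect_equal(res3$t_obs, -res2$t_obs)

  expect_error(two_condition_perm(A, A[, 1:10]), "shapes")
})

test_that("masked comparisons ignore excluded time points", {
  set.seed(6)
  A <- matrix(rnorm(10 * 30, 0.6, 0.05), 10, 30)
  B <- A
  B[, 1:5] <- B[, 1:5] - 0.3
  keep <- rep(TRUE, 30)
  keep[1:5] <- FALSE
  res <- two_condition_perm(A, B, n_perm = 300, mask = keep, seed = 1)
  expect_equal(nrow(res$clusters), 0)
  expect_equal(length(res$t_obs), 25)
})

test_that("peak latencies take the window argmax with earliest-tie rule", {
  times <- seq(0, 0.3, by = 0.01)
  c1 <- exp(-0.5 * ((times - 0.1) / 0.03)^2)
  c2 <- rep(0.5, length(times)) # flat: tie broken to the earliest point
  pl <- peak_latencies(rbind(c1, c2), window = c(0.06, 0.235), times = times)
  expect_equal(pl$peak_time[1], 0.1)
  expect_equal(pl$peak_time[2], 0.06)
  expect_error(peak_latencies(rbind(c1), window = c(2, 3), times = times),
               "empty")
})

test_that("paired t matches the closed-form and stats::t.test oracle", {
  d <- c(5, -3, 4, 6, -1, 3, 2, 4)
  res <- paired_ttest(d, rep(0, 8))
  # textbook formula
  expect_equal(res$t, mean(d) / (sd(d) / sqrt(8)), tolerance = 1e-12)
  ref <- stats::t.test(d)
  expect_equal(res$t, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(res$p, ref$p.value, tolerance = 1e-12)
  expect_equal(c(res$ci_lo, res$ci_hi), unname(ref$conf.int),
               tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(res$cohen_d, mean(d) / sd(d))

  set.seed(8)
  a <- rnorm(25)
  b <- rnorm(25)
  res2 <- paired_ttest(a, b)
  ref2 <- stats::t.test(a, b, paired = TRUE)
  expect_equal(res2$t, unname(ref2$statistic), tolerance = 1e-10)
  expect_equal(res2$p, ref2$p.value, tolerance = 1e-10)

  expect_equal(paired_ttest(1:10, 1:10 + rnorm(10))$df, 9)
  expect_error(paired_ttest(c(1, 2, 3, 4), c(0, 1, 2, 3)), "zero variance")
})

test_that("identical latencies give a null contrast with BF below 1", {
  la <- c(0.1, 0.12, 0.09, 0.11, 0.1, 0.13)
  expect_error(latency_contrast(la, la), "zero variance")
  lb <- la + rnorm(6, 0, 0.001)
  res <- latency_contrast(la, lb)
  expect_lt(res$bf10, 1)
  expect_gt(res$p, 0.05)
})

test_that("an injected latency shift is detected with high power", {
  set.seed(9)
  hits <- vapply(1:40, function(i) {
    diffs <- rnorm(20, 45, 50)
    res <- paired_ttest(diffs, rep(0, 20))
    res$p < 0.05 & res$t > 0
  }, logical(1))
  expect_gte(mean(hits), 0.8)
})

test_that("JZS Bayes factors behave lawfully", {
  # strictly increasing in |t| at fixed n
  bfs <- vapply(c(0, 0.5, 1, 2, 3, 5), jzs_bf10, numeric(1), n = 36)
  expect_true(all(diff(bfs) > 0))
  expect_lt(jzs_bf10(0, 36), 1)
  # matches the conventional implementation (pingouin/BayesFactor) values
  expect_equal(jzs_bf10(2.5, 20), 2.702288, tolerance = 1e-4)
  expect_equal(jzs_bf10(-2.5, 20), 2.702288, tolerance = 1e-4)
})

test_that("a matrix with chance off-diagonal reduces to the 1D test on its diagonal", {
  set.seed(12)
  P <- 10
  Tn <- 20
  X <- matrix(rnorm(P * Tn, 0.5, 0.04), P, Tn)
  X[, 8:12] <- X[, 8:12] + 0.2
  A <- array(0.5, dim = c(P, Tn, Tn))
  for (p in seq_len(P)) diag(A[p, , ]) <- X[p, ]
  r1 <- signflip_maxt(X, n_perm = 500, seed = 21)
  r2 <- signflip_maxt(A, n_perm = 500, seed = 21)
  expect_equal(r2$threshold_t, r1$threshold_t)
  expect_equal(diag(r2$t_obs), unname(r1$t_obs))
  # significant cells are exactly the significant diagonal points
  sig2 <- which(r2$t_obs > r2$threshold_t, arr.ind = TRUE)
  expect_true(all(sig2[, 1] == sig2[, 2]))
  expect_equal(sort(sig2[, 1]), which(r1$t_obs > r1$threshold_t))
})
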