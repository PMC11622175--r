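test_that("the embedding window yields 25 samples per channel", {
  es <- simulate_epochs(20, 4, effects = list(), seed = 1)
  x <- embed_window(es, t_index = 251)
  expect_equal(dim(x), c(20, 25 * 4))
  es2 <- simulate_epochs(6, 306, effects = list(), sfreq = 500,
                         tmin = -0.1, tmax = 0.1, seed = 2)
  expect_equal(ncol(embed_window(es2, t_index = 51)), 7650)
  expect_error(embed_window(es, t_index = 5), "window")
})

test_that("a constant-in-time epoch repeats identically across the window", {
  dat <- array(rnorm(8 * 3), dim = c(8, 3, 51))
  for (t in 2:51) dat[, , t] <- dat[, , 1]
  es <- epoch_set(dat, seq(-0.05, 0.05, by = 0.002),
                  rep("synthetic", 3), tibble::tibble(epoch_id = 1:8))
  x <- embed_window(es, 26)
  for (w in 1:24) {
    expect_equal(x[, 1:3], x[, w * 3 + 1:3])
  }
})

test_that("super-trials average groups of k and discard leftovers", {
  x <- matrix(rnorm(35 * 4), 35, 4)
  st <- make_super_trials(x, rep("a", 35), k = 10, seed = 1)
  expect_equal(nrow(st$x), 3)

  # k identical epochs average to the epoch itself
  xi <- matrix(rep(1:4, each = 10), 10, 4)
  sti <- make_super_trials(xi, rep("a", 10), k = 10, seed = 1)
  expect_equal(drop(sti$x), c(1, 2, 3, 4), ignore_attr = TRUE)

  # k = 1 is an identity mapping up to order
  st1 <- make_super_trials(x, rep(c("a", "b"), length.out = 35), k = 1, seed = 1)
  expect_equal(nrow(st1$x), 35)
  expect_equal(sort(unname(st1$x[, 1])), sort(x[, 1]))

  expect_error(make_super_trials(x, rep(c("a", "b"), c(30, 5)), k = 10),
               "insufficient")
})

test_that("outcome balancing subsamples the majority outcome", {
  es <- simulate_epochs(100, 4, effects = list(), seed = 3)
  es$labels$outcome <- rep(c("correct", "incorrect"), c(80, 20))
  bal <- balance_by_outcome(es, seed = 1)
  expect_equal(dim(bal$correct$data)[1], 20)
  expect_equal(dim(bal$incorrect$data)[1], 20)
  expect_identical(balance_by_outcome(es, seed = 5)$correct$labels$epoch_id,
                   balance_by_outcome(es, seed = 5)$correct$labels$epoch_id)
  # already balanced: unchanged membership
  es$labels$outcome <- rep(c("correct", "incorrect"), 50)
  bal2 <- balance_by_outcome(es, seed = 2)
  expect_equal(dim(bal2$correct$data)[1], 50)
  es$labels$outcome <- rep("correct", 100)
  expect_error(balance_by_outcome(es), "both outcomes")
})

test_that("decoding permuted labels sits at chance", {
  set.seed(10)
  aucs <- vapply(1:10, function(i) {
    es <- simulate_epochs(150, 12, effects = default_effects(1), seed = 20 + i)
    perm <- sample(es$labels$color_scale) # break the label-data link
    mean(decode_sliding(es, "color", labels = perm, n_folds = 5, n_reps = 3,
                        time_step = 5, seed = i)$auc)
  }, numeric(1))
  expect_lt(abs(mean(aucs) - 0.5), 0.03)
})

test_that("separable classes decode perfectly at the injected latency", {
  es <- simulate_epochs(80, 10,
                        effects = list(effect_spec("foveal", "color", 100,
                                                   amplitude = 5)),
                        noise_sd = 0.05, seed = 7)
  cur <- decode_sliding(es, "color", n_folds = 5, n_reps = 2, seed = 1)
  at_peak <- cur$auc[abs(cur$time_s - 0.100) < 0.004]
  expect_true(all(at_peak == 1))
  # far from the effect the curve is not pinned at 1
  expect_lt(mean(cur$auc[cur$time_s < -0.15]), 0.8)
})

test_that("category decoding is exactly the mean of its pairwise AUCs", {
  es <- simulate_epochs(90, 8, effects = default_effects(0.5), seed = 9)
  cur <- decode_sliding(es, "category", n_folds = 3, n_reps = 2,
                        time_step = 10, seed = 4)
  pw <- attr(cur, "pairwise")
  expect_equal(ncol(pw), 3)
  expect_equal(cur$auc, rowMeans(pw))
  expect_setequal(colnames(pw), c("animal_vs_food", "animal_vs_object",
                                  "food_vs_object"))
})

test_that("temporal generalization reproduces the sliding curve on its diagonal", {
  es <- simulate_epochs(60, 6,
                        effects = list(effect_spec("foveal", "color", 100,
                                                   amplitude = 0.8)),
                        seed = 11)
  tg <- decode_generalization(es, "color", n_folds = 3, n_reps = 2,
                              time_step = 10, seed = 21)
  sl <- decode_sliding(es, "color", n_folds = 3, n_reps = 2,
                       time_step = 10, seed = 21)
  expect_equal(diag(tg$auc), sl$auc)
  expect_equal(tg$train_times, sl$time_s)
})

test_that("transient codes stay near the diagonal, sustained codes spread", {
  off_frac <- function(sustained, width) {
    tgs <- lapply(1:6, function(p) {
      es <- simulate_epochs(120, 15,
                            effects = list(effect_spec("foveal", "color", 100,
                                                       width_ms = width,
                                                       amplitude = 0.35,
                                                       sustained = sustained)),
                            seed = 40 + p)
      decode_generalization(es, "color", n_folds = 5, n_reps = 2,
                            time_step = 10, seed = p)
    })
    A <- aperm(simplify2array(lapply(tgs, function(x) x$auc)), c(3, 1, 2))
    tt <- tgs[[1]]$train_times
    res <- signflip_maxt(A, n_perm = 300, seed = 5)
    sig <- res$t_obs > res$threshold_t
    off <- abs(outer(tt, tt, "-")) > 0.05
    sum(sig & off) / max(1, sum(sig))
  }
  expect_lt(off_frac(FALSE, 60), off_frac(TRUE, 200))
})

test_that("decoding is monotone in the injected signal-to-noise ratio", {
  peak <- vapply(c(0, 0.15, 0.5, 2), function(a) {
    g <- rowMeans(vapply(1:4, function(p) {
      es <- simulate_epochs(100, 10,
                            effects = list(effect_spec("foveal", "color", 100,
                                                       amplitude = a)),
                            seed = 60 + p)
      decode_sliding(es, "color", n_folds = 5, n_reps = 2, time_step = 5,
                     seed = p)$auc
    }, numeric(51)))
    max(g)
  }, numeric(1))
  expect_true(all(diff(peak) > -0.05))
  expect_lt(peak[1], 0.75)
  expect_gt(peak[4], 0.95)
})

test_that("time-delay embedding helps under trial-to-trial latency jitter", {
  peak_with <- numeric(4)
  peak_without <- numeric(4)
  for (p in 1:4) {
    es <- simulate_epochs(120, 10,
                          effects = list(effect_spec("foveal", "color", 100,
                                                     width_ms = 40,
                                                     amplitude = 0.5)),
                          latency_jitter_ms = 25, seed = 80 + p)
    peak_with[p] <- max(decode_sliding(es, "color", n_folds = 5, n_reps = 2,
                                       time_step = 5, seed = p)$auc)
    peak_without[p] <- max(decode_sliding(es, "color", n_folds = 5, n_reps = 2,
                                          half_width_samples = 0,
                                          time_step = 5, seed = p)$auc)
  }
  expect_gte(mean(peak_with), mean(peak_without))
})

test_that("decoding errors name the failing class when data are insufficient", {
  es <- simulate_epochs(30, 4, effects = list(), seed = 2)
  # training folds hold ~12 epochs per class: k = 20 cannot be satisfied
  expect_error(decode_sliding(es, "color", n_folds = 5, n_reps = 1,
                              k_super = 20, seed = 1),
               "fewer")
  # fewer epochs per class than folds
  es8 <- simulate_epochs(8, 4, effects = list(), seed = 3)
  expect_error(decode_sliding(es8, "color", n_folds = 5, n_reps = 1,
                              k_super = 1, seed = 1),
               "insufficient")
})
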