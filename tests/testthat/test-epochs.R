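make_recording <- function(n_ch = 4, n_s = 8000, sfreq = 1000, sd = 1,
                           types = rep("synthetic", n_ch), seed = 1) {
  set.seed(seed)
  list(data = matrix(rnorm(n_ch * n_s, sd = sd), n_ch, n_s),
       sfreq = sfreq, channel_types = types)
}

test_that("muscle annotation flags high-frequency bursts and nothing else", {
  rec <- make_recording(seed = 2)
  # pure low-frequency content: no spans
  t <- seq_len(8000) / 1000
  rec$data <- rec$data * 0.01 + matrix(rep(sin(2 * pi * 7 * t), 4), 4,
                                       byrow = TRUE)
  expect_equal(nrow(annotate_muscle(rec)), 0)

  # inject a 125 Hz burst at 20x the background amplitude
  burst <- 20 * sin(2 * pi * 125 * t[3000:3200])
  rec$data[, 3000:3200] <- rec$data[, 3000:3200] +
    matrix(rep(burst, 4), 4, byrow = TRUE)
  sp <- annotate_muscle(rec)
  expect_equal(nrow(sp), 1)
  expect_lte(sp$onset_ms, 3000)
  expect_gte(sp$offset_ms, 3200)

  # an unreachable threshold flags nothing
  expect_equal(nrow(annotate_muscle(rec, z_thresh = Inf)), 0)
})

test_that("muscle annotation needs a rate above twice the band edge", {
  rec <- make_recording(sfreq = 250)
  expect_error(annotate_muscle(rec), "too low")
})

test_that("epoch extraction applies duration, amplitude and edge rules", {
  rec <- make_recording(n_ch = 3, n_s = 10000, sd = 0.1,
                        types = c("grad", "mag", "synthetic"))
  fx <- tibble::tibble(
    onset_sample = c(2000, 3500, 5000, 6500, 9800),
    duration_ms = c(200, 70, 250, 1200, 300)
  )
  # epoch 3 has a gradiometer excursion beyond 5,000 within -1..+1 s
  rec$data[1, 5600] <- 6000
  res <- extract_epochs(rec, fx)
  expect_equal(res$rejections$reason[res$rejections$fixation == 2],
               "duration_filter")
  expect_equal(res$rejections$reason[res$rejections$fixation == 4],
               "duration_filter")
  expect_equal(res$rejections$reason[res$rejections$fixation == 3], "amplitude")
  expect_equal(res$rejections$reason[res$rejections$fixation == 5], "edge")
  # one epoch survives: 501 samples at 500 Hz over -0.5..+0.5 s
  expect_equal(dim(res$epochs$data), c(1, 3, 501))
  expect_equal(res$epochs$times[1], -0.5)
  expect_equal(res$epochs$times[501], 0.5)
  expect_equal(median(diff(res$epochs$times)), 0.002)
})

test_that("magnetometer-tagged channels use the magnetometer threshold", {
  rec <- make_recording(n_ch = 2, n_s = 6000, sd = 0.1, types = c("mag", "mag"))
  rec$data[2, 3100] <- 5500
  fx <- tibble::tibble(onset_sample = 3000, duration_ms = 200)
  res <- extract_epochs(rec, fx)
  expect_equal(res$rejections$reason, "amplitude")
  expect_equal(dim(res$epochs$data)[1], 0)
})

test_that("epochs overlapping annotated artifacts are rejected", {
  rec <- make_recording(n_ch = 2, n_s = 8000, sd = 0.1)
  fx <- tibble::tibble(onset_sample = c(2500, 6000), duration_ms = c(200, 200))
  arte <- tibble::tibble(onset_ms = 3000, offset_ms = 3100)
  res <- extract_epochs(rec, fx, artifacts = arte)
  expect_equal(res$rejections$reason, "muscle")
  expect_equal(dim(res$epochs$data)[1], 1)
})

test_that("loosening thresholds never reduces the surviving epoch count", {
  rec <- make_recording(n_ch = 2, n_s = 30000, sd = 1800,
                        types = c("grad", "grad"))
  fx <- tibble::tibble(
    onset_sample = seq(2000, 28000, by = 1300),
    duration_ms = round(runif(21, 50, 1100))
  )
  n_tight <- dim(extract_epochs(rec, fx,
                                amplitude_thresholds = c(grad = 5000),
                                min_dur_ms = 80, max_dur_ms = 1000)$epochs$data)[1]
  n_amp <- dim(extract_epochs(rec, fx,
                              amplitude_thresholds = c(grad = Inf),
                              min_dur_ms = 80, max_dur_ms = 1000)$epochs$data)[1]
  n_dur <- dim(extract_epochs(rec, fx,
                              amplitude_thresholds = c(grad = 5000),
                              min_dur_ms = 0, max_dur_ms = Inf)$epochs$data)[1]
  expect_gte(n_amp, n_tight)
  expect_gte(n_dur, n_tight)
})

test_that("epoch subsetting and tidying preserve structure", {
  es <- simulate_epochs(10, 3, effects = list(), seed = 1)
  sub <- es[2:4]
  expect_equal(dim(sub$data)[1], 3)
  expect_equal(sub$labels$epoch_id, 2:4)
  td <- tidy(es)
  expect_equal(nrow(td), 10 * 3 * length(es$times))
  expect_equal(td$value[td$epoch == 5 & td$channel == 2 & td$time_s == 0],
               es$data[5, 2, which(es$times == 0)])
})
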