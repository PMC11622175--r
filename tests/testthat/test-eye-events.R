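test_that("a constant-position trace contains no saccades", {
  tr <- tibble::tibble(t_ms = 0:999, x_deg = 1.2, y_deg = -0.3, pupil = 1000)
  expect_equal(nrow(detect_saccades(tr)), 0)
})

test_that("a single minimum-jerk displacement is one saccade", {
  pos <- tibble::tibble(x = c(0, 4), y = c(0, 0))
  tr <- make_step_trace(pos, dwell_ms = 400, move_ms = 40)
  sac <- detect_saccades(tr)
  expect_equal(nrow(sac), 1)
  # movement spans 400..440 ms
  expect_lt(abs(sac$onset_ms - 400), 5)
  expect_lt(abs(sac$offset_ms - 440), 5)
  # peak velocity of a 4 deg / 40 ms minimum-jerk movement is ~187 deg/s
  expect_equal(sac$peak_velocity, 1.875 * 4 / 0.040, tolerance = 0.1)
})

test_that("traces shorter than the differentiation kernel error", {
  tr <- tibble::tibble(t_ms = 0:5, x_deg = 0, y_deg = 0, pupil = 1000)
  expect_error(detect_saccades(tr), "kernel")
})

test_that("detector recovers generated saccades on noiseless traces", {
  cfg <- synth_config(n_participants = 1, n_trials = 1, n_channels = 2,
                      pos_noise_deg = 0)
  tot <- 0
  ok <- 0
  for (i in 1:30) {
    sp <- simulate_scanpath(make_layout(seed = i), cfg, seed = 400 + i)
    tru <- sp$events[sp$events$kind == "saccade", ]
    det <- detect_saccades(sp$trace)
    tot <- tot + nrow(tru)
    for (k in seq_len(nrow(tru))) {
      don <- min(abs(det$onset_ms - tru$onset_ms[k]))
      doff <- min(abs(det$offset_ms - tru$offset_ms[k]))
      if (don <= 4 && doff <= 4) ok <- ok + 1
    }
    expect_equal(nrow(det), nrow(tru)) # no spurious or missed events
  }
  expect_gte(ok / tot, 0.99)
})

test_that("raising the velocity threshold never increases saccade counts", {
  cfg <- synth_config(n_participants = 1, n_trials = 1, n_channels = 2)
  sp <- simulate_scanpath(make_layout(seed = 3), cfg, seed = 33)
  counts <- vapply(c(20, 30, 60, 120, 500),
                   function(v) nrow(detect_saccades(sp$trace, v_thresh = v,
                                                    a_thresh = 1e9)),
                   numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("blinks are found where the pupil collapses, with a guard margin", {
  tr <- tibble::tibble(t_ms = 0:2999, x_deg = 0, y_deg = 0, pupil = 1000)
  expect_equal(nrow(detect_blinks(tr)), 0)

  tr$pupil[tr$t_ms >= 1000 & tr$t_ms < 1150] <- 0
  b <- detect_blinks(tr)
  expect_equal(nrow(b), 1)
  expect_lte(b$onset_ms, 1000)
  expect_gte(b$offset_ms, 1150)

  expect_error(detect_blinks(tr[, c("t_ms", "x_deg", "y_deg")]), "pupil")
})

test_that("generator-injected blinks are recovered", {
  cfg <- synth_config(n_participants = 1, n_trials = 1, n_channels = 2,
                      blink_prob = 1)
  found <- 0
  n_blinks <- 0
  for (i in 1:10) {
    sp <- simulate_scanpath(make_layout(seed = i), cfg, seed = 600 + i)
    tru <- sp$events[sp$events$kind == "blink", ]
    det <- detect_blinks(sp$trace)
    n_blinks <- n_blinks + nrow(tru)
    for (k in seq_len(nrow(tru))) {
      hit <- any(det$onset_ms <= tru$onset_ms[k] &
                   det$offset_ms >= tru$offset_ms[k])
      if (hit) found <- found + 1
    }
  }
  expect_gt(n_blinks, 0)
  expect_equal(found, n_blinks)
})

test_that("fixations are the exact complement of saccades and blinks", {
  tr <- make_step_trace(tibble::tibble(x = c(0, 4, 2), y = c(0, 0, 3)),
                        dwell_ms = 300, move_ms = 40)
  sac <- detect_saccades(tr)
  fix <- segment_fixations(tr, sac)
  expect_equal(nrow(sac), 2)
  expect_equal(nrow(fix), 3)
  spans <- rbind(cbind(sac$onset_ms, sac$offset_ms),
                 cbind(fix$onset_ms, fix$offset_ms))
  spans <- spans[order(spans[, 1]), ]
  expect_true(all(abs(spans[-1, 1] - head(spans[, 2], -1)) < 1e-9))
  expect_equal(min(spans[, 1]), 0)
  expect_equal(max(spans[, 2]), nrow(tr))

  # no events at all: one fixation spanning the trace
  still <- tibble::tibble(t_ms = 0:499, x_deg = 0, y_deg = 0, pupil = 1000)
  f1 <- segment_fixations(still, detect_saccades(still))
  expect_equal(nrow(f1), 1)
  expect_equal(f1$offset_ms - f1$onset_ms, 500)
})

test_that("detected event sequence matches ground truth on synthetic trials", {
  cfg <- synth_config(n_participants = 1, n_trials = 1, n_channels = 2,
                      pos_noise_deg = 0)
  sp <- simulate_scanpath(make_layout(seed = 9), cfg, seed = 900)
  ev <- detect_eye_events(sp$trace)
  tru <- sp$events
  expect_equal(sum(ev$kind == "fixation"), sum(tru$kind == "fixation"))
  expect_equal(sum(ev$kind == "saccade"), sum(tru$kind == "saccade"))
  # fixation mean positions agree with the generated landing points
  fx_d <- ev[ev$kind == "fixation", ]
  fx_t <- tru[tru$kind == "fixation", ]
  expect_equal(fx_d$x_deg, fx_t$x_deg, tolerance = 0.05)
  expect_equal(fx_d$y_deg, fx_t$y_deg, tolerance = 0.05)
})
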