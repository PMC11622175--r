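#' Simulate a free-viewing scan path over a trial layout
#'
#' Alternating fixations and saccades over the seven images. Fixation
#' durations follow a gamma distribution matched to the configured mean/SD
#' (positive support with the right skew typical of fixation data). Saccades
#' follow a minimum-jerk position profile; their durations are drawn around
#' the value implied by the configured saccade rate
#' (`1000 / saccade_rate_hz - mean_fixation_ms` ms) and capped at the longest
#' duration for which the peak acceleration `5.77 A / T^2` still exceeds the
#' 8,000 deg/s^2 detection threshold, so every simulated saccade exceeds both
#' the velocity (30 deg/s) and acceleration detection thresholds. Slot choice
#' favors unvisited images 3:1. Optionally one blink per trial is carved out
#' of a fixation (pupil drops to 0, gaze frozen).
#'
#' @param layout a `trial_layout` from [make_layout()].
#' @param cfg a [synth_config()]; only the gaze-related fields are used.
#' @param seed optional integer seed.
#' @return list with `trace` (tibble `t_ms`, `x_deg`, `y_deg`, `pupil`) and
#'   `events`, the ground-truth event list (tibble `kind`, `onset_ms`,
#'   `offset_ms`, `slot_id`, `x_deg`, `y_deg`, `peak_velocity`,
#'   `peak_acceleration`), usable as an oracle for the event detectors.
#' @examples
#' sp <- simulate_scanpath(make_layout(seed = 1), synth_config(), seed = 1)
#' table(sp$events$kind)
#' @export
simulate_scanpath <- function(layout, cfg = synth_config(), seed = NULL) {
  if (cfg$mean_fixation_ms > cfg$trial_duration_s * 1000) {
    stop("degenerate config: mean fixation duration exceeds the trial duration")
  }
  with_seed(seed, {
    t_total <- cfg$trial_duration_s * 1000
    shape <- (cfg$mean_fixation_ms / cfg$fixation_sd_ms)^2
    rate <- cfg$mean_fixation_ms / cfg$fixation_sd_ms^2

    land <- function(slot) {
      jit_max <- layout$half_width_deg[1] - 0.3
      c(
        layout$x_deg[slot + 1] + max(-jit_max, min(jit_max, rnorm(1, 0, cfg$landing_jitter_deg))),
        layout$y_deg[slot + 1] + max(-jit_max, min(jit_max, rnorm(1, 0, cfg$landing_jitter_deg)))
      )
    }

    # schedule events ------------------------------------------------------
    sacc_mean <- if (cfg$saccade_rate_hz > 0) {
      max(25, 1000 / cfg$saccade_rate_hz - cfg$mean_fixation_ms)
    } else {
      Inf
    }
    slot <- 0L
    pos <- land(slot)
    visited <- c(0L)
    t <- 0
    ev <- list()
    repeat {
      fix_dur <- rgamma(1, shape = shape, rate = rate)
      if (cfg$saccade_rate_hz == 0 || t + fix_dur >= t_total) {
        ev[[length(ev) + 1]] <- list(kind = "fixation", onset = t, offset = t_total,
                                     slot = slot, x = pos[1], y = pos[2])
        break
      }
      nxt_pool <- setdiff(0:6, slot)
      w <- ifelse(nxt_pool %in% visited, 1, 3)
      nxt <- sample(nxt_pool, 1, prob = w)
      target <- land(nxt)
      amp <- sqrt(sum((target - pos)^2))
      t_nom <- rgamma(1, shape = (sacc_mean / 8)^2, rate = sacc_mean / 8^2)
      t_kin <- 1000 * sqrt(5.773 * amp / 8400) # cap: peak accel stays > 8,000
      sac_dur <- max(12, min(t_nom, t_kin))
      if (t + fix_dur + sac_dur >= t_total) {
        ev[[length(ev) + 1]] <- list(kind = "fixation", onset = t, offset = t_total,
                                     slot = slot, x = pos[1], y = pos[2])
        break
      }
      ev[[length(ev) + 1]] <- list(kind = "fixation", onset = t, offset = t + fix_dur,
                                   slot = slot, x = pos[1], y = pos[2])
      ev[[length(ev) + 1]] <- list(kind = "saccade", onset = t + fix_dur,
                                   offset = t + fix_dur + sac_dur,
                                   slot = NA_integer_, x = target[1], y = target[2],
                                   amp = amp,
                                   from = pos, to = target)
      t <- t + fix_dur + sac_dur
      pos <- target
      slot <- nxt
      visited <- c(visited, nxt)
    }

    # optionally carve one blink out of a sufficiently long fixation --------
    if (runif(1) < cfg$blink_prob) {
      fix_idx <- which(vapply(ev, function(e) e$kind == "fixation" &&
                                (e$offset - e$onset) > 160, logical(1)))
      if (length(fix_idx) > 0) {
        i <- if (length(fix_idx) == 1) fix_idx else sample(fix_idx, 1)
        e <- ev[[i]]
        b_dur <- min(max(80, rnorm(1, 150, 30)), (e$offset - e$onset) - 40)
        b_on <- runif(1, e$onset + 20, e$offset - 20 - b_dur)
        ev[[i]] <- list(kind = "fixation", onset = e$onset, offset = b_on,
                        slot = e$slot, x = e$x, y = e$y)
        ev[[length(ev) + 1]] <- list(kind = "blink", onset = b_on, offset = b_on + b_dur,
                                     slot = NA_integer_, x = e$x, y = e$y)
        ev[[length(ev) + 1]] <- list(kind = "fixation", onset = b_on + b_dur,
                                     offset = e$offset, slot = e$slot, x = e$x, y = e$y)
      }
    }

    events <- dplyr::bind_rows(lapply(ev, function(e) {
      dur_s <- (e$offset - e$onset) / 1000
      tibble(
        kind = e$kind, onset_ms = e$onset, offset_ms = e$offset,
        slot_id = e$slot, x_deg = e$x, y_deg = e$y,
        peak_velocity = if (e$kind == "saccade") 1.875 * e$amp / dur_s else NA_real_,
        peak_acceleration = if (e$kind == "saccade") 5.773 * e$amp / dur_s^2 else NA_real_
      )
    }))
    events <- dplyr::arrange(events, .data$onset_ms)

    # synthesize the gaze trace --------------------------------------------
    dt <- 1000 / cfg$sfreq_gaze
    t_ms <- seq(0, t_total - dt, by = dt)
    n <- length(t_ms)
    x <- numeric(n)
    y <- numeric(n)
    pupil <- 1000 + 20 * sin(2 * pi * t_ms / 2700) + rnorm(n, 0, 4)
    for (e in ev) {
      idx <- which(t_ms >= e$onset & t_ms < e$offset)
      if (length(idx) == 0) next
      if (e$kind == "saccade") {
        tau <- (t_ms[idx] - e$onset) / (e$offset - e$onset)
        s <- 10 * tau^3 - 15 * tau^4 + 6 * tau^5 # minimum-jerk path fraction
        x[idx] <- e$from[1] + s * (e$to[1] - e$from[1])
        y[idx] <- e$from[2] + s * (e$to[2] - e$from[2])
      } else {
        x[idx] <- e$x + rnorm(length(idx), 0, cfg$pos_noise_deg)
        y[idx] <- e$y + rnorm(length(idx), 0, cfg$pos_noise_deg)
        if (e$kind == "blink") {
          x[idx] <- e$x
          y[idx] <- e$y
          pupil[idx] <- 0
        }
      }
    }

    list(
      trace = tibble(t_ms = t_ms, x_deg = x, y_deg = y, pupil = pupil),
      events = events
    )
  })
}
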