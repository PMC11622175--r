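#' Detect saccades from a gaze trace by velocity/acceleration thresholds
#'
#' Velocity and acceleration are estimated by Savitzky-Golay smoothed
#' differentiation (cubic fit over a 9-sample window). A sample is saccadic
#' when the gaze speed exceeds `v_thresh` or the absolute acceleration
#' exceeds `a_thresh`, mirroring the EyeLink parser the thresholds come from.
#' Candidate spans separated by less than `merge_gap_ms` are merged, spans
#' shorter than `min_dur_ms` dropped (suppressing one-sample threshold
#' crossings), and each retained span is extended outward while the speed
#' stays above `onset_frac * v_thresh`, which locates the onset/offset of the
#' underlying movement rather than the threshold crossing.
#'
#' @param trace tibble with `t_ms`, `x_deg`, `y_deg` (uniformly sampled);
#'   a `trial_id` column, if present, is processed per trial.
#' @param v_thresh velocity threshold, deg/s.
#' @param a_thresh acceleration threshold, deg/s^2.
#' @param blinks optional blink events (from [detect_blinks()]); samples
#'   inside blink spans are never saccadic.
#' @param merge_gap_ms,min_dur_ms,onset_frac detector constants (see above).
#' @return tibble of saccade events: `trial_id`, `kind`, `onset_ms`,
#'   `offset_ms`, `peak_velocity`, `peak_acceleration`.
#' @examples
#' sp <- simulate_scanpath(make_layout(seed = 2), synth_config(), seed = 2)
#' detect_saccades(sp$trace)
#' @export
detect_saccades <- function(trace, v_thresh = 30, a_thresh = 8000,
                            blinks = NULL, merge_gap_ms = 4, min_dur_ms = 6,
                            onset_frac = 0.25) {
  per_trial(trace, function(tr, id) {
    blk <- if (!is.null(blinks) && nrow(blinks) > 0) {
      if ("trial_id" %in% names(blinks)) blinks[is.na(id) | blinks$trial_id %in% id, ] else blinks
    } else {
      NULL
    }
    .detect_saccades_one(tr, v_thresh, a_thresh, blk, merge_gap_ms,
                         min_dur_ms, onset_frac)
  })
}

.detect_saccades_one <- function(tr, v_thresh, a_thresh, blinks,
                                 merge_gap_ms, min_dur_ms, onset_frac) {
  n <- nrow(tr)
  if (n < 9) {
    stop("trace shorter than the 9-sample differentiation kernel")
  }
  dt <- median(diff(tr$t_ms))
  sfreq <- 1000 / dt

  x <- tr$x_deg
  y <- tr$y_deg
  # linearly interpolate missing gaze so the filters stay defined
  if (anyNA(x)) x <- approx_fill(tr$t_ms, x)
  if (anyNA(y)) y <- approx_fill(tr$t_ms, y)

  vx <- signal::sgolayfilt(x, p = 3, n = 9, m = 1) * sfreq
  vy <- signal::sgolayfilt(y, p = 3, n = 9, m = 1) * sfreq
  speed <- sqrt(vx^2 + vy^2)
  accel <- signal::sgolayfilt(speed, p = 3, n = 9, m = 1) * sfreq

  cand <- speed > v_thresh | abs(accel) > a_thresh
  if (!is.null(blinks) && nrow(blinks) > 0) {
    for (i in seq_len(nrow(blinks))) {
      cand[tr$t_ms >= blinks$onset_ms[i] & tr$t_ms < blinks$offset_ms[i]] <- FALSE
    }
  }

  runs <- logical_runs(cand)
  if (length(runs$start) == 0) {
    return(empty_events())
  }
  spans <- merge_spans(tr$t_ms[runs$start], tr$t_ms[runs$end] + dt,
                       gap = merge_gap_ms)
  keep <- (spans$offset - spans$onset) >= min_dur_ms
  spans$onset <- spans$onset[keep]
  spans$offset <- spans$offset[keep]
  if (length(spans$onset) == 0) {
    return(empty_events())
  }

  # refine boundaries: walk outward while the speed stays clearly elevated
  lo <- onset_frac * v_thresh
  out <- lapply(seq_along(spans$onset), function(k) {
    i0 <- which.min(abs(tr$t_ms - spans$onset[k]))
    i1 <- which.min(abs(tr$t_ms - (spans$offset[k] - dt)))
    # follow the descending velocity flank to its foot: local minimum below
    # lo, with an absolute floor so smoothing spill-over is not chased
    floor_v <- 0.1 * v_thresh
    while (i0 > 1 && (speed[i0 - 1] > lo ||
                        (speed[i0 - 1] < speed[i0] && speed[i0 - 1] > floor_v))) i0 <- i0 - 1
    while (i1 < n && (speed[i1 + 1] > lo ||
                        (speed[i1 + 1] < speed[i1] && speed[i1 + 1] > floor_v))) i1 <- i1 + 1
    idx <- i0:i1
    tibble(
      kind = "saccade",
      onset_ms = tr$t_ms[i0], offset_ms = tr$t_ms[i1] + dt,
      x_deg = x[i1], y_deg = y[i1],
      peak_velocity = max(speed[idx]),
      peak_acceleration = max(abs(accel[idx]))
    )
  })
  res <- dplyr::bind_rows(out)
  # boundary refinement may have joined neighbouring spans
  sp <- merge_spans(res$onset_ms, res$offset_ms, gap = 0)
  if (length(sp$onset) < nrow(res)) {
    keep <- match(sp$onset, res$onset_ms)
    res <- res[keep, ]
    res$offset_ms <- sp$offset
  }
  res
}

#' Detect blinks from the pupil channel
#'
#' Blink spans are samples where the pupil is missing (`NA`/0) or smaller
#' than `rel_thresh` times the trace median, padded by `pad_ms` on each side
#' (pupil size is unreliable just before/after lid closure).
#'
#' @param trace tibble with `t_ms` and `pupil` (and optionally `trial_id`).
#' @param rel_thresh fraction of the median pupil size below which a sample
#'   counts as closed.
#' @param pad_ms guard margin added to each side of a blink span, ms.
#' @return tibble of blink events (`trial_id`, `kind`, `onset_ms`,
#'   `offset_ms`); zero rows when no blink is found.
#' @export
detect_blinks <- function(trace, rel_thresh = 0.1, pad_ms = 50) {
  if (!"pupil" %in% names(trace)) {
    stop("trace has no pupil channel")
  }
  per_trial(trace, function(tr, id) {
    dt <- median(diff(tr$t_ms))
    p <- tr$pupil
    med <- median(p[!is.na(p) & p > 0])
    closed <- is.na(p) | p < rel_thresh * med
    runs <- logical_runs(closed)
    if (length(runs$start) == 0) {
      return(empty_events())
    }
    spans <- merge_spans(pmax(tr$t_ms[1], tr$t_ms[runs$start] - pad_ms),
                         pmin(tr$t_ms[length(p)] + dt, tr$t_ms[runs$end] + dt + pad_ms),
                         gap = 0)
    tibble(kind = "blink", onset_ms = spans$onset, offset_ms = spans$offset,
           x_deg = NA_real_, y_deg = NA_real_,
           peak_velocity = NA_real_, peak_acceleration = NA_real_)
  })
}

#' Segment fixations as the complement of saccades and blinks
#'
#' Fixations are the intervals of a trace not covered by any saccade or blink
#' event; the three kinds tile the trace. Each fixation carries the mean gaze
#' position over its span.
#'
#' @param trace gaze tibble (see [detect_saccades()]).
#' @param saccades,blinks event tibbles from the detectors (either may have
#'   zero rows).
#' @return tibble of fixation events with mean `x_deg`, `y_deg`.
#' @export
segment_fixations <- function(trace, saccades = NULL, blinks = NULL) {
  per_trial(trace, function(tr, id) {
    dt <- median(diff(tr$t_ms))
    t0 <- tr$t_ms[1]
    t1 <- tr$t_ms[nrow(tr)] + dt
    occ <- dplyr::bind_rows(
      if (!is.null(saccades)) filter_trial(saccades, id),
      if (!is.null(blinks)) filter_trial(blinks, id)
    )
    if (is.null(occ) || nrow(occ) == 0) {
      spans <- list(onset = t0, offset = t1)
    } else {
      m <- merge_spans(occ$onset_ms, occ$offset_ms, gap = 0)
      bounds <- sort(unique(c(t0, t1, pmax(t0, pmin(t1, c(m$onset, m$offset))))))
      spans <- list(onset = numeric(0), offset = numeric(0))
      for (i in seq_len(length(bounds) - 1)) {
        mid <- (bounds[i] + bounds[i + 1]) / 2
        inside <- any(m$onset <= mid & mid < m$offset)
        if (!inside && bounds[i + 1] > bounds[i]) {
          spans$onset <- c(spans$onset, bounds[i])
          spans$offset <- c(spans$offset, bounds[i + 1])
        }
      }
    }
    if (length(spans$onset) == 0) {
      return(empty_events())
    }
    dplyr::bind_rows(lapply(seq_along(spans$onset), function(k) {
      idx <- tr$t_ms >= spans$onset[k] & tr$t_ms < spans$offset[k]
      tibble(
        kind = "fixation",
        onset_ms = spans$onset[k], offset_ms = spans$offset[k],
        x_deg = mean(tr$x_deg[idx], na.rm = TRUE),
        y_deg = mean(tr$y_deg[idx], na.rm = TRUE),
        peak_velocity = NA_real_, peak_acceleration = NA_real_
      )
    }))
  })
}

#' Run all three eye-event detectors on a gaze trace
#'
#' Convenience wrapper: blinks, then saccades (blink-masked), then fixations
#' as the complement. The returned events partition each trial.
#'
#' @inheritParams detect_saccades
#' @param ... passed on to [detect_saccades()].
#' @return tibble of events of all three kinds, ordered by trial and onset.
#' @export
detect_eye_events <- function(trace, v_thresh = 30, a_thresh = 8000, ...) {
  blinks <- if ("pupil" %in% names(trace)) detect_blinks(trace) else empty_events()
  saccades <- detect_saccades(trace, v_thresh, a_thresh, blinks = blinks, ...)
  fixations <- segment_fixations(trace, saccades, blinks)
  out <- dplyr::bind_rows(fixations, saccades, blinks)
  if ("trial_id" %in% names(out)) {
    dplyr::arrange(out, .data$trial_id, .data$onset_ms)
  } else {
    dplyr::arrange(out, .data$onset_ms)
  }
}

# --- internals ------------------------------------------------------------

empty_events <- function() {
  tibble(
    kind = character(0), onset_ms = numeric(0), offset_ms = numeric(0),
    x_deg = numeric(0), y_deg = numeric(0),
    peak_velocity = numeric(0), peak_acceleration = numeric(0)
  )
}

# Apply `f(trial_tibble, trial_id)` per trial (or once if no trial column).
per_trial <- function(trace, f) {
  if (!"trial_id" %in% names(trace)) {
    return(f(trace, NA))
  }
  ids <- unique(trace$trial_id)
  dplyr::bind_rows(lapply(ids, function(id) {
    res <- f(trace[trace$trial_id == id, , drop = FALSE], id)
    if (nrow(res) > 0) res$trial_id <- id
    res
  }))
}

filter_trial <- function(events, id) {
  if (is.null(events) || nrow(events) == 0) {
    return(events)
  }
  if ("trial_id" %in% names(events) && !is.na(id)) {
    events[events$trial_id == id, , drop = FALSE]
  } else {
    events
  }
}

approx_fill <- function(t, v) {
  ok <- !is.na(v)
  if (all(ok)) {
    return(v)
  }
  stats::approx(t[ok], v[ok], xout = t, rule = 2)$y
}
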