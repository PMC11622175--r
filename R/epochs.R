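#' Fixation-locked epoch container
#'
#' Holds an `n_epochs x n_channels x n_times` data array together with its
#' time axis (seconds relative to fixation onset), per-channel type tags
#' (`grad`, `mag`, or `synthetic`) and a label tibble with one row per epoch.
#'
#' @param data numeric 3-D array, epochs x channels x times.
#' @param times numeric vector of epoch times, seconds.
#' @param channel_types character vector, one per channel.
#' @param labels tibble with `nrow(labels) == dim(data)[1]`.
#' @return an object of class `epoch_set`.
#' @export
epoch_set <- function(data, times, channel_types, labels) {
  stopifnot(length(dim(data)) == 3, dim(data)[3] == length(times),
            dim(data)[2] == length(channel_types),
            nrow(labels) == dim(data)[1])
  structure(
    list(data = data, times = times, channel_types = channel_types,
         labels = tibble::as_tibble(labels)),
    class = "epoch_set"
  )
}

#' @export
print.epoch_set <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<epoch_set> %d epochs x %d channels x %d samples (%.3f..%.3f s, %g Hz)\n",
    d[1], d[2], d[3], min(x$times), max(x$times),
    round(1 / median(diff(x$times)))
  ))
  cat("labels: ", paste(names(x$labels), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.epoch_set <- function(x) dim(x$data)

#' Subset an epoch set by epoch index
#'
#' @param x an `epoch_set`.
#' @param i integer or logical index over epochs.
#' @param ... unused.
#' @export
`[.epoch_set` <- function(x, i, ...) {
  epoch_set(x$data[i, , , drop = FALSE], x$times, x$channel_types,
            x$labels[i, , drop = FALSE])
}

#' @method tidy epoch_set
#' @export
tidy.epoch_set <- function(x, ...) {
  d <- dim(x$data)
  out <- tidyr::expand_grid(
    epoch = seq_len(d[1]), channel = seq_len(d[2]), time_s = x$times
  )
  # aperm to (time, channel, epoch) so flattening matches the grid ordering
  out$value <- as.vector(aperm(x$data, c(3, 2, 1)))
  out
}

#' Extract cleaned fixation-locked epochs from a continuous recording
#'
#' Epochs are cut at -1..+1 s around each fixation onset, then filtered in
#' four stages, with per-stage counts in the rejection log:
#'
#' 1. `edge` — the window does not fit inside the recording;
#' 2. `duration_filter` — fixation duration below `min_dur_ms` (80 ms) or
#'    above `max_dur_ms` (1,000 ms);
#' 3. `amplitude` — any sample within -1..+1 s exceeds the channel-type
#'    threshold (5,000 fT/cm for gradiometers, 5,000 fT for magnetometers;
#'    unbounded for `synthetic` channels unless a threshold is supplied);
#' 4. `muscle` — the window overlaps an annotated artifact span (see
#'    [annotate_muscle()]), when `artifacts` is given.
#'
#' Surviving epochs are zero-phase low-pass filtered at 200 Hz, decimated to
#' 500 Hz, and cropped to -0.5..+0.5 s (501 samples).
#'
#' @param recording list with `data` (channels x samples), `sfreq`,
#'   `channel_types` (as produced by [simulate_sensor_data()]).
#' @param fixations tibble with `onset_sample` (1-based fixation onset in the
#'   recording) and `duration_ms`; all its columns are carried into the
#'   output labels.
#' @param artifacts optional artifact spans (`onset_ms`, `offset_ms`).
#' @param amplitude_thresholds named vector of per-channel-type rejection
#'   thresholds.
#' @param min_dur_ms,max_dur_ms fixation-duration filter bounds, ms.
#' @param out_sfreq analysis sampling rate after decimation, Hz.
#' @param crop final epoch window, seconds.
#' @return list with `epochs` (an [epoch_set()]) and `rejections` (tibble
#'   `fixation`, `reason`).
#' @export
extract_epochs <- function(recording, fixations, artifacts = NULL,
                           amplitude_thresholds = c(grad = 5000, mag = 5000,
                                                    synthetic = Inf),
                           min_dur_ms = 80, max_dur_ms = 1000,
                           out_sfreq = 500, crop = c(-0.5, 0.5)) {
  sfreq <- recording$sfreq
  if (sfreq %% out_sfreq != 0) {
    stop("recording rate must be an integer multiple of the output rate")
  }
  dec <- sfreq / out_sfreq
  nch <- nrow(recording$data)
  n_samples <- ncol(recording$data)
  half <- sfreq # 1 s in samples
  thr <- amplitude_thresholds[recording$channel_types]
  thr[is.na(thr)] <- Inf

  rej <- tibble(fixation = integer(0), reason = character(0))
  note <- function(i, why) {
    rej <<- dplyr::bind_rows(rej, tibble(fixation = i, reason = why))
  }

  # low-pass prototype (anti-aliasing before decimation)
  bf <- signal::butter(4, (0.4 * out_sfreq) / (sfreq / 2), type = "low")

  kept <- list()
  kept_rows <- integer(0)
  for (i in seq_len(nrow(fixations))) {
    on <- fixations$onset_sample[i]
    if (on - half < 1 || on + half > n_samples) {
      note(i, "edge")
      next
    }
    dur <- fixations$duration_ms[i]
    if (is.na(dur) || dur < min_dur_ms || dur > max_dur_ms) {
      note(i, "duration_filter")
      next
    }
    win <- recording$data[, (on - half):(on + half), drop = FALSE]
    if (any(abs(win) > thr)) {
      note(i, "amplitude")
      next
    }
    if (!is.null(artifacts) && nrow(artifacts) > 0) {
      t0 <- (on - half) / sfreq * 1000
      t1 <- (on + half) / sfreq * 1000
      if (any(artifacts$onset_ms < t1 & artifacts$offset_ms > t0)) {
        note(i, "muscle")
        next
      }
    }
    filt <- t(apply(win, 1, function(ch) signal::filtfilt(bf, ch)))
    kept[[length(kept) + 1]] <- filt[, seq(1, ncol(filt), by = dec), drop = FALSE]
    kept_rows <- c(kept_rows, i)
  }

  times_full <- seq(-1, 1, by = 1 / out_sfreq)
  crop_idx <- which(times_full >= crop[1] - 1e-9 & times_full <= crop[2] + 1e-9)
  nt <- length(crop_idx)
  data <- array(0, dim = c(length(kept), nch, nt))
  for (k in seq_along(kept)) {
    data[k, , ] <- kept[[k]][, crop_idx]
  }

  labels <- fixations[kept_rows, , drop = FALSE]
  labels$epoch_id <- seq_len(nrow(labels))
  list(
    epochs = epoch_set(data, times_full[crop_idx], recording$channel_types, labels),
    rejections = rej
  )
}
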