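#' Annotate muscle artifacts in a continuous recording
#'
#' Muscle activity concentrates above ~100 Hz. The recording is band-pass
#' filtered to 110-140 Hz (zero-phase Butterworth), the envelope taken as a
#' moving RMS over `smooth_ms`, averaged across channels, and z-scored over
#' time (robustly, median/MAD, so bursts do not inflate their own
#' yardstick); spans where the z-score exceeds `z_thresh` (10 by default)
#' are returned as artifact annotations for epoch rejection.
#'
#' @param recording list with `data` (channels x samples) and `sfreq`, or a
#'   plain matrix plus `sfreq` argument.
#' @param sfreq sampling rate, Hz, when `recording` is a matrix. Must exceed
#'   280 Hz (twice the upper band edge).
#' @param band numeric length-2 band edges, Hz.
#' @param z_thresh z-score threshold.
#' @param smooth_ms RMS envelope window, ms.
#' @param pad_ms padding added around supra-threshold spans, ms.
#' @return tibble of artifact spans: `onset_ms`, `offset_ms`, `peak_z`.
#' @export
annotate_muscle <- function(recording, sfreq = NULL, band = c(110, 140),
                            z_thresh = 10, smooth_ms = 20, pad_ms = 100) {
  if (is.list(recording)) {
    data <- recording$data
    sfreq <- recording$sfreq
  } else {
    data <- recording
    if (is.null(sfreq)) stop("sfreq required when recording is a matrix")
  }
  if (sfreq <= 2 * band[2]) {
    stop("sampling rate ", sfreq, " Hz too low for the ", band[1], "-",
         band[2], " Hz band")
  }
  bf <- signal::butter(4, band / (sfreq / 2), type = "pass")
  win <- max(3, round(smooth_ms / 1000 * sfreq))
  kern <- rep(1 / win, win)

  env <- rep(0, ncol(data))
  for (ch in seq_len(nrow(data))) {
    bp <- signal::filtfilt(bf, data[ch, ])
    env <- env + as.numeric(stats::filter(bp^2, kern, sides = 2, circular = TRUE))
  }
  env <- sqrt(env / nrow(data))
  # robust z-score (median/MAD) so the artifacts themselves do not inflate
  # the scale estimate
  z <- (env - median(env)) / stats::mad(env)

  runs <- logical_runs(z > z_thresh)
  if (length(runs$start) == 0) {
    return(tibble(onset_ms = numeric(0), offset_ms = numeric(0), peak_z = numeric(0)))
  }
  spans <- merge_spans(pmax(0, (runs$start - 1) / sfreq * 1000 - pad_ms),
                       pmin(ncol(data) / sfreq * 1000, runs$end / sfreq * 1000 + pad_ms),
                       gap = 0)
  peak <- vapply(seq_along(spans$onset), function(k) {
    i0 <- max(1, floor(spans$onset[k] / 1000 * sfreq))
    i1 <- min(length(z), ceiling(spans$offset[k] / 1000 * sfreq))
    max(z[i0:i1])
  }, numeric(1))
  tibble(onset_ms = spans$onset, offset_ms = spans$offset, peak_z = peak)
}
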