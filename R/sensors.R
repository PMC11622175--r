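class_levels <- function(dimension) {
  switch(dimension,
    color = c("color", "gray"),
    category = c("animal", "food", "object"),
    stop("unknown dimension: ", dimension)
  )
}

# Unit-norm random spatial pattern per (role, dimension, class), fixed per
# participant. Distinct classes get independent Gaussian directions, which
# are non-collinear with probability one.
draw_patterns <- function(n_channels, roles = c("foveal", "upcoming", "past"),
                          dimensions = c("color", "category")) {
  pats <- list()
  for (r in roles) {
    for (d in dimensions) {
      for (cl in class_levels(d)) {
        v <- rnorm(n_channels)
        pats[[paste(r, d, cl, sep = ".")]] <- v / sqrt(sum(v^2))
      }
    }
  }
  pats
}

#' Simulate a continuous multichannel sensor recording
#'
#' Forward model: the recording is the sum, over fixations and applicable
#' injected effects, of a class-specific spatial pattern times a temporal
#' kernel placed `latency_ms` after fixation onset, plus Gaussian noise
#' (optionally mixed through a random channel-mixing matrix so the noise is
#' spatially correlated — the property that matters for multivariate
#' decoding). Optionally, high-frequency (125 Hz) artifact bursts are
#' injected at `cfg$artifact_rate` per minute and returned as ground truth.
#'
#' @param fixations tibble with one row per fixation: `onset_sample`
#'   (1-based index into the recording) and, for every role/dimension an
#'   effect may target, columns `<role>_color` / `<role>_category` holding
#'   the class (or `NA` when the role does not apply).
#' @param n_samples length of the recording in samples.
#' @param cfg a [synth_config()] (channels, sampling rate, effects, noise).
#' @param patterns optional pattern set (from an earlier call, to keep
#'   patterns fixed across blocks of one participant); drawn fresh if `NULL`.
#' @param seed optional seed.
#' @return list with `data` (channels x samples matrix), `sfreq`,
#'   `channel_types` (all `"synthetic"`), `patterns`, and `artifacts`
#'   (tibble of injected artifact spans, ms).
#' @export
simulate_sensor_data <- function(fixations, n_samples, cfg = synth_config(),
                                 patterns = NULL, seed = NULL) {
  if (cfg$n_channels < 2) {
    stop("at least 2 channels are needed for spatial patterns")
  }
  with_seed(seed, {
    nch <- cfg$n_channels
    sfreq <- cfg$sfreq_meg
    if (is.null(patterns)) {
      patterns <- draw_patterns(nch)
    }

    data <- matrix(0, nch, n_samples)
    for (e in cfg$effects) {
      if (e$amplitude == 0) next
      col <- paste0(e$role, "_", e$dimension)
      if (!col %in% names(fixations)) next
      half_ms <- if (e$sustained) e$width_ms + 80 else 3 * e$width_ms
      k0 <- floor((e$latency_ms - (if (e$sustained) 80 else half_ms)) * sfreq / 1000)
      k1 <- ceiling((e$latency_ms + half_ms) * sfreq / 1000)
      rel_ms <- (k0:k1) * 1000 / sfreq
      kern <- e$amplitude * temporal_kernel(rel_ms, e$latency_ms, e$width_ms, e$sustained)
      for (i in seq_len(nrow(fixations))) {
        cl <- fixations[[col]][i]
        if (is.na(cl)) next
        pat <- patterns[[paste(e$role, e$dimension, cl, sep = ".")]]
        idx <- fixations$onset_sample[i] + (k0:k1)
        ok <- idx >= 1 & idx <= n_samples
        if (!any(ok)) next
        data[, idx[ok]] <- data[, idx[ok]] + pat %o% kern[ok]
      }
    }

    if (cfg$noise_sd > 0) {
      noise <- matrix(rnorm(nch * n_samples, sd = cfg$noise_sd), nch, n_samples)
      if (cfg$spatial_noise_mixing) {
        mix <- matrix(rnorm(nch * nch, sd = 1 / sqrt(nch)), nch, nch)
        noise <- mix %*% noise
      }
      data <- data + noise
    }

    artifacts <- tibble(onset_ms = numeric(0), offset_ms = numeric(0))
    if (cfg$artifact_rate > 0) {
      n_art <- rbinom(1, max(1, round(n_samples / sfreq / 60 * cfg$artifact_rate * 3)),
                      prob = 1 / 3)
      if (n_art > 0) {
        for (a in seq_len(n_art)) {
          dur <- round(runif(1, 0.08, 0.15) * sfreq)
          on <- sample.int(n_samples - dur, 1)
          tt <- seq_len(dur) / sfreq
          burst <- sin(2 * pi * 125 * tt) * sin(pi * seq_len(dur) / dur)^2
          wch <- rnorm(nch, sd = 1) * (20 * max(cfg$noise_sd, 0.1))
          data[, on + seq_len(dur)] <- data[, on + seq_len(dur)] + wch %o% burst
          artifacts <- dplyr::bind_rows(artifacts, tibble(
            onset_ms = on / sfreq * 1000, offset_ms = (on + dur) / sfreq * 1000
          ))
        }
      }
    }

    list(data = data, sfreq = sfreq,
         channel_types = rep("synthetic", nch),
         patterns = patterns, artifacts = artifacts)
  })
}

#' Simulate fixation-locked epochs directly
#'
#' Generates an [epoch_set()] without going through continuous recordings:
#' balanced class labels, per-participant spatial patterns, injected effects
#' for one fixation role, and spatially mixed Gaussian noise. This is the
#' generator used for decoding-level calibration (chance level, latency
#' recovery, generalization morphology) where the eye-movement machinery is
#' irrelevant.
#'
#' @param n_epochs,n_channels counts.
#' @param effects list of [effect_spec()]; only those whose `role` matches
#'   `role` are injected.
#' @param role the fixation role these epochs represent.
#' @param noise_sd Gaussian noise SD.
#' @param spatial_noise_mixing mix noise across channels.
#' @param sfreq,tmin,tmax epoch time axis (defaults: 500 Hz, -0.5..+0.5 s).
#' @param base_correct_rate probability an epoch belongs to a correct trial.
#' @param latency_jitter_ms SD of a per-epoch Gaussian jitter of the effect
#'   latency, emulating trial-to-trial variability in activation delays.
#' @param seed optional seed.
#' @return an [epoch_set()].
#' @examples
#' es <- simulate_epochs(40, 8, effects = default_effects(2), seed = 1)
#' es
#' @export
simulate_epochs <- function(n_epochs, n_channels, effects = default_effects(),
                            role = "foveal", noise_sd = 1,
                            spatial_noise_mixing = TRUE,
                            sfreq = 500, tmin = -0.5, tmax = 0.5,
                            base_correct_rate = 0.668,
                            latency_jitter_ms = 0, seed = NULL) {
  with_seed(seed, {
    times <- seq(tmin, tmax, by = 1 / sfreq)
    nt <- length(times)
    labels <- tibble(
      epoch_id = seq_len(n_epochs),
      color_scale = sample(rep_len(class_levels("color"), n_epochs)),
      category = sample(rep_len(class_levels("category"), n_epochs)),
      outcome = ifelse(runif(n_epochs) < base_correct_rate, "correct", "incorrect")
    )
    patterns <- draw_patterns(n_channels, roles = role)

    data <- array(rnorm(n_epochs * n_channels * nt, sd = noise_sd),
                  dim = c(n_epochs, n_channels, nt))
    if (spatial_noise_mixing && noise_sd > 0) {
      mix <- matrix(rnorm(n_channels^2, sd = 1 / sqrt(n_channels)), n_channels, n_channels)
      for (i in seq_len(n_epochs)) {
        data[i, , ] <- mix %*% data[i, , ]
      }
    }

    t_ms <- times * 1000
    for (e in effects) {
      if (e$role != role || e$amplitude == 0) next
      jit <- if (latency_jitter_ms > 0) rnorm(n_epochs, 0, latency_jitter_ms) else numeric(n_epochs)
      cl_col <- if (e$dimension == "color") labels$color_scale else labels$category
      for (cl in class_levels(e$dimension)) {
        pat <- patterns[[paste(role, e$dimension, cl, sep = ".")]]
        for (i in which(cl_col == cl)) {
          kern <- e$amplitude *
            temporal_kernel(t_ms, e$latency_ms + jit[i], e$width_ms, e$sustained)
          data[i, , ] <- data[i, , ] + pat %o% kern
        }
      }
    }

    epoch_set(data, times, channel_types = rep("synthetic", n_channels),
              labels = labels)
  })
}
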