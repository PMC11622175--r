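#' Specify an injected decodable effect
#'
#' An effect is a class-specific evoked response tied to one fixation role and
#' one stimulus dimension: at `latency_ms` after fixation onset, each class of
#' that dimension evokes its own fixed spatial pattern across channels, scaled
#' by a temporal kernel. Transient effects use a Gaussian bump of FWHM
#' `width_ms`; sustained effects use a smoothed plateau of length `width_ms`.
#' Transient kernels produce diagonal temporal-generalization patterns,
#' sustained kernels square ones.
#'
#' @param role which fixation role carries the effect: `"foveal"`,
#'   `"upcoming"`, or `"past"`.
#' @param dimension the decoded stimulus dimension, `"color"` or `"category"`.
#' @param latency_ms peak (transient) or onset (sustained) latency relative to
#'   fixation onset, ms.
#' @param width_ms FWHM of the transient bump, or plateau length of the
#'   sustained response, ms.
#' @param amplitude signal amplitude in sensor units; 0 disables the effect.
#' @param sustained logical; plateau instead of bump.
#' @return an `effect_spec` list.
#' @export
effect_spec <- function(role = c("foveal", "upcoming", "past"),
                        dimension = c("color", "category"),
                        latency_ms, width_ms = 60, amplitude = 1,
                        sustained = FALSE) {
  role <- match.arg(role)
  dimension <- match.arg(dimension)
  stopifnot(is.numeric(latency_ms), length(latency_ms) == 1L,
            amplitude >= 0, width_ms > 0)
  structure(
    list(role = role, dimension = dimension, latency_ms = latency_ms,
         width_ms = width_ms, amplitude = amplitude, sustained = sustained),
    class = "effect_spec"
  )
}

#' Default injected effects
#'
#' Six effects at the group peak latencies reported for free visual
#' exploration: foveal color at 100 ms and category at 145 ms, upcoming
#' parafoveal color at 112 ms and category at 165 ms, past parafoveal color at
#' 88 ms and category at 170 ms. The foveal category response is sustained
#' (square temporal generalization); all others are transient.
#'
#' @param amplitude common amplitude applied to all six effects.
#' @return list of [effect_spec()] objects.
#' @export
default_effects <- function(amplitude = 1) {
  list(
    effect_spec("foveal", "color", latency_ms = 100, amplitude = amplitude),
    effect_spec("foveal", "category", latency_ms = 145, width_ms = 200,
                amplitude = amplitude, sustained = TRUE),
    effect_spec("upcoming", "color", latency_ms = 112, amplitude = amplitude),
    effect_spec("upcoming", "category", latency_ms = 165, amplitude = amplitude),
    effect_spec("past", "color", latency_ms = 88, amplitude = amplitude),
    effect_spec("past", "category", latency_ms = 170, amplitude = amplitude)
  )
}

#' Configuration of a synthetic free-viewing study
#'
#' Defaults reproduce the published study conditions: 36 participants, 10
#' blocks of 30 trials (300 trials), 4 s trials of seven images, gaze and
#' sensors sampled at 1,000 Hz, mean fixation duration 240 +/- 36 ms, 3.26
#' saccades per second, and effects injected at the reported group peak
#' latencies.
#'
#' @param n_participants,n_trials,n_channels counts (all >= 1).
#' @param sfreq_gaze,sfreq_meg sampling rates, Hz. `sfreq_meg` must be
#'   divisible by 500 so epochs can be decimated to the 500 Hz analysis rate.
#' @param trial_duration_s trial length, seconds.
#' @param mean_fixation_ms,fixation_sd_ms fixation-duration distribution
#'   (gamma, matched mean/SD), ms. Mean must exceed 80 ms, the lower epoch
#'   duration filter.
#' @param saccade_rate_hz nominal saccade rate, 1/s, governing the scheduled
#'   saccade durations (`1000 / rate - mean_fixation_ms` ms on average).
#' @param landing_jitter_deg SD of the fixation landing-position jitter around
#'   image centers, degrees.
#' @param pos_noise_deg SD of within-fixation gaze tremor, degrees.
#' @param blink_prob probability that a trial contains one blink.
#' @param effects list of [effect_spec()]; `default_effects()` by default.
#' @param noise_sd sensor noise SD, signal units.
#' @param spatial_noise_mixing mix the sensor noise through a random channel
#'   mixing matrix, giving spatially correlated noise.
#' @param base_correct_rate baseline probability of a correct behavioral
#'   response (0.668, the reported group mean).
#' @param accuracy_coupling logistic slope linking target-image fixation count
#'   to response accuracy; 0 decouples them.
#' @param artifact_rate expected number of injected high-frequency (muscle
#'   like) artifact bursts per minute of recording; 0 for none.
#' @param seed integer seed making the whole study reproducible.
#' @return a `synth_config` list, validated.
#' @export
synth_config <- function(n_participants = 36, n_trials = 300, n_channels = 306,
                         sfreq_gaze = 1000, sfreq_meg = 1000,
                         trial_duration_s = 4.0,
                         mean_fixation_ms = 240, fixation_sd_ms = 36,
                         saccade_rate_hz = 3.26,
                         landing_jitter_deg = 0.5, pos_noise_deg = 0.02,
                         blink_prob = 0,
                         effects = default_effects(),
                         noise_sd = 1, spatial_noise_mixing = TRUE,
                         base_correct_rate = 0.668, accuracy_coupling = 0.8,
                         artifact_rate = 0,
                         seed = 1L) {
  stopifnot(
    n_participants >= 1, n_trials >= 1, n_channels >= 1,
    sfreq_meg %% 500 == 0,
    mean_fixation_ms > 80,
    trial_duration_s > 0, fixation_sd_ms > 0, saccade_rate_hz >= 0,
    noise_sd >= 0, base_correct_rate > 0, base_correct_rate < 1
  )
  if (mean_fixation_ms > trial_duration_s * 1000) {
    stop("degenerate config: mean fixation duration exceeds the trial duration")
  }
  epoch_lim <- 500 # ms, half-width of the raw epoch window
  for (e in effects) {
    stopifnot(inherits(e, "effect_spec"))
    if (abs(e$latency_ms) > epoch_lim) {
      stop("effect latency ", e$latency_ms, " ms lies outside the epoch window")
    }
  }
  structure(
    list(
      n_participants = as.integer(n_participants),
      n_trials = as.integer(n_trials),
      n_channels = as.integer(n_channels),
      sfreq_gaze = sfreq_gaze, sfreq_meg = sfreq_meg,
      trial_duration_s = trial_duration_s,
      mean_fixation_ms = mean_fixation_ms, fixation_sd_ms = fixation_sd_ms,
      saccade_rate_hz = saccade_rate_hz,
      landing_jitter_deg = landing_jitter_deg, pos_noise_deg = pos_noise_deg,
      blink_prob = blink_prob,
      effects = effects,
      noise_sd = noise_sd, spatial_noise_mixing = spatial_noise_mixing,
      base_correct_rate = base_correct_rate,
      accuracy_coupling = accuracy_coupling,
      artifact_rate = artifact_rate,
      seed = as.integer(seed)
    ),
    class = "synth_config"
  )
}
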