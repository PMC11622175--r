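#' Simulate a complete multi-participant free-viewing study
#'
#' Generates, for every participant: per-trial layouts, scan paths and gaze
#' traces, a continuous sensor recording with class-specific evoked
#' responses injected at the configured latencies (the forward model uses
#' the *true* scan path roles: the class of the currently fixated, next and
#' previous image at each fixation), and behavioral responses coupled to
#' target-image fixations. Trials are separated by 750 ms gaps and the
#' recording is padded by 1.5 s at both ends so all fixation epochs fit.
#' Everything is reproducible from `cfg$seed`.
#'
#' @param cfg a [synth_config()].
#' @param participants optional subset of participant indices to generate.
#' @return a `simulated_study` list: `cfg` and `participants`, each with
#'   `layouts`, `gaze`, `events` (ground-truth event list), `fixations`
#'   (ground-truth fixation table with role classes and `onset_sample`),
#'   `recording`, `behavior`, `patterns`.
#' @examples
#' \donttest{
#' study <- simulate_study(synth_config(n_participants = 1, n_trials = 3,
#'                                      n_channels = 6))
#' }
#' @export
simulate_study <- function(cfg = synth_config(), participants = NULL) {
  participants <- participants %||% seq_len(cfg$n_participants)
  sfreq <- cfg$sfreq_meg
  trial_samp <- round(cfg$trial_duration_s * sfreq)
  gap_samp <- round(0.75 * sfreq)
  pad_samp <- round(1.5 * sfreq)
  n_samples <- cfg$n_trials * (trial_samp + gap_samp) + 2 * pad_samp

  out <- lapply(participants, function(p) {
    pseed <- derive_seed(cfg$seed, p)
    layouts <- dplyr::bind_rows(lapply(seq_len(cfg$n_trials), function(t) {
      lay <- make_layout(seed = derive_seed(pseed, t))
      lay$trial_id <- t
      lay
    }))

    gaze <- list()
    events <- list()
    fixrows <- list()
    for (t in seq_len(cfg$n_trials)) {
      lay <- layouts[layouts$trial_id == t, ]
      sp <- simulate_scanpath(lay, cfg, seed = derive_seed(pseed, 10000 + t))
      sp$trace$trial_id <- t
      sp$events$trial_id <- t
      gaze[[t]] <- sp$trace
      events[[t]] <- sp$events

      fx <- sp$events[sp$events$kind == "fixation", ]
      m <- nrow(fx)
      slot_of <- function(s) ifelse(is.na(s), NA_integer_, s)
      cls <- function(s, what) {
        ifelse(is.na(s), NA_character_,
               lay[[what]][match(s, lay$slot_id)])
      }
      s_cur <- slot_of(fx$slot_id)
      s_nxt <- c(s_cur[-1], NA)
      s_prv <- c(NA, s_cur[-m])
      trial_onset <- pad_samp + (t - 1) * (trial_samp + gap_samp)
      fixrows[[t]] <- tibble(
        trial_id = t,
        fixation_index = seq_len(m),
        onset_ms = fx$onset_ms, offset_ms = fx$offset_ms,
        duration_ms = fx$offset_ms - fx$onset_ms,
        x_deg = fx$x_deg, y_deg = fx$y_deg,
        slot_id = s_cur,
        onset_sample = trial_onset + round(fx$onset_ms / 1000 * sfreq) + 1L,
        foveal_color = cls(s_cur, "color_scale"),
        foveal_category = cls(s_cur, "category"),
        upcoming_color = cls(s_nxt, "color_scale"),
        upcoming_category = cls(s_nxt, "category"),
        past_color = cls(s_prv, "color_scale"),
        past_category = cls(s_prv, "category")
      )
    }
    fixations <- dplyr::bind_rows(fixrows)

    recording <- simulate_sensor_data(fixations, n_samples, cfg,
                                      seed = derive_seed(pseed, 777))

    target_slots <- layouts |>
      filter(.data$is_target) |>
      select("trial_id", target_slot = "slot_id")
    counts <- fixations |>
      dplyr::left_join(target_slots, by = "trial_id") |>
      group_by(.data$trial_id) |>
      summarise(target_fixations = sum(!is.na(.data$slot_id) &
                                         .data$slot_id == .data$target_slot[1]),
                .groups = "drop")
    behavior <- simulate_behavior(counts, cfg, seed = derive_seed(pseed, 888))
    behavior <- dplyr::left_join(behavior, target_slots, by = "trial_id")

    list(
      participant = p,
      layouts = layouts,
      gaze = dplyr::bind_rows(gaze),
      events = dplyr::bind_rows(events),
      fixations = fixations,
      recording = recording,
      behavior = behavior
    )
  })

  structure(
    list(cfg = cfg, participants = out,
         trial_onsets = pad_samp + (seq_len(cfg$n_trials) - 1) * (trial_samp + gap_samp)),
    class = "simulated_study"
  )
}

#' @export
print.simulated_study <- function(x, ...) {
  cat(sprintf("<simulated_study> %d participant(s), %d trials, %d channels\n",
              length(x$participants), x$cfg$n_trials, x$cfg$n_channels))
  invisible(x)
}

#' Write a simulated study to disk
#'
#' One subdirectory per participant holding `gaze.tsv` (trial_id, t_ms,
#' x_deg, y_deg, pupil), `layouts.tsv`, `events.tsv` (ground-truth events),
#' `behavior.tsv`, `ground_truth.json` (injected effects and artifact
#' spans), and `recording.rds` (the channels x samples array with rate and
#' channel types).
#'
#' @param study a `simulated_study`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (p in study$participants) {
    pd <- file.path(dir, sprintf("sub-%02d", p$participant))
    dir.create(pd, showWarnings = FALSE)
    write_tsv_(p$gaze, file.path(pd, "gaze.tsv"))
    write_tsv_(p$layouts, file.path(pd, "layouts.tsv"))
    write_tsv_(p$events, file.path(pd, "events.tsv"))
    write_tsv_(p$behavior, file.path(pd, "behavior.tsv"))
    saveRDS(p$recording[c("data", "sfreq", "channel_types")],
            file.path(pd, "recording.rds"))
    jsonlite::write_json(
      list(
        effects = lapply(study$cfg$effects, unclass),
        artifacts = p$recording$artifacts,
        seed = study$cfg$seed
      ),
      file.path(pd, "ground_truth.json"),
      auto_unbox = TRUE, digits = NA
    )
  }
  invisible(dir)
}
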