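#' Simulate behavioral responses from scan paths
#'
#' One response per trial of a change-detection task: the probability of a
#' correct response rises monotonically (logistic link) with the number of
#' fixations the scan path made on the target image, around a configurable
#' base rate (0.668 by default, the reported group mean). Reaction times are
#' log-normal, slower on incorrect trials (medians ~2.8 s correct vs ~4.0 s
#' incorrect).
#'
#' @param fixation_counts tibble with `trial_id` and `target_fixations`
#'   (fixation count on the target image per trial).
#' @param cfg a [synth_config()] (uses `base_correct_rate`,
#'   `accuracy_coupling`).
#' @param seed optional seed.
#' @return tibble: `trial_id`, `target_fixations`, `correct` (logical),
#'   `rt_ms`.
#' @export
simulate_behavior <- function(fixation_counts, cfg = synth_config(),
                              seed = NULL) {
  with_seed(seed, {
    k <- fixation_counts$target_fixations
    eta <- qlogis(cfg$base_correct_rate) +
      cfg$accuracy_coupling * (k - mean(k))
    correct <- runif(length(k)) < plogis(eta)
    rt <- ifelse(correct,
                 rlnorm(length(k), log(2813), 0.22),
                 rlnorm(length(k), log(4010), 0.24))
    tibble(
      trial_id = fixation_counts$trial_id,
      target_fixations = k,
      correct = correct,
      rt_ms = rt
    )
  })
}

#' Summarize behavioral and eye-movement metrics by outcome
#'
#' Computes, per participant and outcome (correct/incorrect): percent
#' correct, median and mean reaction times, saccade count and duration per
#' trial, fixation count and duration per trial, and the fixation count and
#' duration on the target image — then contrasts each metric between
#' outcomes across participants with two-tailed paired t tests
#' ([paired_ttest()]). Contrasts that cannot be formed (an outcome split
#' with fewer than 2 participants with both outcomes) are flagged as
#' undefined rather than dropped.
#'
#' @param events tibble of eye events with `participant`, `trial_id`,
#'   `kind`, `onset_ms`, `offset_ms` and (for fixations) `slot_id`.
#' @param responses tibble with `participant`, `trial_id`, `correct`,
#'   `rt_ms` and `target_slot` (slot id of the target image).
#' @return list with `summary` (tibble per participant x outcome) and
#'   `contrasts` (tibble per metric with t, p, Cohen's d, CI95; `NA` row
#'   flagged `undefined` when not computable).
#' @export
summarize_behavior <- function(events, responses) {
  if (!"participant" %in% names(events)) events$participant <- 1L
  if (!"participant" %in% names(responses)) responses$participant <- 1L

  ev <- dplyr::left_join(
    events,
    responses[, c("participant", "trial_id", "correct", "target_slot")],
    by = c("participant", "trial_id")
  )
  per_trial <- ev |>
    group_by(.data$participant, .data$trial_id, .data$correct) |>
    summarise(
      n_saccades = sum(.data$kind == "saccade"),
      saccade_dur = mean((.data$offset_ms - .data$onset_ms)[.data$kind == "saccade"]),
      n_fixations = sum(.data$kind == "fixation"),
      fixation_dur = mean((.data$offset_ms - .data$onset_ms)[.data$kind == "fixation"]),
      n_target_fix = sum(.data$kind == "fixation" &
                           !is.na(.data$slot_id) &
                           .data$slot_id == .data$target_slot[1]),
      target_fix_dur = mean((.data$offset_ms - .data$onset_ms)[
        .data$kind == "fixation" & !is.na(.data$slot_id) &
          .data$slot_id == .data$target_slot[1]]),
      .groups = "drop"
    )

  rt <- responses |>
    group_by(.data$participant, .data$correct) |>
    summarise(rt_median_ms = median(.data$rt_ms),
              rt_mean_ms = mean(.data$rt_ms), .groups = "drop")

  summary <- per_trial |>
    group_by(.data$participant, .data$correct) |>
    summarise(dplyr::across(c("n_saccades", "saccade_dur", "n_fixations",
                              "fixation_dur", "n_target_fix", "target_fix_dur"),
                            ~ mean(.x, na.rm = TRUE)),
              n_trials = dplyr::n(), .groups = "drop") |>
    dplyr::left_join(rt, by = c("participant", "correct")) |>
    mutate(outcome = ifelse(.data$correct, "correct", "incorrect")) |>
    select(-"correct")

  pc <- responses |>
    group_by(.data$participant) |>
    summarise(percent_correct = 100 * mean(.data$correct), .groups = "drop")
  summary <- dplyr::left_join(summary, pc, by = "participant")

  metrics <- c("rt_median_ms", "rt_mean_ms", "n_saccades", "saccade_dur",
               "n_fixations", "fixation_dur", "n_target_fix", "target_fix_dur")
  contrasts <- dplyr::bind_rows(lapply(metrics, function(mname) {
    w <- tidyr::pivot_wider(summary[, c("participant", "outcome", mname)],
                            names_from = "outcome",
                            values_from = dplyr::all_of(mname))
    if (!all(c("correct", "incorrect") %in% names(w))) {
      return(tibble(metric = mname, undefined = TRUE))
    }
    ok <- complete.cases(w$correct, w$incorrect)
    if (sum(ok) < 3 || sd(w$correct[ok] - w$incorrect[ok]) == 0) {
      return(tibble(metric = mname, undefined = TRUE))
    }
    res <- paired_ttest(w$correct[ok], w$incorrect[ok])
    res$metric <- mname
    res$undefined <- FALSE
    res
  }))

  list(summary = summary, contrasts = contrasts)
}
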