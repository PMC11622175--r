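#' Label fixations with foveal/upcoming/past/remaining condition roles
#'
#' For every image fixation in a trial, derives the four analysis roles with
#' their exclusion rules:
#'
#' * **foveal** — the currently fixated image; excluded if the image was
#'   already visited earlier in the trial (`revisited`).
#' * **upcoming** — the image fixated next; excluded when there is no next
#'   image fixation (`none_available`), when its eccentricity from the current
#'   gaze position falls outside the parafoveal band (`out_of_band`), when it
#'   was already visited (`revisited`), or when it shares its color scale
#'   *or* its category with the foveal image (`feature_match` — e.g. with a
#'   grayscale animal in the fovea, any grayscale image and any animal are
#'   discarded, limiting contamination by foveal processing).
#' * **past** — the image fixated just before, same rules (revisits judged
#'   against fixations before the previous one).
#' * **remaining** — one image that is neither the previous nor the next,
#'   in-band and feature-mismatched; if several qualify one is chosen
#'   uniformly at random (seeded).
#'
#' Eccentricity is the distance from the current fixation's gaze position to
#' the candidate image center; the parafoveal band is `band` degrees
#' (2-5 deg by default; images beyond it are peripheral and never analyzed).
#' Exclusion reasons are reported with precedence `none_available` >
#' `out_of_band` > `revisited` > `feature_match`.
#'
#' @param fixations tibble of image fixations in time order, with columns
#'   `trial_id`, `onset_ms`, `offset_ms`, `x_deg`, `y_deg` and `slot_id`
#'   (`NA` for background fixations, which are carried in the sequence but
#'   not analyzed).
#' @param layouts a single `trial_layout`, or a tibble of layouts with a
#'   `trial_id` column.
#' @param band numeric length-2, parafoveal eccentricity band in degrees.
#' @param seed seed for the random choice among remaining candidates.
#' @return tibble with one row per analyzed (image) fixation: the fixation
#'   keys plus, for each role `r` in foveal/upcoming/past/remaining,
#'   `r_slot`, `r_color`, `r_category`, `r_reason` (`"none"` when labeled;
#'   slot/color/category are `NA` when excluded).
#' @export
label_roles <- function(fixations, layouts, band = c(2, 5), seed = NULL) {
  with_seed(seed, {
    if (!"trial_id" %in% names(fixations)) {
      fixations$trial_id <- 1L
    }
    one_layout <- !("trial_id" %in% names(layouts))
    out <- lapply(unique(fixations$trial_id), function(id) {
      fx <- fixations[fixations$trial_id == id, , drop = FALSE]
      fx <- fx[order(fx$onset_ms), , drop = FALSE]
      lay <- if (one_layout) layouts else layouts[layouts$trial_id == id, , drop = FALSE]
      .label_roles_trial(fx, lay, band)
    })
    dplyr::bind_rows(out)
  })
}

.label_roles_trial <- function(fx, lay, band) {
  n <- nrow(fx)
  slots <- fx$slot_id
  slot_color <- setNames(lay$color_scale, lay$slot_id)
  slot_cat <- setNames(lay$category, lay$slot_id)
  slot_x <- setNames(lay$x_deg, lay$slot_id)
  slot_y <- setNames(lay$y_deg, lay$slot_id)

  rows <- lapply(seq_len(n), function(i) {
    if (is.na(slots[i])) {
      return(NULL) # background fixations are not analyzed
    }
    gx <- fx$x_deg[i]
    gy <- fx$y_deg[i]
    fov_slot <- slots[i]
    fov_color <- slot_color[[as.character(fov_slot)]]
    fov_cat <- slot_cat[[as.character(fov_slot)]]

    ecc <- function(s) {
      sqrt((slot_x[[as.character(s)]] - gx)^2 + (slot_y[[as.character(s)]] - gy)^2)
    }
    feature_clash <- function(s) {
      slot_color[[as.character(s)]] == fov_color ||
        slot_cat[[as.character(s)]] == fov_cat
    }
    # parafoveal candidate under the full rule set; `visited_before` is the
    # set of slots fixated before the candidate's own fixation
    judge <- function(s, visited_before) {
      if (is.na(s)) {
        return(list(slot = NA_integer_, reason = "none_available"))
      }
      e <- ecc(s)
      if (e < band[1] || e > band[2]) {
        return(list(slot = NA_integer_, reason = "out_of_band"))
      }
      if (s %in% visited_before) {
        return(list(slot = NA_integer_, reason = "revisited"))
      }
      if (feature_clash(s)) {
        return(list(slot = NA_integer_, reason = "feature_match"))
      }
      list(slot = s, reason = "none")
    }

    fov_reason <- if (fov_slot %in% slots[seq_len(i - 1)]) "revisited" else "none"

    up_slot <- if (i < n) slots[i + 1] else NA_integer_
    up <- judge(up_slot, visited_before = slots[seq_len(i)])

    past_slot <- if (i > 1) slots[i - 1] else NA_integer_
    past <- judge(past_slot, visited_before = if (i > 2) slots[seq_len(i - 2)] else integer(0))

    rem_pool <- setdiff(lay$slot_id, c(fov_slot, up_slot, past_slot))
    rem_ok <- rem_pool[vapply(rem_pool, function(s) {
      e <- ecc(s)
      e >= band[1] && e <= band[2] && !feature_clash(s)
    }, logical(1))]
    if (length(rem_ok) == 0) {
      rem <- list(slot = NA_integer_, reason = "none_available")
    } else {
      pick <- if (length(rem_ok) == 1) rem_ok else sample(rem_ok, 1)
      rem <- list(slot = pick, reason = "none")
    }

    lab <- function(role, slot, reason) {
      out <- list(slot, reason)
      names(out) <- paste0(role, c("_slot", "_reason"))
      if (is.na(slot)) {
        out[[paste0(role, "_color")]] <- NA_character_
        out[[paste0(role, "_category")]] <- NA_character_
      } else {
        out[[paste0(role, "_color")]] <- slot_color[[as.character(slot)]]
        out[[paste0(role, "_category")]] <- slot_cat[[as.character(slot)]]
      }
      out
    }

    tibble::as_tibble(c(
      list(trial_id = fx$trial_id[i], fixation_index = i,
           onset_ms = fx$onset_ms[i], offset_ms = fx$offset_ms[i],
           duration_ms = fx$offset_ms[i] - fx$onset_ms[i],
           x_deg = gx, y_deg = gy),
      lab("foveal", if (fov_reason == "none") fov_slot else NA_integer_, fov_reason),
      lab("upcoming", up$slot, up$reason),
      lab("past", past$slot, past$reason),
      lab("remaining", rem$slot, rem$reason)
    ))
  })
  dplyr::bind_rows(rows)
}
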