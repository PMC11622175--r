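# A layout in the standard geometry with known labels, for rule examples:
# slot 0 center; ring slots at 0..300 deg.
fixed_layout <- function(colors, cats) {
  lay <- make_layout(seed = 1)
  lay$color_scale <- colors
  lay$category <- cats
  lay
}

fx_row <- function(slot, lay, onset, x = NULL, y = NULL) {
  tibble::tibble(
    trial_id = 1,
    onset_ms = onset, offset_ms = onset + 200,
    x_deg = x %||% lay$x_deg[lay$slot_id == slot],
    y_deg = y %||% lay$y_deg[lay$slot_id == slot],
    slot_id = slot
  )
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("parafoveal candidates sharing a feature with the fovea are discarded", {
  # foveal = gray animal at center; upcoming = gray food at 4 deg:
  # shares the gray scale -> feature_match
  lay <- fixed_layout(
    colors = c("gray", "gray", "color", "color", "gray", "color", "gray"),
    cats = c("animal", "food", "food", "object", "object", "animal", "food")
  )
  fx <- rbind(fx_row(0, lay, 0), fx_row(1, lay, 300))
  lab <- label_roles(fx, lay, seed = 1)
  expect_equal(lab$upcoming_reason[1], "feature_match")
  expect_true(is.na(lab$upcoming_slot[1]))

  # foveal = color food; upcoming = gray animal: no shared feature, in band
  lay2 <- fixed_layout(
    colors = c("color", "gray", "gray", "color", "gray", "color", "gray"),
    cats = c("food", "animal", "food", "object", "object", "animal", "food")
  )
  fx2 <- rbind(fx_row(0, lay2, 0), fx_row(1, lay2, 300))
  lab2 <- label_roles(fx2, lay2, seed = 1)
  expect_equal(lab2$upcoming_reason[1], "none")
  expect_equal(lab2$upcoming_slot[1], 1L)
  expect_equal(lab2$upcoming_color[1], "gray")
  expect_equal(lab2$upcoming_category[1], "animal")
})

test_that("candidates outside the 2-5 degree parafoveal band are excluded", {
  lay <- fixed_layout(
    colors = c("color", "gray", "gray", "color", "gray", "color", "gray"),
    cats = c("food", "animal", "food", "object", "object", "animal", "food")
  )
  # fixating ring slot 1 at (4, 0); previous was slot 4 at (-4, 0): 8 deg away
  fx <- rbind(fx_row(4, lay, 0), fx_row(1, lay, 300), fx_row(0, lay, 600))
  lab <- label_roles(fx, lay, seed = 1)
  i <- which(lab$fixation_index == 2)
  expect_equal(lab$past_reason[i], "out_of_band")

  # upcoming at exactly 4 deg from current gaze is inside the band
  expect_equal(lab$upcoming_slot[i], 0L)
})

test_that("revisited images are excluded for foveal, upcoming, and past roles", {
  lay <- fixed_layout(
    colors = c("color", "gray", "gray", "color", "gray", "color", "gray"),
    cats = c("food", "animal", "food", "object", "object", "animal", "food")
  )
  # path 0 -> 1 -> 0: the second fixation on 0 is a foveal revisit, and as
  # the upcoming of fixation 2 it is also a revisit
  fx <- rbind(fx_row(0, lay, 0), fx_row(1, lay, 300), fx_row(0, lay, 600))
  lab <- label_roles(fx, lay, seed = 1)
  expect_equal(lab$foveal_reason, c("none", "none", "revisited"))
  expect_equal(lab$upcoming_reason[2], "revisited")
})

test_that("role labeling matches a brute-force rule enumerator", {
  cfg <- synth_config(n_participants = 1, n_trials = 1, n_channels = 2)
  n_paths <- 200
  mismatches <- 0
  for (i in seq_len(n_paths)) {
    lay <- make_layout(seed = i)
    sp <- simulate_scanpath(lay, cfg, seed = 5000 + i)
    fx0 <- sp$events[sp$events$kind == "fixation", ]
    fx <- tibble::tibble(
      trial_id = 1, onset_ms = fx0$onset_ms, offset_ms = fx0$offset_ms,
      x_deg = fx0$x_deg, y_deg = fx0$y_deg, slot_id = fx0$slot_id
    )
    got <- label_roles(fx, lay, seed = i)
    want <- brute_force_roles(fx, lay)
    expect_equal(nrow(got), length(want))
    for (k in seq_along(want)) {
      w <- want[[k]]
      g <- got[k, ]
      ok <- identical(g$foveal_reason, w$foveal_reason) &&
        identical(g$upcoming_reason, w$upcoming_reason) &&
        identical(g$past_reason, w$past_reason) &&
        identical(is.na(g$upcoming_slot), is.na(w$upcoming_slot)) &&
        (is.na(w$upcoming_slot) || g$upcoming_slot == w$upcoming_slot) &&
        (is.na(w$past_slot) || g$past_slot == w$past_slot) &&
        (length(w$remaining_set) == 0) == is.na(g$remaining_slot) &&
        (is.na(g$remaining_slot) || g$remaining_slot %in% w$remaining_set)
      if (!ok) mismatches <- mismatches + 1
    }
  }
  expect_equal(mismatches, 0)
})

test_that("labeled parafoveal images obey the band and feature invariants", {
  cfg <- synth_config(n_participants = 1, n_trials = 1, n_channels = 2)
  for (i in 1:40) {
    lay <- make_layout(seed = 100 + i)
    sp <- simulate_scanpath(lay, cfg, seed = 7000 + i)
    fx0 <- sp$events[sp$events$kind == "fixation", ]
    fx <- tibble::tibble(
      trial_id = 1, onset_ms = fx0$onset_ms, offset_ms = fx0$offset_ms,
      x_deg = fx0$x_deg, y_deg = fx0$y_deg, slot_id = fx0$slot_id
    )
    lab <- label_roles(fx, lay, seed = i)
    for (role in c("upcoming", "past", "remaining")) {
      sl <- lab[[paste0(role, "_slot")]]
      sel <- !is.na(sl)
      if (!any(sel)) next
      ecc <- sqrt((lay$x_deg[match(sl[sel], lay$slot_id)] - lab$x_deg[sel])^2 +
                    (lay$y_deg[match(sl[sel], lay$slot_id)] - lab$y_deg[sel])^2)
      expect_true(all(ecc >= 2 & ecc <= 5))
      # labeled parafoveal images differ from the fovea in BOTH features
      expect_true(all(lab[[paste0(role, "_color")]][sel] != lab$foveal_color[sel] |
                        is.na(lab$foveal_color[sel])))
      expect_true(all(lab[[paste0(role, "_category")]][sel] != lab$foveal_category[sel] |
                        is.na(lab$foveal_category[sel])))
    }
  }
})
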