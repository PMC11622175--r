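# Independent brute-force oracle for fixation role labeling: checks every
# slot against every rule by direct enumeration, sharing no code with
# label_roles() beyond the layout tibble format.
brute_force_roles <- function(fx, lay, band = c(2, 5)) {
  fx <- fx[order(fx$onset_ms), , drop = FALSE]
  n <- nrow(fx)
  res <- list()
  for (i in seq_len(n)) {
    s <- fx$slot_id[i]
    if (is.na(s)) next
    gx <- fx$x_deg[i]
    gy <- fx$y_deg[i]
    fov_row <- which(lay$slot_id == s)
    fcol <- lay$color_scale[fov_row]
    fcat <- lay$category[fov_row]

    check <- function(cand, visited) {
      if (is.na(cand)) {
        return(c(NA, "none_available"))
      }
      row <- which(lay$slot_id == cand)
      e <- sqrt((lay$x_deg[row] - gx)^2 + (lay$y_deg[row] - gy)^2)
      if (e < band[1] || e > band[2]) {
        return(c(NA, "out_of_band"))
      }
      if (cand %in% visited) {
        return(c(NA, "revisited"))
      }
      if (lay$color_scale[row] == fcol || lay$category[row] == fcat) {
        return(c(NA, "feature_match"))
      }
      c(cand, "none")
    }

    prev <- if (i > 1) fx$slot_id[i - 1] else NA
    nxt <- if (i < n) fx$slot_id[i + 1] else NA
    up <- check(nxt, fx$slot_id[seq_len(i)])
    pa <- check(prev, if (i > 2) fx$slot_id[seq_len(i - 2)] else integer(0))
    fov_rev <- s %in% fx$slot_id[seq_len(i - 1)]

    # all remaining candidates passing band + feature rules (set, not choice)
    rem_set <- c()
    for (cand in setdiff(lay$slot_id, c(s, prev, nxt))) {
      row <- which(lay$slot_id == cand)
      e <- sqrt((lay$x_deg[row] - gx)^2 + (lay$y_deg[row] - gy)^2)
      if (e >= band[1] && e <= band[2] &&
            lay$color_scale[row] != fcol && lay$category[row] != fcat) {
        rem_set <- c(rem_set, cand)
      }
    }

    res[[length(res) + 1]] <- list(
      fixation = i,
      foveal_reason = if (fov_rev) "revisited" else "none",
      upcoming_slot = suppressWarnings(as.integer(up[1])),
      upcoming_reason = up[2],
      past_slot = suppressWarnings(as.integer(pa[1])),
      past_reason = pa[2],
      remaining_set = rem_set
    )
  }
  res
}

# Minimal gaze trace: stationary segments at given positions with linear
# ramps between them.
make_step_trace <- function(positions, dwell_ms = 300, move_ms = 40,
                            sfreq = 1000, pupil = 1000) {
  xs <- c()
  ys <- c()
  for (i in seq_len(nrow(positions))) {
    n_dwell <- dwell_ms * sfreq / 1000
    xs <- c(xs, rep(positions$x[i], n_dwell))
    ys <- c(ys, rep(positions$y[i], n_dwell))
    if (i < nrow(positions)) {
      n_mv <- move_ms * sfreq / 1000
      tau <- seq_len(n_mv) / n_mv
      s <- 10 * tau^3 - 15 * tau^4 + 6 * tau^5
      xs <- c(xs, positions$x[i] + s * (positions$x[i + 1] - positions$x[i]))
      ys <- c(ys, positions$y[i] + s * (positions$y[i + 1] - positions$y[i]))
    }
  }
  tibble::tibble(
    t_ms = seq_along(xs) - 1,
    x_deg = xs, y_deg = ys,
    pupil = rep(pupil, length(xs))
  )
}
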