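#' Generate the seven-image trial layout
#'
#' One 3 deg x 3 deg image sits at screen center and six more on a ring at
#' angles 0, 60, ..., 300 degrees. With a 1 deg gap between image borders the
#' center-to-center distance to the ring is 1.5 + 1 + 1.5 = 4 deg. Color scale
#' (gray/color) and category (animal/food/object) assignments are balanced as
#' evenly as seven slots allow (4/3 for color scale, 3/2/2 for category), with
#' the slot assignment randomized. One slot is designated as the target image
#' (the one that changes after the mask).
#'
#' @param seed optional integer seed; the same seed reproduces the layout.
#' @param ring_radius_deg center-to-center distance from screen center to the
#'   ring images, degrees of visual angle.
#' @param half_width_deg half-width of the square images, degrees.
#' @return a `trial_layout` tibble with one row per slot: `slot_id` (0 =
#'   center), `x_deg`, `y_deg`, `half_width_deg`, `color_scale`, `category`,
#'   `is_target`.
#' @examples
#' make_layout(seed = 1)
#' @export
make_layout <- function(seed = NULL, ring_radius_deg = 4, half_width_deg = 1.5) {
  with_seed(seed, {
    angles <- c(0, 60, 120, 180, 240, 300)
    x <- c(0, ring_radius_deg * cos(angles * pi / 180))
    y <- c(0, ring_radius_deg * sin(angles * pi / 180))

    # balanced labels: color scale 4/3 split, category 3/2/2 split
    n_gray <- sample(3:4, 1)
    colors <- sample(c(rep("gray", n_gray), rep("color", 7 - n_gray)))
    cat_counts <- c(3, 2, 2)[sample.int(3)]
    cats <- sample(rep(c("animal", "food", "object"), times = cat_counts))

    out <- tibble(
      slot_id = 0:6,
      x_deg = round(x, 10),
      y_deg = round(y, 10),
      half_width_deg = half_width_deg,
      color_scale = colors,
      category = cats,
      is_target = seq_len(7) == sample.int(7, 1)
    )
    class(out) <- c("trial_layout", class(out))
    out
  })
}

#' Assign a gaze position to an image slot
#'
#' A fixation belongs to the slot whose square bounds contain the gaze
#' position; positions between image borders are background.
#'
#' @param x_deg,y_deg gaze position(s), degrees, screen-centered.
#' @param layout a `trial_layout` (see [make_layout()]).
#' @return integer vector of slot ids, `NA` for background.
#' @examples
#' lay <- make_layout(seed = 1)
#' assign_fixation_image(c(0, 1.6, 4), c(0, 0, 0), lay)
#' @export
assign_fixation_image <- function(x_deg, y_deg, layout) {
  stopifnot(length(x_deg) == length(y_deg))
  vapply(seq_along(x_deg), function(i) {
    hit <- which(abs(x_deg[i] - layout$x_deg) <= layout$half_width_deg &
                   abs(y_deg[i] - layout$y_deg) <= layout$half_width_deg)
    if (length(hit) == 0L) NA_integer_ else layout$slot_id[hit[1L]]
  }, integer(1))
}
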