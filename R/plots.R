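#' Plot group decoding curves
#'
#' Group mean AUC over time with a standard-error ribbon, one panel per
#' problem and color per role; significant temporal clusters (if supplied)
#' are drawn as horizontal bars near the chance line.
#'
#' @param curves tidy curve tibble (`participant`, `time_s`, `auc`, and
#'   optionally `role`, `problem`).
#' @param cluster_tests optional named list of `cluster_test` objects keyed
#'   `"<role>.<problem>"` (as in a `results_bundle`).
#' @param chance chance level reference line.
#' @return a ggplot object.
#' @export
plot_decoding_curves <- function(curves, cluster_tests = NULL, chance = 0.5) {
  if (!"role" %in% names(curves)) curves$role <- "all"
  if (!"problem" %in% names(curves)) curves$problem <- "all"
  g <- curves |>
    group_by(.data$role, .data$problem, .data$time_s) |>
    summarise(
      mean_auc = mean(.data$auc),
      sem = sd(.data$auc) / sqrt(dplyr::n()),
      .groups = "drop"
    )
  p <- ggplot2::ggplot(g, ggplot2::aes(.data$time_s, .data$mean_auc,
                                       color = .data$role, fill = .data$role)) +
    ggplot2::geom_hline(yintercept = chance, linetype = 2, color = "grey40") +
    ggplot2::geom_vline(xintercept = 0, linetype = 3, color = "grey60") +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean_auc - .data$sem,
                                      ymax = .data$mean_auc + .data$sem),
                         alpha = 0.25, color = NA) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(ggplot2::vars(.data$problem)) +
    ggplot2::labs(x = "time from fixation onset (s)", y = "AUC") +
    ggplot2::theme_minimal()
  if (!is.null(cluster_tests)) {
    bars <- dplyr::bind_rows(lapply(names(cluster_tests), function(k) {
      cls <- cluster_tests[[k]]$clusters
      if (nrow(cls) == 0 || !"onset" %in% names(cls)) return(NULL)
      parts <- strsplit(k, ".", fixed = TRUE)[[1]]
      tibble(role = parts[1], problem = parts[2],
             onset = cls$onset, offset = cls$offset)
    }))
    if (!is.null(bars) && nrow(bars) > 0) {
      p <- p + ggplot2::geom_segment(
        data = bars,
        ggplot2::aes(x = .data$onset, xend = .data$offset,
                     y = chance - 0.015, yend = chance - 0.015,
                     color = .data$role),
        linewidth = 1.5, inherit.aes = FALSE
      )
    }
  }
  p
}

#' @method autoplot decoding_curve
#' @export
autoplot.decoding_curve <- function(object, chance = 0.5, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$time_s, .data$auc)) +
    ggplot2::geom_hline(yintercept = chance, linetype = 2, color = "grey40") +
    ggplot2::geom_line(color = "steelblue") +
    ggplot2::labs(x = "time from fixation onset (s)", y = "AUC") +
    ggplot2::theme_minimal()
}

#' @method autoplot tg_matrix
#' @export
autoplot.tg_matrix <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(.data$test_time_s, .data$train_time_s,
                               fill = .data$auc)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(midpoint = 0.5, low = "navy",
                                  mid = "white", high = "firebrick") +
    ggplot2::labs(x = "test time (s)", y = "train time (s)", fill = "AUC") +
    ggplot2::coord_equal() +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @method glance decoding_curve
#' @export
glance.decoding_curve <- function(x, ...) {
  tibble(
    peak_auc = max(x$auc),
    peak_time_s = x$time_s[which.max(x$auc)],
    mean_auc = mean(x$auc),
    n_epochs = attr(x, "n_epochs") %||% NA_integer_,
    problem = attr(x, "problem") %||% NA_character_
  )
}
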