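# Plain-text interchange helpers. Gaze traces, event lists, layouts,
# responses and decoding curves all travel as TSV with documented headers;
# array-valued intermediates (recordings, epoch sets) are cached as RDS.

write_tsv_ <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv_ <- function(path) {
  tibble::as_tibble(read.table(path, sep = "\t", header = TRUE,
                               stringsAsFactors = FALSE))
}

#' Read / write gaze traces as TSV
#'
#' Columns: `trial_id`, `t_ms`, `x_deg`, `y_deg`, `pupil`. Vendor binary
#' files (EyeLink EDF/ASC) are out of scope; convert them to this layout
#' with the vendor tools first.
#'
#' @param path file path.
#' @return a gaze tibble.
#' @export
read_gaze_tsv <- function(path) {
  g <- read_tsv_(path)
  need <- c("trial_id", "t_ms", "x_deg", "y_deg")
  if (!all(need %in% names(g))) {
    stop("gaze TSV must have columns ", paste(need, collapse = ", "))
  }
  g
}

#' @rdname read_gaze_tsv
#' @param gaze gaze tibble to write.
#' @export
write_gaze_tsv <- function(gaze, path) {
  write_tsv_(gaze, path)
}

#' Read / write eye-event lists as TSV
#'
#' Columns: `trial_id`, `kind` (fixation/saccade/blink), `onset_ms`,
#' `offset_ms`, `x_deg`, `y_deg`, `peak_velocity`, `peak_acceleration`.
#'
#' @param path file path.
#' @return an events tibble.
#' @export
read_events_tsv <- function(path) read_tsv_(path)

#' @rdname read_events_tsv
#' @param events events tibble to write.
#' @export
write_events_tsv <- function(events, path) write_tsv_(events, path)
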