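# Plain-text I/O: long-format CSV for signals and events, JSON for trees.

#' Write / read an EMG or envelope recording as long-format CSV
#'
#' Columns: `time_s`, `channel`, `value`.
#'
#' @param rec An [emg_recording()].
#' @param path Output file.
#' @return `path`, invisibly (`write_emg_csv`); an [emg_recording()]
#'   (`read_emg_csv`).
#' @export
write_emg_csv <- function(rec, path) {
  stopifnot(inherits(rec, "emg_recording"))
  n <- ncol(rec$samples)
  df <- data.frame(
    time_s = rep((seq_len(n) - 1L) / rec$fs_hz, times = nrow(rec$samples)),
    channel = rep(rec$muscle_names, each = n),
    value = as.vector(t(rec$samples)))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_emg_csv
#' @param fs_hz Sampling rate of the stored signal.
#' @param leg Leg label for the rebuilt recording.
#' @export
read_emg_csv <- function(path, fs_hz, leg = "paretic") {
  df <- read.csv(path, stringsAsFactors = FALSE)
  channels <- unique(df$channel)
  mat <- do.call(rbind, lapply(channels, function(ch) {
    d <- df[df$channel == ch, ]
    d$value[order(d$time_s)]
  }))
  emg_recording(mat, fs_hz, muscle_names = channels, leg = leg)
}

#' Write / read gait events as CSV
#'
#' Columns: `event` (`heel_strike`/`toe_off`), `leg`, `time_s`.
#'
#' @param events A [gait_events()].
#' @param path Output file.
#' @return `path`, invisibly; `read_gait_events_csv` returns a
#'   [gait_events()].
#' @export
write_gait_events_csv <- function(events, path) {
  stopifnot(inherits(events, "gait_events"))
  df <- rbind(
    data.frame(event = "heel_strike", leg = "paretic",
               time_s = events$paretic_heel_strikes),
    data.frame(event = "toe_off", leg = "paretic",
               time_s = events$paretic_toe_offs),
    data.frame(event = "heel_strike", leg = "nonparetic",
               time_s = events$nonparetic_heel_strikes),
    data.frame(event = "toe_off", leg = "nonparetic",
               time_s = events$nonparetic_toe_offs))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_gait_events_csv
#' @export
read_gait_events_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  pick <- function(ev, leg) sort(df$time_s[df$event == ev & df$leg == leg])
  gait_events(pick("heel_strike", "paretic"), pick("toe_off", "paretic"),
              pick("heel_strike", "nonparetic"),
              pick("toe_off", "nonparetic"))
}

#' Serialize a coarse tree to JSON
#'
#' @param model A `coarse_tree`.
#' @param path Optional output file; when `NULL` the JSON string is
#'   returned.
#' @return JSON string (invisibly when written to `path`).
#' @export
tree_to_json <- function(model, path = NULL) {
  stopifnot(inherits(model, "coarse_tree"))
  js <- jsonlite::toJSON(list(nodes = model$nodes,
                              features = model$features,
                              classes = model$classes), dataframe = "rows",
                         na = "null", auto_unbox = TRUE, digits = NA)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}
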