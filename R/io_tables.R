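## Delimited-text I/O: signals, event tables, hypnograms.
## Comma-separated, UTF-8, "." decimal. Numeric fields are printed with a
## fixed format so that write -> read -> write is byte-stable.

fmt_num <- function(x, digits = 6) {
  out <- sprintf(paste0("%.", digits, "f"), x)
  out[!is.finite(x)] <- as.character(x[!is.finite(x)])
  out
}

#' Read a delimited multichannel signal file
#'
#' One numeric column per channel, constant sampling rate supplied by the
#' caller (delimited text carries no timing metadata).
#'
#' @param path CSV file with a header row of channel names.
#' @param rate sampling rate in Hz.
#' @param role_map named character vector of channel roles as in
#'   [read_edf()].
#' @param units unit string applied to all channels (default `"mV"`).
#' @return a [signal_record()].
#' @export
read_delimited <- function(path, rate, role_map, units = "mV") {
  if (!file.exists(path))
    abort(sprintf("file not found: %s", path), class = "swd_io_error")
  lines <- readLines(path, encoding = "UTF-8")
  if (length(lines) < 1L) abort("empty signal file", class = "swd_format_error")
  header <- strsplit(lines[1], ",", fixed = TRUE)[[1]]
  body <- lines[-1]
  parts <- strsplit(body, ",", fixed = TRUE)
  nfield <- lengths(parts)
  bad <- which(nfield != length(header))
  if (length(bad))
    abort(sprintf("ragged row at line %d: %d field(s), expected %d",
                  bad[1] + 1L, nfield[bad[1]], length(header)),
          class = "swd_parse_error")
  mat <- suppressWarnings(
    matrix(as.numeric(unlist(parts, use.names = FALSE)),
           ncol = length(header), byrow = TRUE))
  if (anyNA(mat)) {
    idx <- which(is.na(mat), arr.ind = TRUE)[1, ]
    abort(sprintf("non-numeric value at row %d, column '%s'",
                  idx[["row"]], header[idx[["col"]]]), class = "swd_parse_error")
  }
  channels <- setNames(lapply(seq_along(header), function(j) mat[, j]), header)
  rec <- signal_record(channels, rate = rate, roles = role_map,
                       units = setNames(rep(units, length(header)), header))
  require_roles(rec)
  rec
}

#' Write a signal record as delimited text
#'
#' @param record a [signal_record()].
#' @param path output path.
#' @param digits decimals printed per sample.
#' @return `path`, invisibly.
#' @export
write_delimited <- function(record, path, digits = 6) {
  header <- paste(names(record$channels), collapse = ",")
  cols <- lapply(record$channels, fmt_num, digits = digits)
  body <- do.call(paste, c(cols, sep = ","))
  writeLines(c(header, body), path, useBytes = TRUE)
  invisible(path)
}

event_columns <- c("onset_s", "offset_s", "duration_s", "kind", "band_lo_hz",
                   "band_hi_hz", "peak_freq_hz", "laterality", "state")

#' An empty event table
#'
#' The canonical schema for detected events: one row per SWD/SSWD/spindle
#' with half-open `[onset_s, offset_s)` times.
#' @return zero-row tibble with the event schema.
#' @export
empty_events <- function() {
  tibble(onset_s = numeric(0), offset_s = numeric(0), duration_s = numeric(0),
         kind = character(0), band_lo_hz = numeric(0), band_hi_hz = numeric(0),
         peak_freq_hz = numeric(0), laterality = character(0),
         state = character(0))
}

#' Write an event table
#'
#' Delimited text, one row per event, times printed with millisecond
#' precision. Events must be sorted by onset.
#'
#' @param events tibble with the [empty_events()] schema.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_events <- function(events, path) {
  if (nrow(events) > 1 && is.unsorted(events$onset_s))
    abort("events must be sorted by onset_s", class = "swd_ordering_error")
  ev <- events[, event_columns]
  lines <- do.call(paste, c(list(fmt_num(ev$onset_s, 3), fmt_num(ev$offset_s, 3),
                                 fmt_num(ev$duration_s, 3), ev$kind,
                                 fmt_num(ev$band_lo_hz, 3), fmt_num(ev$band_hi_hz, 3),
                                 fmt_num(ev$peak_freq_hz, 3), ev$laterality,
                                 ev$state), sep = ","))
  writeLines(c(paste(event_columns, collapse = ","),
               if (nrow(ev)) lines), path, useBytes = TRUE)
  invisible(path)
}

#' Read an event table written by [write_events()]
#' @param path event file.
#' @return tibble with the [empty_events()] schema.
#' @export
read_events <- function(path) {
  df <- readr::read_csv(path, col_types = readr::cols(
    onset_s = "d", offset_s = "d", duration_s = "d", kind = "c",
    band_lo_hz = "d", band_hi_hz = "d", peak_freq_hz = "d",
    laterality = "c", state = "c"), progress = FALSE)
  as_tibble(df)[, event_columns]
}

#' Write a hypnogram as delimited text
#'
#' One row per 10-s epoch: `epoch_index` (0-based), `start_s`, `end_s`,
#' `state`, `artifact_flag`.
#'
#' @param hyp a [hypnogram] object (see [score_epochs()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_hypnogram <- function(hyp, path) {
  ep <- hyp$epochs
  lines <- paste(ep$epoch, fmt_num(ep$start_s, 3), fmt_num(ep$end_s, 3),
                 ep$state, as.integer(ep$state == "artifact"), sep = ",")
  writeLines(c("epoch_index,start_s,end_s,state,artifact_flag",
               if (nrow(ep)) lines), path, useBytes = TRUE)
  invisible(path)
}

#' Read a hypnogram written by [write_hypnogram()]
#'
#' Sub-epoch labels are reconstructed as uniform within each epoch (the file
#' format stores epoch-level labels only).
#'
#' @param path hypnogram file.
#' @return a [hypnogram] object.
#' @export
read_hypnogram <- function(path) {
  df <- readr::read_csv(path, col_types = readr::cols(
    epoch_index = "i", start_s = "d", end_s = "d", state = "c",
    artifact_flag = "i"), progress = FALSE)
  epochs <- tibble(epoch = df$epoch_index, start_s = df$start_s,
                   end_s = df$end_s, state = df$state)
  epoch_len <- if (nrow(df)) df$end_s[1] - df$start_s[1] else 10
  sub <- tibble(
    second = unlist(lapply(seq_len(nrow(epochs)), function(i)
      seq(epochs$start_s[i], epochs$end_s[i] - 1))),
    state = rep(epochs$state, each = as.integer(round(epoch_len))))
  new_hypnogram(epochs, sub, epoch_len_s = epoch_len)
}
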