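#' Continuous multichannel polysomnography record
#'
#' Container for simultaneously sampled EEG/EMG channels on one time grid.
#' Channel roles resolve which channel is left EEG, right EEG and EMG;
#' downstream staging and detection require two EEG channels and one EMG
#' channel. Artifact intervals are half-open `[start_s, end_s)` in seconds
#' from record start and are kept normalized (sorted, disjoint).
#'
#' @param channels named list of equal-length numeric vectors (mV).
#' @param rate sampling rate in Hz (> 0), shared by all channels.
#' @param roles named character vector mapping channel name to one of
#'   `"eeg_left"`, `"eeg_right"`, `"emg"`; each role at most once.
#' @param units named character vector of per-channel physical units
#'   (default `"mV"` for all).
#' @param artifacts tibble with columns `start_s`, `end_s` of intervals to
#'   exclude from analysis; normalized on construction.
#' @param start_time record start offset in seconds (0 at record start).
#' @return an object of class `signal_record`.
#' @export
signal_record <- function(channels, rate, roles,
                          units = NULL, artifacts = NULL, start_time = 0) {
  if (!is.list(channels) || is.null(names(channels)) ||
      any(!nzchar(names(channels))) || anyDuplicated(names(channels)))
    abort("`channels` must be a uniquely named list of numeric vectors",
          class = "swd_input_error")
  lens <- vapply(channels, length, integer(1))
  if (length(unique(lens)) != 1L)
    abort("all channels must have the same length", class = "swd_input_error")
  if (!is.numeric(rate) || length(rate) != 1L || rate <= 0)
    abort("`rate` must be a single positive number", class = "swd_input_error")
  roles <- validate_roles(roles, names(channels))
  if (is.null(units)) units <- setNames(rep("mV", length(channels)), names(channels))
  units <- units[names(channels)]
  artifacts <- normalize_intervals(artifacts %||% empty_intervals())
  dur <- lens[[1]] / rate
  if (nrow(artifacts) > 0) {
    artifacts$start_s <- pmax(0, artifacts$start_s)
    artifacts$end_s <- pmin(dur, artifacts$end_s)
    artifacts <- normalize_intervals(artifacts)
  }
  structure(
    list(channels = lapply(channels, as.numeric), rate = rate, roles = roles,
         units = units, artifacts = artifacts, start_time = start_time),
    class = "signal_record")
}

validate_roles <- function(roles, channel_names) {
  valid <- c("eeg_left", "eeg_right", "emg")
  if (is.null(names(roles)) || !all(roles %in% valid))
    abort(sprintf("roles must map channel names to %s",
                  paste(valid, collapse = "/")), class = "swd_config_error")
  if (anyDuplicated(roles))
    abort("each role may be assigned at most once", class = "swd_config_error")
  missing_ch <- setdiff(names(roles), channel_names)
  if (length(missing_ch))
    abort(sprintf("role_map names channels absent from the record: %s",
                  paste(missing_ch, collapse = ", ")), class = "swd_config_error")
  roles
}

require_roles <- function(record, needed = c("eeg_left", "eeg_right", "emg")) {
  missing_roles <- setdiff(needed, unname(record$roles))
  if (length(missing_roles))
    abort(sprintf("record is missing required channel role(s): %s",
                  paste(missing_roles, collapse = ", ")),
          class = "swd_config_error")
  invisible(record)
}

#' @export
print.signal_record <- function(x, ...) {
  cat(sprintf("<signal_record> %d channel(s) @ %g Hz, %.1f s\n",
              length(x$channels), x$rate, record_duration(x)))
  for (nm in names(x$channels)) {
    role <- if (nm %in% names(x$roles)) x$roles[[nm]] else "-"
    cat(sprintf("  %-12s %-9s [%s]\n", nm, role, x$units[[nm]]))
  }
  if (nrow(x$artifacts))
    cat(sprintf("  artifact mask: %d interval(s), %.1f s total\n",
                nrow(x$artifacts), sum(x$artifacts$end_s - x$artifacts$start_s)))
  invisible(x)
}

#' Record duration in seconds
#' @param record a [signal_record()].
#' @return duration in seconds.
#' @export
record_duration <- function(record) {
  length(record$channels[[1]]) / record$rate
}

#' Extract one channel by role
#' @param record a [signal_record()].
#' @param role one of `"eeg_left"`, `"eeg_right"`, `"emg"`.
#' @return numeric vector of samples.
#' @export
channel_by_role <- function(record, role) {
  nm <- names(record$roles)[record$roles == role]
  if (length(nm) != 1L)
    abort(sprintf("no channel with role '%s'", role), class = "swd_config_error")
  record$channels[[nm]]
}

#' @method as_tibble signal_record
#' @export
as_tibble.signal_record <- function(x, ...) {
  n <- length(x$channels[[1]])
  out <- tibble(time_s = (seq_len(n) - 1L) / x$rate)
  for (nm in names(x$channels)) out[[nm]] <- x$channels[[nm]]
  out
}
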