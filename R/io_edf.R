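## Minimal EDF/EDF+ I/O.
##
## EDF stores an ASCII fixed-field header (256 bytes + 256 per signal)
## followed by data records of 16-bit little-endian integers, one block per
## signal per record. Physical values are recovered from the per-signal
## physical/digital ranges. This covers the subset needed for
## polysomnography records: continuous signals, one sampling rate per
## signal, optional EDF+ annotation signals (skipped on read).

edf_field <- function(x, width) {
  s <- format(as.character(x), width = width)
  substr(s, 1, width)
}

read_ascii <- function(con, width) {
  trimws(rawToChar(readBin(con, "raw", width)))
}

#' Read an EDF/EDF+ file into a signal record
#'
#' Channels with differing sampling rates are resampled (anti-aliased /
#' polyphase) to the maximum rate present so downstream code sees a single
#' time grid. EDF+ annotation signals are ignored.
#'
#' @param path path to an EDF file.
#' @param role_map named character vector mapping channel labels to roles
#'   (`"eeg_left"`, `"eeg_right"`, `"emg"`); must cover two EEG channels and
#'   one EMG channel.
#' @return a [signal_record()].
#' @export
read_edf <- function(path, role_map) {
  if (!file.exists(path))
    abort(sprintf("file not found: %s", path), class = "swd_io_error")
  con <- file(path, "rb")
  on.exit(close(con))
  version <- read_ascii(con, 8)
  if (!identical(version, "0"))
    abort("not an EDF file (bad version field)", class = "swd_format_error")
  invisible(readBin(con, "raw", 80 + 80 + 8 + 8))  # patient, recording, date, time
  header_bytes <- suppressWarnings(as.integer(read_ascii(con, 8)))
  invisible(readBin(con, "raw", 44))
  n_records <- suppressWarnings(as.integer(read_ascii(con, 8)))
  record_dur <- suppressWarnings(as.numeric(read_ascii(con, 8)))
  ns <- suppressWarnings(as.integer(read_ascii(con, 4)))
  if (anyNA(c(header_bytes, n_records, record_dur, ns)) || ns < 1 ||
      record_dur <= 0 || n_records < 0)
    abort("corrupt EDF header", class = "swd_format_error")
  labels <- vapply(seq_len(ns), function(i) read_ascii(con, 16), character(1))
  invisible(readBin(con, "raw", 80L * ns))  # transducer
  units <- vapply(seq_len(ns), function(i) read_ascii(con, 8), character(1))
  pmin <- as.numeric(vapply(seq_len(ns), function(i) read_ascii(con, 8), character(1)))
  pmax <- as.numeric(vapply(seq_len(ns), function(i) read_ascii(con, 8), character(1)))
  dmin <- as.numeric(vapply(seq_len(ns), function(i) read_ascii(con, 8), character(1)))
  dmax <- as.numeric(vapply(seq_len(ns), function(i) read_ascii(con, 8), character(1)))
  invisible(readBin(con, "raw", 80L * ns))  # prefilter
  spr <- as.integer(vapply(seq_len(ns), function(i) read_ascii(con, 8), character(1)))
  invisible(readBin(con, "raw", 32L * ns))  # reserved
  if (anyNA(spr) || anyNA(pmin) || anyNA(pmax) || anyNA(dmin) || anyNA(dmax))
    abort("corrupt EDF signal header", class = "swd_format_error")

  keep <- !grepl("^EDF Annotations", labels)
  raw <- vector("list", ns)
  for (i in seq_len(ns)) raw[[i]] <- vector("list", n_records)
  for (r in seq_len(n_records)) {
    for (i in seq_len(ns)) {
      v <- readBin(con, "integer", n = spr[i], size = 2, signed = TRUE,
                   endian = "little")
      if (length(v) < spr[i])
        abort("truncated EDF data record", class = "swd_format_error")
      raw[[i]][[r]] <- v
    }
  }
  rates <- spr / record_dur
  target <- max(rates[keep])
  channels <- list(); ch_units <- character(0)
  for (i in which(keep)) {
    dig <- unlist(raw[[i]], use.names = FALSE)
    scale <- (pmax[i] - pmin[i]) / (dmax[i] - dmin[i])
    phys <- pmin[i] + (dig - dmin[i]) * scale
    if (rates[i] != target) phys <- resample_vector(phys, rates[i], target)
    channels[[labels[i]]] <- phys
    ch_units[labels[i]] <- units[i]
  }
  ## resampling ratios can leave off-by-one lengths; trim to the shortest
  nmin <- min(vapply(channels, length, integer(1)))
  channels <- lapply(channels, function(x) x[seq_len(nmin)])

  roles <- role_map[names(role_map) %in% names(channels)]
  missing_ch <- setdiff(names(role_map), names(channels))
  if (length(missing_ch))
    abort(sprintf("role_map channel(s) not in file: %s",
                  paste(missing_ch, collapse = ", ")), class = "swd_config_error")
  rec <- signal_record(channels, rate = target, roles = roles,
                       units = setNames(ch_units[names(channels)], names(channels)))
  require_roles(rec)
  rec
}

#' Write a signal record as EDF
#'
#' 16-bit EDF with one-second data records. The physical range defaults to
#' +/-10 mV, which covers simulated amplitudes without clipping; samples
#' outside the range are clipped. The final partial second, if any, is
#' zero-padded.
#'
#' @param record a [signal_record()].
#' @param path output path.
#' @param phys_range symmetric physical range (in channel units) encoded by
#'   the 16-bit digital range.
#' @return `path`, invisibly.
#' @export
write_edf <- function(record, path, phys_range = c(-10, 10)) {
  chans <- record$channels
  rate <- record$rate
  if (abs(rate - round(rate)) > 1e-9)
    abort("write_edf requires an integer sampling rate", class = "swd_parameter_error")
  spr <- as.integer(round(rate))
  n <- length(chans[[1]])
  n_records <- as.integer(ceiling(n / spr))
  ns <- length(chans)
  dmin <- -32768; dmax <- 32767
  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(x, width) writeChar(edf_field(x, width), con, eos = NULL)
  wr("0", 8); wr("X X X X", 80); wr("Startdate X X X X", 80)
  wr("01.01.00", 8); wr("00.00.00", 8)
  wr(256L + 256L * ns, 8); wr("", 44); wr(n_records, 8); wr("1", 8); wr(ns, 4)
  for (nm in names(chans)) wr(nm, 16)
  for (nm in names(chans)) wr("", 80)
  for (nm in names(chans)) wr(record$units[[nm]] %||% "mV", 8)
  for (nm in names(chans)) wr(phys_range[1], 8)
  for (nm in names(chans)) wr(phys_range[2], 8)
  for (nm in names(chans)) wr(dmin, 8)
  for (nm in names(chans)) wr(dmax, 8)
  for (nm in names(chans)) wr("", 80)
  for (nm in names(chans)) wr(spr, 8)
  for (nm in names(chans)) wr("", 32)
  scale <- (dmax - dmin) / (phys_range[2] - phys_range[1])
  dig <- lapply(chans, function(x) {
    x <- c(x, numeric(n_records * spr - n))
    d <- round((pmin(pmax(x, phys_range[1]), phys_range[2]) - phys_range[1]) *
                 scale + dmin)
    as.integer(pmin(pmax(d, dmin), dmax))
  })
  for (r in seq_len(n_records)) {
    idx <- ((r - 1L) * spr + 1L):(r * spr)
    for (i in seq_len(ns))
      writeBin(dig[[i]][idx], con, size = 2, endian = "little")
  }
  invisible(path)
}

#' EDF quantization step for a physical range
#'
#' The per-sample resolution of 16-bit EDF encoding:
#' `(phys_max - phys_min) / (dig_max - dig_min)`.
#'
#' @param phys_range length-2 physical range.
#' @return quantization step in physical units.
#' @export
edf_quant_step <- function(phys_range = c(-10, 10)) {
  diff(phys_range) / (32767 - (-32768))
}
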