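#' Minimal single-channel EDF writer / reader
#'
#' Writes an [eeg_signal()] to the European Data Format (EDF): 16-bit
#' little-endian samples, physical dimension microvolts, one-second data
#' records. The recording is zero-padded to a whole number of records; the
#' true sample count is stored so [read_edf()] returns the original length.
#' This is a deliberately small reader/writer for single-channel use, not a
#' general EDF(+) implementation.
#'
#' @param signal real [eeg_signal()] with integer sampling rate.
#' @param path output file path.
#' @param label signal label (<= 16 characters).
#' @return invisibly, `path`.
#' @export
write_edf <- function(signal, path, label = "EEG") {
  signal <- as_signal(signal)
  fs <- signal$fs
  if (fs != round(fs)) stop("EDF writer requires an integer sampling rate")
  x <- Re(signal$samples)
  n <- length(x)
  n_rec <- ceiling(n / fs)
  pad <- n_rec * fs - n
  phys_min <- min(x, -1); phys_max <- max(x, 1)
  dig_min <- -32768L; dig_max <- 32767L
  scale <- (dig_max - dig_min) / (phys_max - phys_min)
  dig <- as.integer(round((c(x, numeric(pad)) - phys_min) * scale + dig_min))
  dig <- pmin(pmax(dig, dig_min), dig_max)

  pad_field <- function(s, width) {
    s <- substr(as.character(s), 1L, width)
    sprintf(paste0("%-", width, "s"), s)
  }
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    pad_field("0", 8),
    pad_field("X X X X", 80),
    # stash the true sample count in the recording-id field
    pad_field(sprintf("Startdate X X X X nsamples=%d", n), 80),
    pad_field("01.01.00", 8), pad_field("00.00.00", 8),
    pad_field(256 + 256, 8),                 # header bytes: fixed + 1 signal
    pad_field("", 44),
    pad_field(n_rec, 8), pad_field("1", 8),  # records, record duration (s)
    pad_field("1", 4),
    # per-signal fields
    pad_field(label, 16), pad_field("", 80), pad_field("uV", 8),
    pad_field(sprintf("%.8g", phys_min), 8),
    pad_field(sprintf("%.8g", phys_max), 8),
    pad_field(dig_min, 8), pad_field(dig_max, 8),
    pad_field("", 80), pad_field(fs, 8), pad_field("", 32))
  writeChar(hdr, con, eos = NULL)
  writeBin(dig, con, size = 2L, endian = "little")
  invisible(path)
}

#' @rdname write_edf
#' @return `read_edf` returns the [eeg_signal()].
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readChar(con, 256L, useBytes = TRUE)
  fld <- function(from, width) trimws(substr(hdr, from, from + width - 1L))
  rec_id <- fld(89, 80)
  n_rec <- as.integer(fld(237, 8))
  ns <- as.integer(fld(253, 4))
  if (ns != 1L) stop("only single-channel EDF files are supported")
  sig <- readChar(con, 256L, useBytes = TRUE)
  sfld <- function(from, width) trimws(substr(sig, from, from + width - 1L))
  phys_min <- as.numeric(sfld(105, 8)); phys_max <- as.numeric(sfld(113, 8))
  dig_min <- as.integer(sfld(121, 8)); dig_max <- as.integer(sfld(129, 8))
  fs <- as.numeric(sfld(217, 8))
  dig <- readBin(con, "integer", n = n_rec * fs, size = 2L, signed = TRUE,
                 endian = "little")
  x <- (dig - dig_min) * (phys_max - phys_min) / (dig_max - dig_min) + phys_min
  m <- regmatches(rec_id, regexpr("nsamples=[0-9]+", rec_id))
  if (length(m) == 1L) x <- x[seq_len(as.integer(sub("nsamples=", "", m)))]
  eeg_signal(x, fs)
}

#' Read / write event annotations as CSV
#'
#' Plain CSV with columns `onset_s,duration_s,label`.
#'
#' @param events an [event_list()].
#' @param path file path.
#' @return `write_events` invisibly returns `path`; `read_events` the
#'   [event_list()].
#' @export
write_events <- function(events, path) {
  utils::write.csv(as.data.frame(events), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  event_list(df$onset_s, df$duration_s, df$label)
}

#' Export a time-frequency grid as long-format CSV
#'
#' Columns `n` (0-based time index), `k` (0-based frequency bin), `v`
#' (normalized frequency), `value` (real part; modified kernels also get an
#' `im` column).
#'
#' @param grid a [tfr_grid()].
#' @param path file path.
#' @return invisibly, `path`.
#' @export
write_tfr_csv <- function(grid, path) {
  N <- nrow(grid$values); K <- ncol(grid$values)
  df <- data.frame(n = rep(grid$time_axis, K),
                   k = rep(seq_len(K) - 1L, each = N),
                   v = rep(grid$freq_axis, each = N),
                   value = as.vector(Re(grid$values)))
  if (is.complex(grid$values)) df$im <- as.vector(Im(grid$values))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Save / load a synthetic-recording configuration as JSON
#' @param cfg a [synth_config()].
#' @param path file path.
#' @return `write_synth_config` invisibly returns `path`;
#'   `read_synth_config` the [synth_config()].
#' @export
write_synth_config <- function(cfg, path) {
  jsonlite::write_json(unclass(cfg), path, digits = NA, auto_unbox = TRUE,
                       null = "null")
  invisible(path)
}

#' @rdname write_synth_config
#' @export
read_synth_config <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(synth_config, obj)
}
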