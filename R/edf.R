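#' Read an EDF (European Data Format) recording
#'
#' Parses the fixed-width EDF header and the 16-bit sample stream, rescales to
#' physical units and returns the requested channels in the requested order.
#' All selected channels must share one sampling rate. Annotation/EDF+ event
#' channels are not interpreted.
#'
#' @param path path to an EDF file.
#' @param channel_selection character vector of channel labels to load, in the
#'   desired order; `NULL` (default) loads every signal.
#' @param alias_map optional named character vector mapping requested names to
#'   on-file labels (see [make_bipolar()]); matching is case-insensitive.
#' @param record_id record identity; defaults to the file name without
#'   extension.
#' @return An [eeg_recording()] with amplitudes in the file's physical units
#'   (µV for EEG).
#' @seealso [write_edf()]
#' @export
read_edf <- function(path, channel_selection = NULL, alias_map = NULL,
                     record_id = NULL) {
  if (!file.exists(path)) stop("cannot read EDF file: ", path, call. = FALSE)
  con <- file(path, "rb")
  on.exit(close(con))
  hdr_txt <- function(n) trimws(rawToChar(readBin(con, "raw", n)))
  version <- hdr_txt(8)
  patient <- hdr_txt(80); recording <- hdr_txt(80)
  startdate <- hdr_txt(8); starttime <- hdr_txt(8)
  header_bytes <- as.integer(hdr_txt(8))
  hdr_txt(44)  # reserved
  n_records <- as.integer(hdr_txt(8))
  record_dur <- as.numeric(hdr_txt(8))
  ns <- as.integer(hdr_txt(4))
  if (is.na(ns) || ns < 1 || is.na(n_records) || is.na(record_dur)) {
    stop("unreadable or truncated EDF header: ", path, call. = FALSE)
  }
  field <- function(w) vapply(seq_len(ns), function(i) hdr_txt(w), character(1))
  labels <- field(16)
  field(80)  # transducer
  field(8)   # physical dimension
  phys_min <- as.numeric(field(8)); phys_max <- as.numeric(field(8))
  dig_min <- as.numeric(field(8)); dig_max <- as.numeric(field(8))
  field(80)  # prefiltering
  spr <- as.integer(field(8))  # samples per data record
  field(32)  # reserved
  total <- sum(spr) * n_records
  raw_all <- readBin(con, "integer", n = total, size = 2, signed = TRUE,
                     endian = "little")
  if (length(raw_all) < total) {
    stop("unreadable or truncated EDF data section: ", path, call. = FALSE)
  }
  if (is.null(channel_selection)) channel_selection <- labels
  sel <- vapply(channel_selection, match_channel, integer(1),
                available = labels, alias_map = alias_map)
  fs <- spr[sel] / record_dur
  if (length(unique(fs)) != 1) {
    stop("selected channels have differing sampling rates", call. = FALSE)
  }
  # per-record channel offsets within the interleaved stream
  offsets <- c(0, cumsum(spr))
  rec_len <- sum(spr)
  out <- matrix(0, nrow = length(sel), ncol = spr[sel[1]] * n_records)
  for (j in seq_along(sel)) {
    s <- sel[j]
    gain <- (phys_max[s] - phys_min[s]) / (dig_max[s] - dig_min[s])
    idx <- as.vector(outer(seq_len(spr[s]) + offsets[s],
                           (seq_len(n_records) - 1) * rec_len, `+`))
    out[j, ] <- phys_min[s] + gain * (raw_all[idx] - dig_min[s])
  }
  if (is.null(record_id)) record_id <- sub("\\.[^.]*$", "", basename(path))
  eeg_recording(out, fs[1], channel_selection, record_id)
}

#' Write a recording to EDF
#'
#' Writes 16-bit EDF with one-second data records (the sampling rate must be a
#' positive integer, as for the 250/256 Hz rates used here, and the duration a
#' whole number of seconds; the signal is zero-padded to the next full second
#' if needed). Physical scaling spans the observed amplitude range, so the
#' round trip is exact to the format's 16-bit quantization.
#'
#' @param rec an [eeg_recording()].
#' @param path output path.
#' @param physical_range optional `c(min, max)` clipping/scaling range in µV;
#'   defaults to the data range (symmetrized, never degenerate).
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path, physical_range = NULL) {
  stopifnot(inherits(rec, "eeg_recording"))
  fs <- rec$fs
  if (fs != round(fs)) stop("EDF writer requires an integer sampling rate", call. = FALSE)
  nch <- n_channels(rec)
  n_records <- as.integer(ceiling(n_samples(rec) / fs))
  data <- rec$data
  if (ncol(data) < n_records * fs) {
    data <- cbind(data, matrix(0, nch, n_records * fs - ncol(data)))
  }
  if (is.null(physical_range)) {
    m <- max(abs(data), 1e-6)
    physical_range <- c(-m, m)
  }
  pmin <- physical_range[1]; pmax <- physical_range[2]
  dmin <- -32768; dmax <- 32767
  dig <- round((data - pmin) / (pmax - pmin) * (dmax - dmin) + dmin)
  dig[] <- pmin(pmax(dig, dmin), dmax)
  con <- file(path, "wb")
  on.exit(close(con))
  pad <- function(x, w) {
    s <- formatC(as.character(x), width = -w)  # left-justified
    vapply(s, function(si) substr(paste0(si, strrep(" ", w)), 1, w), character(1))
  }
  wr <- function(x, w) writeChar(paste(pad(x, w), collapse = ""), con, eos = NULL)
  wr("0", 8)                                   # version
  wr(rec$record_id, 80)                        # patient id field
  wr(rec$record_id, 80)                        # recording id field
  wr("01.01.00", 8); wr("00.00.00", 8)         # start date/time
  wr(256 * (nch + 1), 8)                       # header bytes
  wr("", 44)
  wr(n_records, 8)
  wr("1", 8)                                   # record duration (s)
  wr(nch, 4)
  wr(rec$channel_names, 16)
  wr(rep("", nch), 80)                         # transducer
  wr(rep("uV", nch), 8)
  wr(rep(format(pmin, digits = 7), nch), 8)
  wr(rep(format(pmax, digits = 7), nch), 8)
  wr(rep(dmin, nch), 8)
  wr(rep(dmax, nch), 8)
  wr(rep("", nch), 80)                         # prefiltering
  wr(rep(fs, nch), 8)                          # samples per record
  wr(rep("", nch), 32)
  # interleave: per record, each channel's fs samples
  for (r in seq_len(n_records)) {
    cols <- ((r - 1) * fs + 1):(r * fs)
    block <- as.integer(t(dig[, cols, drop = FALSE]))
    writeBin(block, con, size = 2, endian = "little")
  }
  invisible(path)
}
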