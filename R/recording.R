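#' Construct an EEG recording
#'
#' A recording holds a channels-by-samples amplitude matrix in microvolts,
#' together with its sampling rate, channel names, a record identifier and the
#' recording start offset. All channels share one sampling rate and one sample
#' count.
#'
#' @param data numeric matrix, channels in rows, samples in columns (µV).
#'   A vector is treated as a single channel.
#' @param fs sampling rate in Hz (> 0).
#' @param channel_names character vector of unique channel labels, one per row.
#' @param record_id record identifier string.
#' @param t0 recording start offset in seconds (default 0).
#'
#' @return An object of class `eeg_recording`.
#' @examples
#' rec <- eeg_recording(matrix(rnorm(500), 2, 250), fs = 250,
#'                      channel_names = c("F7-T7", "T7-P7"))
#' rec
#' @export
eeg_recording <- function(data, fs, channel_names, record_id = "rec", t0 = 0) {
  if (is.vector(data)) data <- matrix(data, nrow = 1)
  stopifnot(is.matrix(data), is.numeric(data))
  if (!is.numeric(fs) || length(fs) != 1 || fs <= 0) {
    stop("`fs` must be a single positive number", call. = FALSE)
  }
  if (ncol(data) < 1) stop("recording must contain at least one sample", call. = FALSE)
  channel_names <- as.character(channel_names)
  if (length(channel_names) != nrow(data)) {
    stop("`channel_names` length must equal the channel count", call. = FALSE)
  }
  if (anyDuplicated(channel_names)) {
    stop("`channel_names` must be unique", call. = FALSE)
  }
  rownames(data) <- channel_names
  structure(
    list(data = data, fs = fs, channel_names = channel_names,
         record_id = as.character(record_id), t0 = as.numeric(t0)),
    class = "eeg_recording"
  )
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %s: %d channel(s) x %d samples @ %g Hz (%.1f s)\n",
              x$record_id, n_channels(x), n_samples(x), x$fs, duration(x)))
  cat("  channels:", paste(x$channel_names, collapse = ", "), "\n")
  invisible(x)
}

#' Recording dimensions and duration
#'
#' @param rec an [eeg_recording()].
#' @return `n_channels()` and `n_samples()` return integers; `duration()`
#'   returns seconds.
#' @export
n_channels <- function(rec) nrow(rec$data)

#' @rdname n_channels
#' @export
n_samples <- function(rec) ncol(rec$data)

#' @rdname n_channels
#' @export
duration <- function(rec) n_samples(rec) / rec$fs

# case-insensitive channel lookup; alias_map maps user-name -> file-name
# (e.g. the 10-20 renaming T3 -> T7) and is never applied implicitly.
match_channel <- function(name, available, alias_map = NULL) {
  target <- name
  if (!is.null(alias_map) && tolower(name) %in% tolower(names(alias_map))) {
    target <- alias_map[[which(tolower(names(alias_map)) == tolower(name))[1]]]
  }
  hit <- which(tolower(available) == tolower(target))
  if (length(hit) == 0) {
    stop(sprintf("channel '%s' not found; available: %s",
                 name, paste(available, collapse = ", ")), call. = FALSE)
  }
  hit[1]
}

#' Build a bipolar montage from referential channels
#'
#' Each output channel is the sample-wise difference anode − cathode, named
#' `"anode-cathode"`. This is how the four temporal derivations used by the
#' detectors (F7–T7, T7–P7, F8–T8, T8–P8, or their TCP-era synonyms) are formed
#' from a referential recording.
#'
#' @param rec an [eeg_recording()].
#' @param pairs list of length-2 character vectors `c(anode, cathode)`.
#' @param alias_map optional named character vector mapping requested electrode
#'   names to names as stored in the file (e.g. `c("T7" = "T3")`). Matching is
#'   case-insensitive; aliases are only applied when supplied explicitly.
#'
#' @return An `eeg_recording` with one channel per pair.
#' @examples
#' rec <- eeg_recording(rbind(F7 = sin(1:100), T7 = cos(1:100)), 250,
#'                      c("F7", "T7"))
#' bp <- make_bipolar(rec, list(c("F7", "T7")))
#' bp$channel_names
#' @export
make_bipolar <- function(rec, pairs, alias_map = NULL) {
  stopifnot(inherits(rec, "eeg_recording"), length(pairs) >= 1)
  out <- matrix(0, nrow = length(pairs), ncol = n_samples(rec))
  nm <- character(length(pairs))
  for (i in seq_along(pairs)) {
    p <- pairs[[i]]
    if (length(p) != 2) stop("each pair must have an anode and a cathode", call. = FALSE)
    a <- match_channel(p[1], rec$channel_names, alias_map)
    c_ <- match_channel(p[2], rec$channel_names, alias_map)
    out[i, ] <- rec$data[a, ] - rec$data[c_, ]
    nm[i] <- paste0(p[1], "-", p[2])
  }
  eeg_recording(out, rec$fs, nm, rec$record_id, rec$t0)
}

#' The default temporal bipolar montages
#'
#' Electrode pairs for the four temporal derivations in the modern 10–20
#' naming (`"1020"`: F7–T7, T7–P7, F8–T8, T8–P8) and the older TCP-era naming
#' (`"tcp"`: F7–T3, T3–T5, F8–T4, T4–T6).
#'
#' @param style `"1020"` or `"tcp"`.
#' @return list of anode/cathode pairs for [make_bipolar()].
#' @export
temporal_montage <- function(style = c("1020", "tcp")) {
  style <- match.arg(style)
  if (style == "1020") {
    list(c("F7", "T7"), c("T7", "P7"), c("F8", "T8"), c("T8", "P8"))
  } else {
    list(c("F7", "T3"), c("T3", "T5"), c("F8", "T4"), c("T4", "T6"))
  }
}

#' Resample a recording to a target rate
#'
#' Band-limited (Fourier-domain) resampling of every channel: the spectrum is
#' truncated at the new Nyquist frequency on downsampling (exact
#' anti-aliasing) or zero-padded on upsampling, with no phase delay. Duration
#' is preserved to within one output sample. When the target equals the
#' current rate the recording is returned unchanged. Used to reconcile
#' 256 Hz seizure-corpus data with the 250 Hz rate of the artifact pipeline.
#'
#' @param rec an [eeg_recording()].
#' @param fs_target target sampling rate in Hz (> 0).
#' @return An `eeg_recording` at `fs_target`.
#' @examples
#' rec <- eeg_recording(matrix(sin(2 * pi * 10 * (0:2559) / 256), 1), 256, "ch1")
#' resample_recording(rec, 250)$fs
#' @export
resample_recording <- function(rec, fs_target) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (!is.numeric(fs_target) || length(fs_target) != 1 || fs_target <= 0) {
    stop("`fs_target` must be a single positive number", call. = FALSE)
  }
  if (fs_target == rec$fs) return(rec)
  n_in <- n_samples(rec)
  n_out <- round(n_in * fs_target / rec$fs)
  out <- matrix(0, nrow = n_channels(rec), ncol = n_out)
  for (i in seq_len(n_channels(rec))) {
    out[i, ] <- fourier_resample(rec$data[i, ], n_out)
  }
  eeg_recording(out, fs_target, rec$channel_names, rec$record_id, rec$t0)
}

# length-preserving-in-time spectral resampling of a real vector
fourier_resample <- function(x, n_out) {
  n_in <- length(x)
  if (n_out == n_in) return(x)
  X <- stats::fft(x)
  Y <- complex(n_out)
  m <- min(n_in, n_out)
  half <- floor(m / 2)
  Y[1] <- X[1]
  if (half >= 1) {
    Y[2:(half + 1)] <- X[2:(half + 1)]
    Y[n_out - (1:half) + 1] <- X[n_in - (1:half) + 1]
  }
  if (m %% 2 == 0) {
    # shared Nyquist-edge bin: split/merge keeps the signal real and Parseval
    if (n_out < n_in) {
      Y[half + 1] <- X[half + 1] + X[n_in - half + 1]
      Y[half + 1] <- Re(Y[half + 1]) / 2 + 0i
      Y[n_out - half + 1] <- Conj(Y[half + 1])
    } else {
      Y[half + 1] <- X[half + 1] / 2
      Y[n_out - half + 1] <- Conj(Y[half + 1])
    }
  }
  Re(stats::fft(Y, inverse = TRUE)) / n_in
}

#' Plot an EEG recording
#'
#' Stacked per-channel traces, optionally restricted to a time range and
#' decimated for display.
#'
#' @param object an [eeg_recording()].
#' @param from,to time range in seconds from recording start.
#' @param max_points cap on plotted points per channel (display decimation).
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.eeg_recording <- function(object, from = 0, to = duration(object),
                                   max_points = 4000, ...) {
  i0 <- max(1L, floor(from * object$fs) + 1L)
  i1 <- min(n_samples(object), ceiling(to * object$fs))
  idx <- seq(i0, i1)
  if (length(idx) > max_points) idx <- idx[seq(1, length(idx), length.out = max_points)]
  df <- tidyr::pivot_longer(
    tibble::as_tibble(t(object$data[, idx, drop = FALSE])) |>
      stats::setNames(object$channel_names) |>
      dplyr::mutate(time_s = object$t0 + (idx - 1) / object$fs),
    -"time_s", names_to = "channel", values_to = "uv"
  )
  df$channel <- factor(df$channel, levels = object$channel_names)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time_s, y = .data$uv)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$channel)) +
    ggplot2::labs(x = "time (s)", y = "amplitude (\u00b5V)",
                  title = object$record_id) +
    ggplot2::theme_minimal()
}
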