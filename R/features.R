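#' Analysis window specification
#'
#' Windows tile the recording from its start at a fixed stride. The detectors
#' use non-overlapping windows (`hop_s = length_s`), one decision per window —
#' the convention under which specificity converts to false alarms per hour as
#' `3600/W * (1 - Sp)`.
#'
#' @param length_s window duration W in seconds (typically 1, 2, 4 or 8).
#' @param fs sampling rate in Hz.
#' @param hop_s stride in seconds; defaults to `length_s`.
#' @return An object of class `window_spec`.
#' @export
window_spec <- function(length_s = 4, fs = 250, hop_s = length_s) {
  stopifnot(length_s > 0, hop_s > 0, fs > 0)
  n <- length_s * fs
  if (abs(n - round(n)) > 1e-9) {
    stop("`length_s * fs` must be a positive integer", call. = FALSE)
  }
  structure(list(length_s = length_s, hop_s = hop_s, fs = fs,
                 n_samples = as.integer(round(n))),
            class = "window_spec")
}

#' @export
print.window_spec <- function(x, ...) {
  cat(sprintf("<window_spec> W = %g s, hop = %g s @ %g Hz (%d samples)\n",
              x$length_s, x$hop_s, x$fs, x$n_samples))
  invisible(x)
}

#' Segment a recording into windows
#'
#' @param rec an [eeg_recording()].
#' @param spec a [window_spec()]; its `fs` must match the recording.
#' @return A list with `starts_s` (window start times, relative to recording
#'   start) and `blocks` (list of channels-by-samples matrices). A recording
#'   shorter than one window yields zero windows with a warning; a trailing
#'   partial window is dropped.
#' @export
segment_windows <- function(rec, spec) {
  stopifnot(inherits(rec, "eeg_recording"), inherits(spec, "window_spec"))
  if (spec$fs != rec$fs) {
    stop("window spec fs does not match recording fs", call. = FALSE)
  }
  L <- spec$n_samples
  hop <- spec$hop_s * rec$fs
  if (abs(hop - round(hop)) > 1e-9) stop("`hop_s * fs` must be an integer", call. = FALSE)
  hop <- as.integer(round(hop))
  n <- n_samples(rec)
  if (n < L) {
    warning("recording shorter than one window; no windows produced")
    return(list(starts_s = numeric(), blocks = list()))
  }
  starts <- seq(0L, n - L, by = hop)
  list(
    starts_s = starts / rec$fs,
    blocks = lapply(starts, function(s) rec$data[, (s + 1):(s + L), drop = FALSE])
  )
}

# one orthonormal Haar analysis step: input matrix rows = independent signals
# with an even number of columns; returns list(a =, d =) halved matrices.
haar_step <- function(m) {
  odd <- m[, seq(1, ncol(m), by = 2), drop = FALSE]
  even <- m[, seq(2, ncol(m), by = 2), drop = FALSE]
  list(a = (odd + even) / sqrt(2), d = (odd - even) / sqrt(2))
}

# symmetric (repeat-last) extension to even length, applied per level
pad_even <- function(m) {
  if (ncol(m) %% 2 == 1) cbind(m, m[, ncol(m), drop = FALSE]) else m
}

#' Haar wavelet detail energies
#'
#' Decomposes a signal with the orthonormal Haar filter pair (coefficients
#' ±1/sqrt(2)) and returns the energy (sum of squares) of the detail
#' coefficients at each level, level 1 (highest frequency band) first. With
#' this normalization the detail energies plus the final approximation energy
#' equal the signal energy exactly (Parseval) for lengths divisible by
#' `2^levels`; other lengths use repeat-last symmetric extension per level,
#' with boundary coefficients included in the energy.
#'
#' @param x numeric vector, `length(x) >= 2^levels`.
#' @param levels decomposition depth (default 4, the depth used by the
#'   detectors: at 250 Hz the four detail bands are roughly 62–125, 31–62,
#'   16–31 and 8–16 Hz).
#' @param return_approx also return the final approximation energy
#'   (for energy-conservation checks).
#' @return Numeric vector of `levels` energies, or, with
#'   `return_approx = TRUE`, `levels + 1` values (approximation last).
#' @examples
#' dwt_detail_energies(rep(1, 16))            # constant: all zero
#' dwt_detail_energies(c(1, -1, 1, -1, 1, -1, 1, -1), levels = 2)
#' @export
dwt_detail_energies <- function(x, levels = 4, return_approx = FALSE) {
  stopifnot(is.numeric(x), levels >= 1)
  if (length(x) < 2^levels) {
    stop(sprintf("signal of length %d too short for a %d-level decomposition",
                 length(x), levels), call. = FALSE)
  }
  m <- matrix(x, nrow = 1)
  e <- numeric(levels)
  for (j in seq_len(levels)) {
    s <- haar_step(pad_even(m))
    e[j] <- sum(s$d^2)
    m <- s$a
  }
  if (return_approx) c(e, sum(m^2)) else e
}

# all-windows variant: rows of `w` are windows of one channel
dwt_energies_matrix <- function(w, levels = 4) {
  out <- matrix(0, nrow = nrow(w), ncol = levels)
  m <- w
  for (j in seq_len(levels)) {
    s <- haar_step(pad_even(m))
    out[, j] <- rowSums(s$d^2)
    m <- s$a
  }
  out
}

#' FFT high-band energy
#'
#' Energy of the one-sided real-signal spectrum in bins with frequency
#' strictly above `cutoff`. Bin k (k = 0 .. floor(N/2)) sits at `k * fs / N`;
#' bin powers are `|X_k|^2 / N`, doubled for bins that are neither DC nor
#' Nyquist, so that summing all bins reproduces the signal energy `sum(x^2)`
#' (Parseval). High energy above 80 Hz is treated by the artifact detector as
#' evidence of non-cerebral (chiefly muscle) activity.
#'
#' @param x numeric vector, `length(x) >= 2`.
#' @param fs sampling rate in Hz; `fs / 2` must exceed `cutoff`.
#' @param cutoff band edge in Hz (default 80); strictly-above bins count.
#' @return Nonnegative scalar; 0 when no bin lies above the cutoff.
#' @examples
#' t <- (0:249) / 250
#' fft_highband_energy(sin(2 * pi * 100 * t), fs = 250)  # = N/2 = 125
#' @export
fft_highband_energy <- function(x, fs, cutoff = 80) {
  stopifnot(is.numeric(x), length(x) >= 2)
  if (cutoff >= fs / 2) {
    stop("`cutoff` must be below the Nyquist frequency fs/2", call. = FALSE)
  }
  n <- length(x)
  sp <- onesided_power(matrix(x, nrow = 1), fs)
  sum(sp$power[1, sp$freq > cutoff])
}

# one-sided Parseval-normalized power for each row of `w`
onesided_power <- function(w, fs) {
  n <- ncol(w)
  ft <- t(stats::mvfft(t(w)))
  half <- floor(n / 2)
  idx <- 1:(half + 1)
  p <- Mod(ft[, idx, drop = FALSE])^2 / n
  mult <- rep(2, half + 1)
  mult[1] <- 1
  if (n %% 2 == 0) mult[half + 1] <- 1
  list(freq = (idx - 1) * fs / n, power = sweep(p, 2, mult, `*`))
}

#' Build the window-by-feature matrix
#'
#' For every complete window and every channel: the 4 Haar detail-band
#' energies, plus (optionally) the FFT energy above 80 Hz. Columns are
#' channel-major (`<channel>_dwt_d1..d4`, then `<channel>_fft_high`), names
#' sanitized from channel labels. The seizure detector uses the DWT features
#' alone; the artifact detector adds the FFT band.
#'
#' @param rec an [eeg_recording()].
#' @param spec a [window_spec()].
#' @param use_fft include the high-band FFT feature (default `TRUE`).
#' @param levels DWT depth (default 4).
#' @param cutoff FFT band edge in Hz (default 80).
#' @return A tibble: `record_id`, `window_start_s`, then feature columns.
#' @examples
#' rec <- eeg_recording(matrix(rnorm(4 * 2500), 4), 250,
#'                      c("F7-T7", "T7-P7", "F8-T8", "T8-P8"))
#' build_feature_matrix(rec, window_spec(4, 250))
#' @export
build_feature_matrix <- function(rec, spec, use_fft = TRUE, levels = 4,
                                 cutoff = 80) {
  seg <- segment_windows(rec, spec)
  nw <- length(seg$starts_s)
  nch <- n_channels(rec)
  per_ch <- levels + as.integer(use_fft)
  vals <- matrix(0, nrow = nw, ncol = nch * per_ch)
  nms <- character(nch * per_ch)
  clean <- gsub("[^A-Za-z0-9]+", ".", rec$channel_names)
  if (nw > 0) {
    # window rows per channel, vectorized across windows
    for (ci in seq_len(nch)) {
      w <- do.call(rbind, lapply(seg$blocks, function(b) b[ci, ]))
      cols <- (ci - 1) * per_ch + seq_len(levels)
      vals[, cols] <- dwt_energies_matrix(w, levels)
      if (use_fft) {
        sp <- onesided_power(w, rec$fs)
        vals[, (ci - 1) * per_ch + levels + 1] <-
          rowSums(sp$power[, sp$freq > cutoff, drop = FALSE])
      }
    }
  }
  for (ci in seq_len(nch)) {
    nms[(ci - 1) * per_ch + seq_len(levels)] <-
      paste0(clean[ci], "_dwt_d", seq_len(levels))
    if (use_fft) nms[(ci - 1) * per_ch + levels + 1] <- paste0(clean[ci], "_fft_high")
  }
  colnames(vals) <- nms
  dplyr::bind_cols(
    tibble::tibble(record_id = rec$record_id, window_start_s = seg$starts_s),
    tibble::as_tibble(vals)
  )
}

#' Feature-matrix helpers
#'
#' `feature_columns()` returns the names of feature columns (everything except
#' the `record_id` / `window_start_s` bookkeeping columns);
#' `feature_values()` the numeric matrix.
#'
#' @param fm a feature tibble from [build_feature_matrix()].
#' @export
feature_columns <- function(fm) setdiff(names(fm), c("record_id", "window_start_s"))

#' @rdname feature_columns
#' @export
feature_values <- function(fm) as.matrix(fm[, feature_columns(fm), drop = FALSE])

#' Derive per-window labels from interval annotations
#'
#' Seizure labels follow the strict-majority rule: a window is ictal when
#' seizure intervals cover more than 50% of it. Artifact labels follow the
#' any-overlap rule: a (window, channel) is an artifact when any artifact
#' interval on that channel intersects the window (global artifact entries
#' count on every channel); `bc` is the any-channel OR of `mc`. `mmc` carries
#' the artifact code per (window, channel); when several artifact types touch
#' one (window, channel) the largest overlap wins, ties to the lower code.
#' A `rule` switch allows majority labelling for artifacts in sensitivity
#' analyses.
#'
#' @param track an `eeg_labels` annotation track.
#' @param spec a [window_spec()].
#' @param n_windows number of windows (rows of the feature matrix).
#' @param n_channels channel count for per-channel labels.
#' @param rule artifact windowing rule, `"any"` (default) or `"majority"`.
#' @return A list with `seizure` (0/1 vector), `bc` (0/1 vector),
#'   `mc` (windows x channels 0/1 matrix) and `mmc` (windows x channels
#'   integer code matrix).
#' @export
label_windows <- function(track, spec, n_windows, n_channels = 4,
                          rule = c("any", "majority")) {
  stopifnot(inherits(track, "eeg_labels"), inherits(spec, "window_spec"))
  rule <- match.arg(rule)
  W <- spec$length_s
  starts <- (seq_len(n_windows) - 1) * spec$hop_s
  e <- track$entries
  voc <- stats::setNames(track$vocabulary$code, track$vocabulary$label)
  seiz <- integer(n_windows)
  mc <- matrix(0L, n_windows, n_channels)
  mmc <- matrix(0L, n_windows, n_channels)
  if (nrow(e) > 0) {
    se <- e[e$label == "seizure", , drop = FALSE]
    ar <- e[e$label != "seizure" & e$label != "bckg", , drop = FALSE]
    for (w in seq_len(n_windows)) {
      a0 <- starts[w]; a1 <- a0 + W
      if (nrow(se) > 0) {
        ov <- interval_overlap(a0, a1, se$start_s, se$end_s)
        seiz[w] <- as.integer(ov > W / 2)  # strictly more than 50%
      }
      if (nrow(ar) == 0) next
      touching <- which(ar$start_s < a1 & ar$end_s > a0)
      if (length(touching) == 0) next
      for (ch in seq_len(n_channels)) {
        rows <- touching[is.na(ar$channel[touching]) |
                           ar$channel[touching] + 1L == ch]
        if (length(rows) == 0) next
        ov <- pmin(a1, ar$end_s[rows]) - pmax(a0, ar$start_s[rows])
        keep <- if (rule == "any") ov > 0 else ov > W / 2
        rows <- rows[keep]; ov <- ov[keep]
        if (length(rows) == 0) next
        codes <- unname(voc[ar$label[rows]])
        best <- order(-ov, codes)[1]  # largest overlap, ties to lower code
        mc[w, ch] <- 1L
        mmc[w, ch] <- codes[best]
      }
    }
  }
  list(seizure = seiz, bc = as.integer(rowSums(mc) > 0), mc = mc, mmc = mmc)
}
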