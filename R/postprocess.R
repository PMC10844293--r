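#' Majority-vote smoothing of per-window predictions
#'
#' Averages k successive binary decisions by majority vote, acting as a
#' low-pass filter on the classifier output: isolated positives are removed
#' and short gaps inside long events are filled, at the price of one window of
#' added decision latency (for the default centered k = 3, each time point
#' considers one window backward and one forward). The causal variant uses
#' only the current and previous k−1 decisions, preserving causality for
#' on-line operation. Edges use the available votes only; ties resolve to 0
#' (conservative toward fewer alarms).
#'
#' @param pred binary (0/1) vector of per-window predictions.
#' @param k odd vote count, >= 1 (default 3).
#' @param mode `"centered"` (default) or `"causal"`.
#' @return Binary vector of the same length.
#' @examples
#' smooth_majority(c(0, 0, 1, 0, 0))        # isolated alarm removed
#' smooth_majority(c(0, 1, 1, 1, 0))        # run preserved
#' @export
smooth_majority <- function(pred, k = 3, mode = c("centered", "causal")) {
  mode <- match.arg(mode)
  stopifnot(k >= 1, k %% 2 == 1)
  n <- length(pred)
  if (n == 0) return(integer(0))
  pred <- as.integer(pred != 0)
  out <- integer(n)
  h <- (k - 1L) %/% 2L
  for (t in seq_len(n)) {
    if (mode == "centered") {
      lo <- max(1L, t - h); hi <- min(n, t + h)
    } else {
      lo <- max(1L, t - k + 1L); hi <- t
    }
    votes <- pred[lo:hi]
    out[t] <- as.integer(sum(votes) > length(votes) / 2)  # ties -> 0
  }
  out
}

#' Detection events from smoothed window decisions
#'
#' Maximal runs of positive windows become half-open time intervals
#' `[onset_s, offset_s)` on the window grid.
#'
#' @param smoothed binary vector of per-window decisions.
#' @param spec the [window_spec()] that produced the windows.
#' @return A tibble with columns `onset_s`, `offset_s`.
#' @examples
#' events_from_windows(c(0, 0, 0, 1, 1, 1, 0), window_spec(4, 250))
#' @export
events_from_windows <- function(smoothed, spec) {
  stopifnot(inherits(spec, "window_spec"))
  smoothed <- as.integer(smoothed != 0)
  if (length(smoothed) == 0 || all(smoothed == 0)) {
    return(tibble::tibble(onset_s = numeric(), offset_s = numeric()))
  }
  r <- rle(smoothed)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  pos <- r$values == 1
  tibble::tibble(
    onset_s = (starts[pos] - 1) * spec$hop_s,
    offset_s = (ends[pos] - 1) * spec$hop_s + spec$length_s
  )
}

#' Added detection latency from gated onset windows
#'
#' When the artifact gate suppresses the leading windows of a seizure, the
#' alarm is delayed by that many window lengths: `count * length_s` seconds
#' (1.2 suppressed 4-second windows per event is 4.8 s of added latency).
#'
#' @param leading_suppressed mean number of gated windows at seizure onset
#'   (>= 0).
#' @param spec a [window_spec()].
#' @return Seconds of added latency.
#' @export
added_latency <- function(leading_suppressed, spec) {
  stopifnot(inherits(spec, "window_spec"), leading_suppressed >= 0)
  leading_suppressed * spec$length_s
}
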