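#' False alarms per hour from specificity
#'
#' With one decision per W-second window, an hour holds 3600/W windows, so a
#' specificity Sp converts to `3600/W * (1 - Sp)` false positives per hour:
#' 99% specificity at W = 2 s is already 18 FP/h, which is why specificity
#' alone understates the false-alarm burden of a wearable detector.
#'
#' @param sp_pct specificity in percent (0–100).
#' @param window_s window length W in seconds (> 0).
#' @return FP/h.
#' @examples
#' fp_per_hour_from_specificity(99, 2)       # 18
#' fp_per_hour_from_specificity(95.66, 3)    # 52.08
#' @export
fp_per_hour_from_specificity <- function(sp_pct, window_s) {
  if (any(window_s <= 0)) stop("`window_s` must be positive", call. = FALSE)
  stopifnot(all(sp_pct >= 0 & sp_pct <= 100))
  (3600 / window_s) * (1 - sp_pct / 100)
}

#' Window-level sensitivity and specificity
#'
#' Sensitivity = TP/(TP+FN), specificity = TN/(TN+FP), in percent. When a
#' class is absent from the truth the corresponding metric is undefined and
#' reported as `NA`.
#'
#' @param y_true,y_pred equal-length binary vectors.
#' @return Named list: `sensitivity_pct`, `specificity_pct`, and the four
#'   counts `tp`, `fn`, `tn`, `fp`.
#' @examples
#' window_metrics(c(1, 1, 0, 0), c(1, 0, 0, 0))
#' @export
window_metrics <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) {
    stop("`y_true` and `y_pred` must have equal length", call. = FALSE)
  }
  y_true <- as.integer(y_true != 0); y_pred <- as.integer(y_pred != 0)
  tp <- sum(y_true == 1 & y_pred == 1); fn <- sum(y_true == 1 & y_pred == 0)
  tn <- sum(y_true == 0 & y_pred == 0); fp <- sum(y_true == 0 & y_pred == 1)
  list(
    sensitivity_pct = if (tp + fn > 0) 100 * tp / (tp + fn) else NA_real_,
    specificity_pct = if (tn + fp > 0) 100 * tn / (tn + fp) else NA_real_,
    tp = tp, fn = fn, tn = tn, fp = fp
  )
}

#' F1 scores
#'
#' `binary`: the positive-class F1, `2PR/(P+R)`. `weighted`: per-class F1
#' averaged with each class's support as weight (the convention for the
#' per-channel multiclass artifact task, where class imbalance is large).
#'
#' @param y_true,y_pred equal-length label vectors (0/1 for binary; any codes
#'   for weighted).
#' @param weighting `"binary"` or `"weighted"`.
#' @return Scalar in \[0, 1\].
#' @examples
#' f1_scores(c(1, 0, 1, 0), c(1, 1, 1, 1))   # P = 0.5, R = 1 -> 2/3
#' @export
f1_scores <- function(y_true, y_pred, weighting = c("binary", "weighted")) {
  weighting <- match.arg(weighting)
  if (length(y_true) != length(y_pred)) {
    stop("`y_true` and `y_pred` must have equal length", call. = FALSE)
  }
  f1_one <- function(cls) {
    tp <- sum(y_true == cls & y_pred == cls)
    fp <- sum(y_true != cls & y_pred == cls)
    fn <- sum(y_true == cls & y_pred != cls)
    if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
  }
  if (weighting == "binary") {
    f1_one(1)
  } else {
    classes <- sort(unique(y_true))
    support <- vapply(classes, function(c) sum(y_true == c), numeric(1))
    sum(vapply(classes, f1_one, numeric(1)) * support) / sum(support)
  }
}

#' Record-level cross-validation splits
#'
#' Records carry a temporal order (their position in `record_ids`). Three
#' schemes: `loocv` — every eligible record once as test, all others train;
#' `wfcv` (walk-forward) — test record r trains only on records strictly
#' earlier in time (the first record is never a test record); `rwcv` (rolling
#' window) — like walk-forward but training is restricted to the `rw_span`
#' records immediately preceding the test record, so that long-past records
#' are not trained on.
#'
#' @param record_ids character vector of record identities in temporal order.
#' @param scheme `"loocv"`, `"wfcv"` or `"rwcv"`.
#' @param rw_span rolling-window training span (records; default 3).
#' @param eligible optional subset of `record_ids` allowed as test records
#'   (for seizure work, the records that contain seizures; the rest join
#'   every LOOCV training set).
#' @return A list of `list(train = ..., test = ...)` id splits.
#' @examples
#' cv_splits(c("A", "B", "C"), "wfcv")
#' cv_splits(c("A", "B", "C", "D"), "rwcv", rw_span = 2)
#' @export
cv_splits <- function(record_ids, scheme = c("loocv", "wfcv", "rwcv"),
                      rw_span = 3, eligible = NULL) {
  scheme <- match.arg(scheme)
  record_ids <- as.character(record_ids)
  if (length(record_ids) < 2) stop("need at least 2 records", call. = FALSE)
  if (anyDuplicated(record_ids)) stop("record ids must be unique", call. = FALSE)
  if (is.null(eligible)) eligible <- record_ids
  n <- length(record_ids)
  splits <- list()
  for (i in seq_len(n)) {
    r <- record_ids[i]
    if (!r %in% eligible) next
    train <- switch(scheme,
      loocv = record_ids[-i],
      wfcv = if (i >= 2) record_ids[seq_len(i - 1)],
      rwcv = {
        stopifnot(rw_span >= 1)
        if (i > rw_span) record_ids[(i - rw_span):(i - 1)]
      })
    if (is.null(train)) next
    splits[[length(splits) + 1]] <- list(train = train, test = r)
  }
  splits
}

#' Window- and event-level metrics report
#'
#' The full evaluation of a detector run: per-record and aggregate window
#' sensitivity/specificity, false alarms per hour (both from direct FP
#' counting against monitored hours and from the 3600/W specificity formula —
#' the two agree by construction), event-level sensitivity (a true event
#' counts as detected when any positive window overlaps it) and mean
#' detection latency from event onset. Raw and smoothed predictions can both
#' be reported by calling this twice.
#'
#' @param y_true,y_pred equal-length binary window vectors.
#' @param spec the [window_spec()] behind the windows.
#' @param record_ids optional per-window record identities for the per-record
#'   breakdown.
#' @param true_events optional tibble of true events (`onset_s`, `offset_s`,
#'   per record in `record_id` if given) for event-level metrics.
#' @return An object of class `eeg_metrics`; see [tidy.eeg_metrics()] /
#'   [glance.eeg_metrics()].
#' @export
metrics_report <- function(y_true, y_pred, spec, record_ids = NULL,
                           true_events = NULL) {
  stopifnot(inherits(spec, "window_spec"))
  if (is.null(record_ids)) record_ids <- rep("all", length(y_true))
  per <- dplyr::group_split(
    tibble::tibble(record_id = record_ids, y = as.integer(y_true != 0),
                   p = as.integer(y_pred != 0)),
    .data$record_id)
  rows <- lapply(per, function(d) {
    m <- window_metrics(d$y, d$p)
    hours <- nrow(d) * spec$length_s / 3600
    tibble::tibble(
      record_id = d$record_id[1], n_windows = nrow(d),
      sensitivity_pct = m$sensitivity_pct, specificity_pct = m$specificity_pct,
      fp = m$fp, fp_per_hour = m$fp / hours
    )
  })
  per_record <- dplyr::bind_rows(rows)
  m <- window_metrics(y_true, y_pred)
  hours <- length(y_true) * spec$length_s / 3600
  ev <- NULL
  if (!is.null(true_events) && nrow(true_events) > 0) {
    if (!"record_id" %in% names(true_events)) {
      true_events$record_id <- "all"
    }
    det <- lapply(split(seq_along(y_pred), record_ids), function(ix) {
      e <- events_from_windows(y_pred[ix], spec)
      e$record_id <- record_ids[ix[1]]
      e
    })
    det <- dplyr::bind_rows(det)
    hit <- logical(nrow(true_events)); lat <- rep(NA_real_, nrow(true_events))
    for (i in seq_len(nrow(true_events))) {
      d <- det[det$record_id == true_events$record_id[i], , drop = FALSE]
      ov <- d$onset_s < true_events$offset_s[i] &
        d$offset_s > true_events$onset_s[i]
      hit[i] <- any(ov)
      if (hit[i]) {
        lat[i] <- max(0, min(d$onset_s[ov]) - true_events$onset_s[i])
      }
    }
    ev <- list(n_events_true = nrow(true_events), n_events_detected = sum(hit),
               event_sensitivity_pct = 100 * mean(hit),
               latency_s = if (any(hit)) mean(lat[hit]) else NA_real_)
  }
  structure(list(
    window = list(sensitivity_pct = m$sensitivity_pct,
                  specificity_pct = m$specificity_pct,
                  fp = m$fp, n_windows = length(y_true),
                  fp_per_hour = m$fp / hours,
                  fp_per_hour_formula = if (!is.na(m$specificity_pct)) {
                    fp_per_hour_from_specificity(m$specificity_pct, spec$length_s)
                  } else NA_real_),
    events = ev, per_record = per_record, spec = spec
  ), class = "eeg_metrics")
}

#' @export
print.eeg_metrics <- function(x, ...) {
  w <- x$window
  cat(sprintf("<eeg_metrics> %d windows @ W = %g s\n", w$n_windows,
              x$spec$length_s))
  cat(sprintf("  sensitivity %.2f%%  specificity %.2f%%  FP/h %.2f\n",
              w$sensitivity_pct, w$specificity_pct, w$fp_per_hour))
  if (!is.null(x$events)) {
    cat(sprintf("  events: %d/%d detected (%.1f%%), mean onset latency %.1f s\n",
                x$events$n_events_detected, x$events$n_events_true,
                x$events$event_sensitivity_pct, x$events$latency_s))
  }
  invisible(x)
}

#' Tidy / summarize a metrics report
#'
#' `tidy()` returns the per-record breakdown; `glance()` the one-row
#' aggregate.
#'
#' @param x an `eeg_metrics` object.
#' @param ... unused.
#' @return A tibble.
#' @export
tidy.eeg_metrics <- function(x, ...) x$per_record

#' @rdname tidy.eeg_metrics
#' @export
glance.eeg_metrics <- function(x, ...) {
  out <- tibble::as_tibble(x$window)
  if (!is.null(x$events)) out <- dplyr::bind_cols(out, tibble::as_tibble(x$events))
  out
}

#' Normal-approximation 95% confidence interval across records
#'
#' Mean ± 1.96 sd/sqrt(n) over per-record metric values (NA values dropped).
#'
#' @param values numeric vector of per-record metric values.
#' @return Named vector `mean`, `half_width`.
#' @export
ci95 <- function(values) {
  v <- values[!is.na(values)]
  c(mean = mean(v),
    half_width = if (length(v) > 1) 1.96 * stats::sd(v) / sqrt(length(v)) else 0)
}

#' Plot a metrics report
#'
#' Per-record sensitivity and FP/h bars.
#'
#' @param object an `eeg_metrics`.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.eeg_metrics <- function(object, ...) {
  df <- tidyr::pivot_longer(object$per_record,
                            c("sensitivity_pct", "fp_per_hour"),
                            names_to = "metric", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$record_id, y = .data$value)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::facet_wrap(ggplot2::vars(.data$metric), scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}
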