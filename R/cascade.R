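#' Fit a feature scaler on a training source
#'
#' When the artifact and seizure detectors are trained on different sources,
#' amplitude conventions differ and three normalization regimes are compared:
#' `none` (raw), `minmax` (each feature mapped to \[0, 1\] on its fit source)
#' and `zscore` (mean 0, sd 1 on its fit source). A scaler is fitted once on
#' a classifier's own training data and then applied, frozen, to whatever
#' data that classifier later receives.
#'
#' @param X feature tibble or matrix (the training source).
#' @param kind `"none"`, `"minmax"` or `"zscore"`.
#' @return An object of class `feature_scaler`.
#' @export
fit_scaler <- function(X, kind = c("none", "minmax", "zscore")) {
  kind <- match.arg(kind)
  Xm <- if (is.matrix(X)) X else feature_values(X)
  if (kind == "zscore" && nrow(Xm) < 2) {
    stop("zscore scaling needs at least 2 rows", call. = FALSE)
  }
  par <- switch(kind,
    none = list(),
    minmax = {
      mn <- apply(Xm, 2, min); mx <- apply(Xm, 2, max)
      rng <- mx - mn
      rng[rng == 0] <- 1           # constant feature maps to 0
      list(min = mn, range = rng)
    },
    zscore = {
      mu <- colMeans(Xm); sd <- apply(Xm, 2, stats::sd)
      sd[sd == 0] <- 1             # constant feature: sd treated as 1
      list(mean = mu, sd = sd)
    })
  structure(list(kind = kind, par = par, n_features = ncol(Xm)),
            class = "feature_scaler")
}

#' @export
print.feature_scaler <- function(x, ...) {
  cat(sprintf("<feature_scaler> %s over %d feature(s)\n", x$kind, x$n_features))
  invisible(x)
}

#' Apply a fitted scaler
#'
#' Uses the frozen fit-source parameters only; never refits.
#'
#' @param scaler a [fit_scaler()] result.
#' @param X feature tibble or matrix.
#' @return Same shape as `X` (tibble in, tibble out).
#' @export
apply_scaler <- function(scaler, X) {
  stopifnot(inherits(scaler, "feature_scaler"))
  is_tbl <- !is.matrix(X)
  Xm <- if (is_tbl) feature_values(X) else X
  if (ncol(Xm) != scaler$n_features) {
    stop("feature count does not match the scaler's fit source", call. = FALSE)
  }
  out <- switch(scaler$kind,
    none = Xm,
    minmax = sweep(sweep(Xm, 2, scaler$par$min), 2, scaler$par$range, `/`),
    zscore = sweep(sweep(Xm, 2, scaler$par$mean), 2, scaler$par$sd, `/`))
  if (!is_tbl) return(out)
  X[, feature_columns(X)] <- tibble::as_tibble(out)
  X
}

# majority vote over the non-rejected decisions of each window's
# neighborhood; a window the gate fired on is itself never an alarm
gated_majority <- function(raw, gate, k, mode) {
  n <- length(raw)
  h <- (k - 1) %/% 2
  out <- logical(n)
  for (t in seq_len(n)) {
    if (gate[t] == 1) next
    idx <- if (mode == "centered") {
      max(1, t - h):min(n, t + h)
    } else {
      max(1, t - k + 1):t
    }
    idx <- idx[gate[idx] == 0]
    out[t] <- sum(raw[idx]) > length(idx) / 2
  }
  out
}

# binary per-window artifact flags from a BC model or per-channel MC list
artifact_flags <- function(model, X, threshold = 0.5) {
  if (inherits(model, "gbt_channel_models")) {
    per_ch <- vapply(model, function(m) {
      if (inherits(m, "gbt_constant")) {
        rep(as.integer(m$value != 0), nrow(X))
      } else if (m$task == "binary") {
        as.integer(predict(m, X, type = "prob") > threshold)
      } else {
        as.integer(predict(m, X, type = "class") != 0)
      }
    }, integer(nrow(X)))
    as.integer(rowSums(per_ch) > 0)     # any-channel-flagged fires the gate
  } else if (inherits(model, "gbt_constant")) {
    rep(as.integer(model$value != 0), nrow(X))
  } else {
    as.integer(predict(model, X, type = "prob") > threshold)
  }
}

#' Run the artifact-gated seizure cascade
#'
#' Per window: the artifact classifier A (behind its own scaler) is consulted
#' first; a flagged window receives the verdict `artifact` and can never raise
#' a seizure alarm. Remaining windows are decided by the seizure classifier S
#' (behind its own scaler, with majority-vote smoothing of its binary
#' output). Gated windows count as non-seizure, so adding the gate can only
#' remove seizure false positives, never add them.
#'
#' @param X feature tibble or matrix (un-scaled; each classifier applies its
#'   own scaler).
#' @param artifact list `(model =, scaler =)` for classifier A; model may be a
#'   BC `gbt_ensemble` or a per-channel `gbt_channel_models`.
#' @param seizure list `(model =, scaler =)` for classifier S.
#' @param smoothing list `(k =, mode =)` for [smooth_majority()]; `NULL`
#'   disables smoothing.
#' @param threshold decision threshold for both classifiers.
#' @details Gating happens on S's raw per-window decisions, before the
#'   majority vote, and a gated window counts as rejected data rather than
#'   as a "no" vote: the vote runs over the remaining decisions in the
#'   neighborhood (the same rule the smoother applies at sequence edges).
#'   Temporally scattered gate fires inside a genuine seizure therefore cost
#'   nothing, while a block of fires at seizure onset delays the alarm, and
#'   false alarms outside seizures — whose windows the artifact model flags
#'   directly — are removed. The output is intersected with the ungated
#'   smoothed alarm set, so the gate can only ever remove alarms, never add
#'   one.
#' @return A tibble with one row per window: `artifact_score` (NA for MC
#'   gates), `gate_fired`, `seizure_prob`, `seizure_raw` (S alone, raw),
#'   `seizure_smoothed` (S alone, smoothed — the ungated baseline),
#'   `seizure_gated` (the cascade output), `verdict` (factor
#'   normal/artifact/seizure; a seizure verdict is only possible where the
#'   gate did not fire).
#' @export
cascade_predict <- function(X, artifact, seizure,
                            smoothing = list(k = 3, mode = "centered"),
                            threshold = 0.5) {
  Xa <- if (is.null(artifact$scaler)) X else apply_scaler(artifact$scaler, X)
  Xs <- if (is.null(seizure$scaler)) X else apply_scaler(seizure$scaler, X)
  gate <- artifact_flags(artifact$model, Xa, threshold)
  a_score <- if (inherits(artifact$model, "gbt_ensemble") &&
                 artifact$model$task == "binary") {
    predict(artifact$model, Xa, type = "prob")
  } else NA_real_
  s_prob <- predict(seizure$model, Xs, type = "prob")
  s_raw <- as.integer(s_prob > threshold)
  sm <- function(p) {
    if (is.null(smoothing)) p else {
      smooth_majority(p, k = smoothing$k, mode = smoothing$mode)
    }
  }
  s_smooth <- sm(s_raw)
  s_gated <- as.integer(
    s_smooth == 1 & gate == 0 &
      gated_majority(s_raw, gate,
                     k = if (is.null(smoothing)) 1 else smoothing$k,
                     mode = if (is.null(smoothing)) "centered" else smoothing$mode))
  verdict <- ifelse(gate == 1, "artifact",
                    ifelse(s_gated == 1, "seizure", "normal"))
  tibble::tibble(
    artifact_score = a_score, gate_fired = gate == 1,
    seizure_prob = s_prob, seizure_raw = s_raw, seizure_smoothed = s_smooth,
    seizure_gated = s_gated,
    verdict = factor(verdict, levels = c("normal", "artifact", "seizure"))
  )
}

#' Cross-feed analysis of the combined detectors
#'
#' Answers the two questions behind the combination study: are artifacts
#' classified as seizures (and does the gate remove those false alarms), and
#' are seizures classified as artifacts (costing sensitivity or only
#' latency)? Feeds artifact-source windows through the seizure classifier
#' with and without the gate, and seizure-source windows through the artifact
#' classifier.
#'
#' @param artifact_data list `(X =, bc =)`: artifact-source features and
#'   window-global binary artifact truth.
#' @param seizure_data list `(X =, seizure =)`: seizure-source features and
#'   binary seizure truth.
#' @param artifact,seizure classifier bundles as in [cascade_predict()].
#' @param spec the [window_spec()] (for FP/h and latency conversion).
#' @param smoothing,threshold as in [cascade_predict()].
#' @param onset_group_windows a gated seizure window counts as "onset-grouped"
#'   when it lies within this many windows of its event start (default 3);
#'   later gated windows count as temporally scattered.
#' @return An object of class `cross_feed_report` (a list of tibbles and
#'   scalars; see `print()` / `tidy()`).
#' @export
cross_feed_report <- function(artifact_data, seizure_data, artifact, seizure,
                              spec, smoothing = list(k = 3, mode = "centered"),
                              threshold = 0.5, onset_group_windows = 3) {
  stopifnot(inherits(spec, "window_spec"))
  # (i) artifact-source windows through S, with and without the gate
  ca <- cascade_predict(artifact_data$X, artifact, seizure, smoothing,
                        threshold)
  is_art <- artifact_data$bc == 1
  fp_ungated <- sum(ca$seizure_smoothed == 1 & is_art)
  fp_gated <- sum(ca$seizure_gated == 1 & is_art)
  hours_art <- sum(is_art) * spec$length_s / 3600
  improvement_pct <- if (fp_ungated > 0) {
    100 * (1 - fp_gated / fp_ungated)
  } else NA_real_
  normal_alarm_pct_ungated <- if (any(!is_art)) {
    100 * mean(ca$seizure_smoothed[!is_art] == 1)
  } else NA_real_
  normal_alarm_pct_gated <- if (any(!is_art)) {
    100 * mean(ca$seizure_gated[!is_art] == 1)
  } else NA_real_
  # (ii) seizure-source windows through A
  Xs <- seizure_data$X
  Xa2 <- if (is.null(artifact$scaler)) Xs else apply_scaler(artifact$scaler, Xs)
  flags <- artifact_flags(artifact$model, Xa2, threshold)
  is_seiz <- seizure_data$seizure == 1
  seiz_as_artifact_pct <- if (any(is_seiz)) {
    100 * mean(flags[is_seiz] == 1)
  } else NA_real_
  normal_as_artifact_pct <- if (any(!is_seiz)) {
    100 * mean(flags[!is_seiz] == 1)
  } else NA_real_
  # onset-grouped vs scattered split over seizure events, and onset latency
  r <- rle(as.integer(is_seiz))
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
  ev_start <- starts[r$values == 1]; ev_end <- ends[r$values == 1]
  onset_grouped <- 0L; scattered <- 0L; leading <- integer(0)
  for (e in seq_along(ev_start)) {
    win <- ev_start[e]:ev_end[e]
    fl <- flags[win] == 1
    onset_grouped <- onset_grouped + sum(fl[seq_len(min(onset_group_windows,
                                                        length(fl)))])
    if (length(fl) > onset_group_windows) {
      scattered <- scattered + sum(fl[-seq_len(onset_group_windows)])
    }
    lead <- match(FALSE, fl, nomatch = length(fl) + 1L) - 1L
    leading <- c(leading, lead)
  }
  mean_leading <- if (length(leading) > 0) mean(leading) else NA_real_
  structure(list(
    artifact_to_seizure = tibble::tibble(
      n_artifact_windows = sum(is_art),
      fp_ungated = fp_ungated, fp_gated = fp_gated,
      fp_per_hour_ungated = if (hours_art > 0) fp_ungated / hours_art else NA_real_,
      fp_per_hour_gated = if (hours_art > 0) fp_gated / hours_art else NA_real_,
      improvement_pct = improvement_pct,
      improvement_ratio = if (!is.na(improvement_pct) && fp_gated > 0) {
        fp_ungated / fp_gated
      } else NA_real_,
      normal_alarm_pct_ungated = normal_alarm_pct_ungated,
      normal_alarm_pct_gated = normal_alarm_pct_gated
    ),
    seizure_to_artifact = tibble::tibble(
      n_seizure_windows = sum(is_seiz),
      seiz_as_artifact_pct = seiz_as_artifact_pct,
      onset_grouped = onset_grouped, scattered = scattered,
      mean_leading_suppressed = mean_leading,
      added_latency_s = if (!is.na(mean_leading)) {
        added_latency(mean_leading, spec)
      } else NA_real_,
      normal_as_artifact_pct = normal_as_artifact_pct
    )
  ), class = "cross_feed_report")
}

#' @export
print.cross_feed_report <- function(x, ...) {
  a <- x$artifact_to_seizure; s <- x$seizure_to_artifact
  cat("<cross_feed_report>\n")
  cat(sprintf("  artifact windows -> seizure alarms: %d ungated, %d gated",
              a$fp_ungated, a$fp_gated))
  if (!is.na(a$improvement_pct)) {
    cat(sprintf(" (%.1f%% fewer", a$improvement_pct))
    if (!is.na(a$improvement_ratio)) {
      cat(sprintf(", %.1fx", a$improvement_ratio))
    }
    cat(")")
  } else {
    cat(" (improvement not applicable: no ungated alarms)")
  }
  cat("\n")
  cat(sprintf("  seizure windows flagged artifact: %.1f%% (%d onset-grouped, %d scattered)\n",
              s$seiz_as_artifact_pct, s$onset_grouped, s$scattered))
  cat(sprintf("  mean leading suppressed windows %.2f -> added latency %.1f s\n",
              s$mean_leading_suppressed, s$added_latency_s))
  cat(sprintf("  normal windows flagged artifact: %.1f%%\n",
              s$normal_as_artifact_pct))
  invisible(x)
}

#' @export
tidy.cross_feed_report <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::mutate(tidyr::pivot_longer(x$artifact_to_seizure,
                                      dplyr::everything()),
                  direction = "artifact_to_seizure"),
    dplyr::mutate(tidyr::pivot_longer(x$seizure_to_artifact,
                                      dplyr::everything()),
                  direction = "seizure_to_artifact")
  )
}
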