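#' Run the synthetic artifact-gated cascade study
#'
#' The desk-scale version of the two-dataset combination experiment: a
#' global seizure detector (classifier S) is trained on artifact-free
#' records from several synthetic patients — the situation of curated
#' epilepsy-monitoring-unit corpora, which carry almost no artifacts — while
#' an artifact detector (classifier A) is trained on artifact-rich,
#' seizure-free records, the situation of an artifact corpus. Both are then
#' run, each behind its own frozen scaler, on a held-out artifact-rich
#' record from an unseen patient containing both seizures and artifacts,
#' with and without the artifact gate in front of S. The global S is the
#' detector the combination experiment calls for: it is the model whose
#' false alarms on artifact-laden data the gate is there to remove (a
#' subject-specific detector is far less artifact-fallible to begin with;
#' see [separability_study()]).
#'
#' @param seed base RNG seed; every stochastic step derives from it.
#' @param window_s analysis window length W (s).
#' @param s_train_records,s_train_s count and length (s) of artifact-free
#'   seizure training records, one synthetic patient (ictal focus) each
#'   (default 12 x 1800 s: a global model generalizes to an unseen patient
#'   through the diversity of training foci — twelve half-hour patients
#'   beat six one-hour patients at equal data volume).
#' @param a_train_records,a_train_s count and length (s) of artifact-rich,
#'   seizure-free artifact training records (default 3 x 3600 s; the
#'   artifact detector needs a few hours before its background specificity
#'   transfers across records).
#' @param eval_s length of the held-out joint record.
#' @param scaling normalization regime for both classifiers
#'   (`"zscore"` default, `"minmax"`, `"none"`).
#' @param hyper a [gbt_hyper()] shared by both detectors.
#' @param smoothing smoothing config for [cascade_predict()].
#' @param threshold decision threshold.
#' @param cfg base [synth_config()]; the study derives the three source
#'   configurations from it (seizure rate zeroed for the artifact source,
#'   artifact rates zeroed for the seizure source).
#' @return A list: `ungated` and `gated` [metrics_report()]s against seizure
#'   truth on the held-out record, `cross_feed` ([cross_feed_report()]),
#'   `models` (S, A, scalers), `spec`, and a `summary` tibble of the headline
#'   numbers.
#' @export
cascade_study <- function(seed = 0, window_s = 4,
                          s_train_records = 12, s_train_s = 1800,
                          a_train_records = 3, a_train_s = 3600,
                          eval_s = 3600,
                          scaling = c("zscore", "minmax", "none"),
                          hyper = gbt_hyper(),
                          smoothing = list(k = 3, mode = "centered"),
                          threshold = 0.5,
                          cfg = synth_config()) {
  scaling <- match.arg(scaling)
  cfg_s <- cfg; cfg_s$duration_s <- s_train_s
  cfg_s$artifact_rates_per_h[] <- 0          # EMU-like: clean seizure source
  cfg_a <- cfg; cfg_a$duration_s <- a_train_s
  cfg_a$seizure_rate_per_h <- 0              # corpus-like: artifacts only
  cfg_e <- cfg; cfg_e$duration_s <- eval_s   # wearable-like: both
  # global-model setting: one focus per training patient, unseen eval patient
  cfg_e$seizure_focus <- sample_seizure_focus(record_substream_seed(seed, 8),
                                              cfg$seizure_band)
  spec <- window_spec(window_s, cfg$fs)

  featurize <- function(r) {
    fm <- build_feature_matrix(r$recording, spec, use_fft = TRUE)
    nlab_win <- nrow(fm)
    lab_s <- label_windows(r$seizures, spec, nlab_win, 4)
    lab_a <- label_windows(r$artifacts, spec, nlab_win, 4)
    list(fm = fm, seizure = lab_s$seizure, bc = lab_a$bc,
         events = r$seizures$entries)
  }

  s_train <- lapply(seq_len(s_train_records), function(i) {
    cfg_i <- cfg_s
    cfg_i$seizure_focus <- sample_seizure_focus(
      record_substream_seed(seed, 7 + 2 * i), cfg$seizure_band)
    featurize(gen_record(cfg_i, seed = record_substream_seed(seed, 11 + i),
                         record_id = sprintf("strain%02d", i)))
  })
  a_train <- lapply(gen_dataset(cfg_a, a_train_records,
                                seed = record_substream_seed(seed, 23),
                                id_prefix = "atrain"), featurize)
  eval_r <- featurize(gen_record(cfg_e,
                                 seed = record_substream_seed(seed, 37),
                                 record_id = "eval"))

  X_s <- dplyr::bind_rows(lapply(s_train, `[[`, "fm"))
  y_s <- unlist(lapply(s_train, `[[`, "seizure"))
  scaler_s <- fit_scaler(X_s, scaling)
  S <- train_detector(apply_scaler(scaler_s, X_s), y_s, hyper)

  X_a <- dplyr::bind_rows(lapply(a_train, `[[`, "fm"))
  scaler_a <- fit_scaler(X_a, scaling)
  A <- train_detector(apply_scaler(scaler_a, X_a),
                      unlist(lapply(a_train, `[[`, "bc")), hyper)

  casc <- cascade_predict(eval_r$fm,
                          artifact = list(model = A, scaler = scaler_a),
                          seizure = list(model = S, scaler = scaler_s),
                          smoothing = smoothing, threshold = threshold)
  truth <- eval_r$seizure
  ev <- eval_r$events[, c("start_s", "end_s")]
  names(ev) <- c("onset_s", "offset_s")
  ungated <- metrics_report(truth, casc$seizure_smoothed, spec,
                            true_events = ev)
  gated <- metrics_report(truth, casc$seizure_gated, spec, true_events = ev)

  cross <- cross_feed_report(
    artifact_data = list(X = eval_r$fm, bc = eval_r$bc),
    seizure_data = list(X = eval_r$fm, seizure = truth),
    artifact = list(model = A, scaler = scaler_a),
    seizure = list(model = S, scaler = scaler_s),
    spec = spec, smoothing = smoothing, threshold = threshold)

  summary <- tibble::tibble(
    scaling = scaling, window_s = window_s,
    sensitivity_pct = ungated$window$sensitivity_pct,
    specificity_pct = ungated$window$specificity_pct,
    fp_per_hour_ungated = ungated$window$fp_per_hour,
    fp_per_hour_gated = gated$window$fp_per_hour,
    fp_reduction_pct = if (ungated$window$fp > 0) {
      100 * (1 - gated$window$fp / ungated$window$fp)
    } else NA_real_,
    event_sensitivity_ungated_pct = ungated$events$event_sensitivity_pct,
    event_sensitivity_gated_pct = gated$events$event_sensitivity_pct
  )
  list(ungated = ungated, gated = gated, cross_feed = cross,
       models = list(seizure = S, artifact = A,
                     scaler_s = scaler_s, scaler_a = scaler_a),
       spec = spec, summary = summary)
}

#' Separability floor of the synthetic generator
#'
#' Trains the seizure detector on default-condition records of one synthetic
#' patient (two hours by default, artifacts included, labeled by the standard
#' rules) and evaluates window metrics on a held-out hour of the same
#' patient. This is the learnability guarantee behind every downstream
#' experiment: if this detector cannot beat chance comfortably, cascade
#' results would be vacuous.
#'
#' @param seed base seed ("patient" identity and record realizations).
#' @param train_records,train_s training record count and length (s).
#' @param test_s held-out record length (s).
#' @param window_s window length (s).
#' @param hyper a [gbt_hyper()].
#' @param cfg base [synth_config()].
#' @return A one-row tibble: `sensitivity_pct`, `specificity_pct`,
#'   `fp_per_hour`, `n_train_windows`, `n_test_windows`.
#' @export
separability_study <- function(seed = 0, train_records = 2, train_s = 3600,
                               test_s = 3600, window_s = 4,
                               hyper = gbt_hyper(), cfg = synth_config()) {
  cfg$seizure_focus <- sample_seizure_focus(record_substream_seed(seed, 7),
                                            cfg$seizure_band)
  spec <- window_spec(window_s, cfg$fs)
  feat <- function(r) {
    fm <- build_feature_matrix(r$recording, spec, use_fft = TRUE)
    list(X = fm, y = label_windows(r$seizures, spec, nrow(fm), 4)$seizure)
  }
  cfg$duration_s <- train_s
  trs <- lapply(gen_dataset(cfg, train_records, seed = seed,
                            id_prefix = "floor_tr"), feat)
  X <- dplyr::bind_rows(lapply(trs, `[[`, "X"))
  y <- unlist(lapply(trs, `[[`, "y"))
  cfg$duration_s <- test_s
  te <- feat(gen_record(cfg, seed = record_substream_seed(seed, 99),
                        record_id = "floor_te"))
  fit <- train_detector(X, y, hyper)
  m <- window_metrics(te$y, predict(fit, te$X, type = "class"))
  tibble::tibble(
    sensitivity_pct = m$sensitivity_pct,
    specificity_pct = m$specificity_pct,
    fp_per_hour = m$fp / (length(te$y) * window_s / 3600),
    n_train_windows = length(y), n_test_windows = length(te$y))
}

#' Class-weight ratio sweep (sensitivity/specificity trade-off)
#'
#' Trains the seizure detector at several positive-class weight ratios on one
#' fixed synthetic train/test split and reports window sensitivity and
#' specificity per ratio. Raising the weight on the rare ictal class buys
#' sensitivity at the price of specificity; ratio 1 is the unweighted
#' baseline. The split emulates the global-model setting: each training
#' record is a different synthetic patient (its own ictal focus), the
#' held-out record a further unseen patient. That is where the weighting
#' trade-off is visible; a subject-specific split saturates both metrics and
#' shows nothing.
#'
#' @param seed base seed for the fixed split.
#' @param ratios increasing positive/negative weight ratios.
#' @param window_s window length (s).
#' @param train_records,train_s training record count and length (s).
#' @param test_s held-out record length (s).
#' @param hyper base [gbt_hyper()] (its `weights` field is overridden).
#' @param cfg base [synth_config()]; artifact rates are zeroed (the sweep
#'   isolates the weighting effect on clean data).
#' @return A tibble: `ratio`, `sensitivity_pct`, `specificity_pct`.
#' @export
weight_ratio_study <- function(seed = 0, ratios = c(1, 8, 64), window_s = 4,
                               train_records = 3, train_s = 3600,
                               test_s = 3600,
                               hyper = gbt_hyper(), cfg = synth_config()) {
  cfg$artifact_rates_per_h[] <- 0
  spec <- window_spec(window_s, cfg$fs)
  feat <- function(r) {
    fm <- build_feature_matrix(r$recording, spec, use_fft = TRUE)
    list(X = fm, y = label_windows(r$seizures, spec, nrow(fm), 4)$seizure)
  }
  patient <- function(sub, dur) {
    cfg$seizure_focus <- sample_seizure_focus(record_substream_seed(seed, sub),
                                              cfg$seizure_band)
    cfg$duration_s <- dur
    feat(gen_record(cfg, seed = record_substream_seed(seed, sub + 1)))
  }
  trs <- lapply(seq_len(train_records), function(i) patient(300 + 2 * i, train_s))
  tr <- list(X = dplyr::bind_rows(lapply(trs, `[[`, "X")),
             y = unlist(lapply(trs, `[[`, "y")))
  te <- patient(400, test_s)
  rows <- lapply(ratios, function(rt) {
    h <- hyper; h$weights <- rt
    fit <- train_detector(tr$X, tr$y, h)
    m <- window_metrics(te$y, predict(fit, te$X, type = "class"))
    tibble::tibble(ratio = rt, sensitivity_pct = m$sensitivity_pct,
                   specificity_pct = m$specificity_pct)
  })
  dplyr::bind_rows(rows)
}

#' Plot the weight-ratio trade-off
#'
#' @param ratios a tibble from [weight_ratio_study()].
#' @return A ggplot object.
#' @export
plot_weight_ratio <- function(ratios) {
  df <- tidyr::pivot_longer(ratios, c("sensitivity_pct", "specificity_pct"),
                            names_to = "metric", values_to = "pct")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$ratio, y = .data$pct,
                                   colour = .data$metric)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "positive-class weight ratio", y = "%") +
    ggplot2::theme_minimal()
}
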