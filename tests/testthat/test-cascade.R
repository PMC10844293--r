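test_that("scalers have the documented moments on their fit source", {
  set.seed(81)
  X <- matrix(rnorm(60 * 5, mean = 10, sd = 3), 60, 5,
              dimnames = list(NULL, paste0("f", 1:5)))
  none <- fit_scaler(X, "none")
  expect_equal(apply_scaler(none, X), X)
  z <- apply_scaler(fit_scaler(X, "zscore"), X)
  expect_equal(colMeans(z), rep(0, 5), tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(apply(z, 2, sd), rep(1, 5), tolerance = 1e-12,
               ignore_attr = TRUE)
  mm <- apply_scaler(fit_scaler(X, "minmax"), X)
  expect_equal(unname(apply(mm, 2, min)), rep(0, 5))
  expect_equal(unname(apply(mm, 2, max)), rep(1, 5))
  # constant features degrade gracefully
  Xc <- cbind(X, k = 7)
  expect_equal(unname(apply_scaler(fit_scaler(Xc, "zscore"), Xc)[, 6]),
               rep(0, 60))
  expect_equal(unname(apply_scaler(fit_scaler(Xc, "minmax"), Xc)[, 6]),
               rep(0, 60))
  # parameters are frozen: new data is not refit
  X2 <- X + 100
  expect_equal(apply_scaler(fit_scaler(X, "zscore"), X2)[1, 1],
               (X2[1, 1] - mean(X[, 1])) / sd(X[, 1]), ignore_attr = TRUE)
})

test_that("an always-firing gate suppresses every seizure verdict", {
  m <- cascade_models()
  always <- eeggate:::constant_model(1L, 6)
  out <- cascade_predict(m$X, artifact = list(model = always, scaler = NULL),
                         seizure = list(model = m$S, scaler = NULL))
  expect_true(all(out$gate_fired))
  expect_equal(sum(out$verdict == "seizure"), 0)
  expect_equal(sum(out$seizure_gated), 0)
})

test_that("a silent gate reproduces the standalone seizure detector", {
  m <- cascade_models()
  never <- eeggate:::constant_model(0L, 6)
  out <- cascade_predict(m$X, artifact = list(model = never, scaler = NULL),
                         seizure = list(model = m$S, scaler = NULL))
  expect_false(any(out$gate_fired))
  expect_equal(out$seizure_gated, out$seizure_smoothed)
})

test_that("gated alarms are a subset of ungated alarms (monotonicity)", {
  m <- cascade_models()
  out <- cascade_predict(m$X, artifact = list(model = m$A, scaler = NULL),
                         seizure = list(model = m$S, scaler = NULL))
  expect_true(all(out$seizure_gated <= out$seizure_smoothed))
  # and per-window: no seizure verdict where the gate fired
  expect_equal(sum(out$verdict == "seizure" & out$gate_fired), 0)
  # the same holds without smoothing
  raw <- cascade_predict(m$X, artifact = list(model = m$A, scaler = NULL),
                         seizure = list(model = m$S, scaler = NULL),
                         smoothing = NULL)
  expect_true(all(raw$seizure_gated <= raw$seizure_smoothed))
})

test_that("a perfect artifact oracle yields 100% FP improvement", {
  m <- cascade_models()
  spec <- window_spec(4, 250)
  # axis-aligned artifact truth with a hand-built stump that decides it
  # exactly: x1 >= 1.2 -> artifact (large positive leaf)
  bc <- as.integer(m$X[, 1] >= 1.2)
  stump <- hand_tree(feature = c(0L, NA, NA), threshold = c(1.2, NA, NA),
                     yes = c(2L, NA, NA), no = c(3L, NA, NA),
                     value = c(0, -10, 10), risk = c(1, 0, 0))
  oracle <- m$A
  oracle$trees <- list(stump); oracle$tree_class <- 0L
  expect_equal(as.integer(predict(oracle, m$X) > 0.5), bc)
  rep <- cross_feed_report(
    artifact_data = list(X = m$X, bc = bc),
    seizure_data = list(X = m$X, seizure = m$y_seiz),
    artifact = list(model = oracle, scaler = NULL),
    seizure = list(model = m$S, scaler = NULL),
    spec = spec)
  a <- rep$artifact_to_seizure
  expect_equal(a$fp_gated, 0)
  if (!is.na(a$improvement_pct)) expect_equal(a$improvement_pct, 100)
})

test_that("cross-feed improvement arithmetic is reproduced by counting", {
  m <- cascade_models()
  spec <- window_spec(4, 250)
  rep <- cross_feed_report(
    artifact_data = list(X = m$X, bc = m$y_art),
    seizure_data = list(X = m$X, seizure = m$y_seiz),
    artifact = list(model = m$A, scaler = NULL),
    seizure = list(model = m$S, scaler = NULL),
    spec = spec)
  a <- rep$artifact_to_seizure
  expect_gte(a$fp_ungated, a$fp_gated)
  if (!is.na(a$improvement_pct)) {
    expect_equal(a$improvement_pct, 100 * (1 - a$fp_gated / a$fp_ungated))
    if (a$fp_gated > 0) {
      expect_equal(a$improvement_ratio, a$fp_ungated / a$fp_gated)
    }
  }
  expect_equal(nrow(tidy(rep)), 16)  # 9 + 7 report fields
})

test_that("improvement is not-applicable when S never alarms", {
  m <- cascade_models()
  silent_s <- eeggate:::constant_model(0L, 6)
  rep <- cross_feed_report(
    artifact_data = list(X = m$X, bc = m$y_art),
    seizure_data = list(X = m$X, seizure = m$y_seiz),
    artifact = list(model = m$A, scaler = NULL),
    seizure = list(model = silent_s, scaler = NULL),
    spec = window_spec(4, 250))
  expect_true(is.na(rep$artifact_to_seizure$improvement_pct))
})

test_that("MC-mode gates fire on any flagged channel", {
  set.seed(83)
  n <- 200
  X <- matrix(abs(rnorm(n * 4)), n, 4)
  mc <- cbind(as.integer(X[, 1] > 1.2), as.integer(X[, 2] > 1.2),
              0L, as.integer(X[, 4] > 1.2))
  labels <- list(bc = as.integer(rowSums(mc) > 0), mc = mc, mmc = mc)
  suppressWarnings(
    mcm <- fit_artifact_task(X, labels, "mc", gbt_hyper(n_trees = 5,
                                                        max_depth = 2)))
  flags <- eeggate:::artifact_flags(mcm, X)
  per_ch <- vapply(seq_len(4), function(ch) {
    if (inherits(mcm[[ch]], "gbt_constant")) rep(0L, n)
    else as.integer(predict(mcm[[ch]], X) > 0.5)
  }, integer(n))
  expect_equal(flags, as.integer(rowSums(per_ch) > 0))
})

test_that("onset-grouped versus scattered split follows the window cutoff", {
  spec <- window_spec(4, 250)
  # one seizure event of 8 windows; the gate fires on event windows 1, 2, 7
  seiz <- c(rep(0, 6), rep(1, 8), rep(0, 6))
  flag_pattern <- c(rep(0, 6), 1, 1, 0, 0, 0, 0, 1, 0, rep(0, 6))
  r <- rle(seiz)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
  ev_start <- starts[r$values == 1]; ev_end <- ends[r$values == 1]
  fl <- flag_pattern[ev_start:ev_end] == 1
  expect_equal(sum(fl[1:3]), 2)              # onset-grouped
  expect_equal(sum(fl[-(1:3)]), 1)           # scattered
  lead <- match(FALSE, fl) - 1
  expect_equal(added_latency(lead, spec), 8) # two leading windows suppressed
})
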