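test_that("the specificity-to-FP/h conversion reproduces worked values", {
  expect_equal(fp_per_hour_from_specificity(99, 2), 18)
  expect_equal(fp_per_hour_from_specificity(95.66, 3), 52.08)
  expect_equal(fp_per_hour_from_specificity(100, 8), 0)
  expect_error(fp_per_hour_from_specificity(99, 0), "positive")
})

test_that("window metrics follow their definitions", {
  y <- c(1, 1, 0, 0)
  expect_equal(window_metrics(y, y)$sensitivity_pct, 100)
  expect_equal(window_metrics(y, y)$specificity_pct, 100)
  inv <- window_metrics(y, 1 - y)
  expect_equal(inv$sensitivity_pct, 0)
  expect_equal(inv$specificity_pct, 0)
  # TP=8 FN=2 TN=90 FP=10 -> 80 / 90
  yt <- c(rep(1, 10), rep(0, 100))
  yp <- c(rep(1, 8), 0, 0, rep(1, 10), rep(0, 90))
  m <- window_metrics(yt, yp)
  expect_equal(m$sensitivity_pct, 80)
  expect_equal(m$specificity_pct, 90)
  expect_true(is.na(window_metrics(rep(0, 4), rep(0, 4))$sensitivity_pct))
  expect_error(window_metrics(c(1, 0), 1), "equal length")
})

test_that("F1 matches closed forms", {
  expect_equal(f1_scores(c(1, 0, 1), c(1, 0, 1)), 1)
  # all-one prediction vs 50/50 truth: P = 0.5, R = 1 -> 2/3
  expect_equal(f1_scores(c(1, 0, 1, 0), rep(1, 4)), 2 / 3)
  # weighted F1 over a single-class truth equals that class's F1
  expect_equal(f1_scores(rep(2, 5), c(2, 2, 2, 0, 2), "weighted"),
               f1_one <- 2 * 4 / (2 * 4 + 0 + 1))
  # weighted mode averages by support
  yt <- c(0, 0, 0, 1); yp <- c(0, 0, 1, 1)
  f0 <- 2 * 2 / (2 * 2 + 0 + 1); f1 <- 2 * 1 / (2 * 1 + 1 + 0)
  expect_equal(f1_scores(yt, yp, "weighted"), 0.75 * f0 + 0.25 * f1)
})

test_that("cross-validation splitters implement their definitions", {
  expect_error(cv_splits("A", "loocv"), "at least 2")
  lo <- cv_splits(c("A", "B", "C"), "loocv")
  expect_length(lo, 3)
  expect_true(all(vapply(lo, function(s) length(s$train) == 2, logical(1))))
  wf <- cv_splits(c("A", "B", "C"), "wfcv")
  expect_equal(wf, list(list(train = "A", test = "B"),
                        list(train = c("A", "B"), test = "C")))
  rw <- cv_splits(c("A", "B", "C", "D"), "rwcv", rw_span = 2)
  expect_equal(rw, list(list(train = c("A", "B"), test = "C"),
                        list(train = c("B", "C"), test = "D")))
})

test_that("splitter invariants: no leakage, nested WFCV, constant RWCV span", {
  ids <- sprintf("r%02d", 1:8)
  for (scheme in c("loocv", "wfcv", "rwcv")) {
    sp <- cv_splits(ids, scheme, rw_span = 3)
    for (s in sp) expect_false(s$test %in% s$train)
  }
  wf <- cv_splits(ids, "wfcv")
  sizes <- vapply(wf, function(s) length(s$train), numeric(1))
  expect_true(all(diff(sizes) == 1))                       # grows by one
  for (i in seq_along(wf)[-1]) {
    expect_true(all(wf[[i - 1]]$train %in% wf[[i]]$train)) # nested
  }
  rw <- cv_splits(ids, "rwcv", rw_span = 3)
  expect_true(all(vapply(rw, function(s) length(s$train), numeric(1)) == 3))
  # eligibility: ineligible records never test but may train
  lo <- cv_splits(ids, "loocv", eligible = ids[c(2, 5)])
  expect_setequal(vapply(lo, `[[`, character(1), "test"), ids[c(2, 5)])
  expect_true(all(ids[1] %in% lo[[1]]$train))
})

test_that("metrics report: counted FP/h equals the formula on measured Sp", {
  set.seed(71)
  spec <- window_spec(4, 250)
  y <- rbinom(900, 1, 0.1)
  p <- ifelse(runif(900) < 0.9, y, 1 - y)
  rep <- metrics_report(y, p, spec)
  w <- rep$window
  # counted: FP / monitored hours; formula: 3600/W * (1 - Sp) scaled by the
  # negative fraction — the two agree exactly when Sp is measured
  direct <- w$fp / (length(y) * 4 / 3600)
  formula_all_neg <- fp_per_hour_from_specificity(w$specificity_pct, 4)
  expect_equal(direct, formula_all_neg * mean(y == 0), tolerance = 1e-9)
})

test_that("event-level sensitivity and latency come from event overlap", {
  spec <- window_spec(4, 250)
  y <- c(rep(0, 5), rep(1, 5), rep(0, 5), rep(1, 3), rep(0, 2))
  ev <- tibble::tibble(onset_s = c(20, 60), offset_s = c(40, 72))
  p <- c(rep(0, 7), rep(1, 3), rep(0, 10))   # hits event 1 late, misses 2
  r <- metrics_report(y, p, spec, true_events = ev)
  expect_equal(r$events$n_events_detected, 1)
  expect_equal(r$events$event_sensitivity_pct, 50)
  expect_equal(r$events$latency_s, 8)        # alarm at 28 s vs onset 20 s
  expect_equal(nrow(tidy(r)), 1)
  expect_true("fp_per_hour" %in% names(glance(r)))
})

test_that("ci95 is a normal-approximation interval over records", {
  v <- c(60, 70, 80)
  ci <- ci95(v)
  expect_equal(unname(ci["mean"]), 70)
  expect_equal(unname(ci["half_width"]), 1.96 * sd(v) / sqrt(3))
})
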