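test_that("segmentation tiles the recording and drops partial windows", {
  spec <- window_spec(4, 256)
  seg <- segment_windows(toy_recording(2, 10, 256, names = c("a", "b")), spec)
  expect_equal(seg$starts_s, c(0, 4))                   # floor(10/4) = 2
  expect_equal(dim(seg$blocks[[1]]), c(2, 1024))
  one <- segment_windows(toy_recording(1, 8, 256, names = "a"),
                         window_spec(8, 256))
  expect_length(one$starts_s, 1)
  expect_warning(
    short <- segment_windows(toy_recording(1, 3.9, 250, names = "a"),
                             window_spec(4, 250)),
    "shorter")
  expect_length(short$starts_s, 0)
})

test_that("Haar detail energies match hand-derived values", {
  expect_equal(dwt_detail_energies(rep(5, 16)), rep(0, 4))   # constant
  expect_equal(dwt_detail_energies(rep(0, 32)), rep(0, 4))
  # alternating +-1: all energy in level 1
  expect_equal(dwt_detail_energies(c(1, -1, 1, -1, 1, -1, 1, -1), levels = 2),
               c(8, 0))
  expect_error(dwt_detail_energies(rnorm(8), levels = 4), "too short")
})

test_that("Haar decomposition conserves energy (Parseval, orthonormal)", {
  for (seed in 1:5) {
    set.seed(seed)
    n <- 16 * sample(1:8, 1)           # divisible by 2^4
    x <- rnorm(n, sd = 30)
    e <- dwt_detail_energies(x, 4, return_approx = TRUE)
    expect_lt(abs(sum(e) - sum(x^2)) / sum(x^2), 1e-9)
  }
})

test_that("FFT high-band energy matches closed forms and the DFT oracle", {
  t <- (0:249) / 250
  expect_equal(fft_highband_energy(sin(2 * pi * 100 * t), 250), 125,
               tolerance = 1e-9)                        # N/2 for unit sine
  expect_lt(fft_highband_energy(sin(2 * pi * 10 * t), 250), 1e-9 * 125)
  expect_equal(fft_highband_energy(rep(0, 100), 250), 0)
  expect_error(fft_highband_energy(t, 250, cutoff = 125), "Nyquist")
  set.seed(4)
  x <- rnorm(64)
  expect_equal(fft_highband_energy(x, 250, 80), dft_band_energy(x, 250, 80),
               tolerance = 1e-9)
})

test_that("high band plus low-band complement is the Parseval total", {
  set.seed(9)
  x <- rnorm(200, sd = 12)
  hi <- fft_highband_energy(x, 250, 80)
  total_above_dc <- fft_highband_energy(x, 250, 1e-12)
  dc <- mean(x)^2 * length(x)
  expect_equal(total_above_dc + dc, sum(x^2), tolerance = 1e-9)
  expect_lte(hi, total_above_dc + 1e-12)
})

test_that("feature matrix has the documented shape, order and determinism", {
  rec <- toy_recording(4, 20, 250)
  spec <- window_spec(4, 250)
  fm <- build_feature_matrix(rec, spec, use_fft = FALSE)
  expect_equal(length(feature_columns(fm)), 16)          # 4 ch x 4 levels
  fm2 <- build_feature_matrix(rec, spec, use_fft = TRUE)
  expect_equal(length(feature_columns(fm2)), 20)         # + fft per channel
  expect_identical(fm2, build_feature_matrix(rec, spec, use_fft = TRUE))
  # channel-major order
  expect_equal(feature_columns(fm2)[1:5],
               c("F7.T7_dwt_d1", "F7.T7_dwt_d2", "F7.T7_dwt_d3",
                 "F7.T7_dwt_d4", "F7.T7_fft_high"))
  expect_true(all(feature_values(fm2) >= 0))
  expect_false(anyNA(feature_values(fm2)))
})

test_that("feature rows are translation-covariant with window order", {
  rec <- toy_recording(2, 12, 250, names = c("a", "b"))
  spec <- window_spec(4, 250)
  fm <- build_feature_matrix(rec, spec)
  # windows correspond 1:1 with per-window computation on sliced recordings
  for (w in 1:3) {
    sl <- eeg_recording(rec$data[, ((w - 1) * 1000 + 1):(w * 1000)],
                        250, rec$channel_names, "slice")
    one <- build_feature_matrix(sl, spec)
    expect_equal(feature_values(fm)[w, ], feature_values(one)[1, ])
  }
})

test_that("seizure labels use the strict majority-of-samples rule", {
  spec <- window_spec(4, 250)
  # exactly 50% of window [0, 4): not a seizure
  tr50 <- label_track(data.frame(start_s = 0, end_s = 2,
                                 label = "seizure", channel = NA))
  expect_equal(label_windows(tr50, spec, 1, 4)$seizure, 0L)
  # 51%: a seizure
  tr51 <- label_track(data.frame(start_s = 0, end_s = 2.04,
                                 label = "seizure", channel = NA))
  expect_equal(label_windows(tr51, spec, 1, 4)$seizure, 1L)
})

test_that("artifact labels follow any-overlap with bc/mc/mmc consistency", {
  spec <- window_spec(4, 250)
  tr <- label_track(data.frame(start_s = 1, end_s = 1.5,
                               label = "musc", channel = 2L))
  lab <- label_windows(tr, spec, 2, 4)
  expect_equal(lab$bc, c(1L, 0L))
  expect_equal(lab$mc[1, ], c(0L, 0L, 1L, 0L))
  musc_code <- artifact_vocabulary()$code[artifact_vocabulary()$label == "musc"]
  expect_equal(lab$mmc[1, 3], musc_code)
  # mmc == 0 exactly where mc == 0; bc == any channel
  expect_true(all((lab$mmc == 0) == (lab$mc == 0)))
  expect_equal(lab$bc, as.integer(rowSums(lab$mc) > 0))
  # majority rule variant drops the sub-majority overlap
  expect_equal(label_windows(tr, spec, 2, 4, rule = "majority")$bc, c(0L, 0L))
})

test_that("mmc tie-break picks the larger overlap, then the lower code", {
  spec <- window_spec(4, 250)
  tr <- label_track(data.frame(
    start_s = c(0.0, 2.5), end_s = c(2.5, 3.0),
    label = c("chew", "musc"), channel = c(1L, 1L)))
  lab <- label_windows(tr, spec, 1, 4)
  chew_code <- artifact_vocabulary()$code[artifact_vocabulary()$label == "chew"]
  expect_equal(lab$mmc[1, 2], chew_code)                # 2.5 s beats 0.5 s
  # equal overlaps: lower code wins (musc = 1 < chew = 4)
  tr2 <- label_track(data.frame(
    start_s = c(0, 2), end_s = c(2, 4),
    label = c("chew", "musc"), channel = c(1L, 1L)))
  expect_equal(label_windows(tr2, spec, 1, 4)$mmc[1, 2], 1L)
})
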