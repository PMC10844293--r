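test_that("the generator is deterministic and respects zero rates", {
  cfg <- synth_config(duration_s = 120)
  r1 <- gen_record(cfg, seed = 5)
  r2 <- gen_record(cfg, seed = 5)
  expect_identical(r1$recording$data, r2$recording$data)
  expect_identical(r1$seizures$entries, r2$seizures$entries)
  quiet <- synth_config(duration_s = 120, seizure_rate_per_h = 0,
                        artifact_rates_per_h = c(musc = 0, eyem = 0,
                                                 elpp = 0, chew = 0))
  rq <- gen_record(quiet, seed = 5)
  expect_equal(nrow(rq$seizures$entries), 0)
  expect_equal(nrow(rq$artifacts$entries), 0)
  expect_equal(n_channels(rq$recording), 4)
})

test_that("event counts follow the Poisson law of the configured rate", {
  # 20 seeds x 0.2 h at 30/h: total ~ Poisson(120)
  cfg <- synth_config(duration_s = 720, seizure_rate_per_h = 30,
                      seizure_meanlog = log(15), seizure_sdlog = 0.3,
                      artifact_rates_per_h = c(musc = 0, eyem = 0,
                                               elpp = 0, chew = 0))
  counts <- vapply(1:20, function(s) {
    nrow(gen_record(cfg, seed = 1000 + s)$seizures$entries)
  }, numeric(1))
  lambda <- 20 * 30 * 720 / 3600
  expect_gte(sum(counts), qpois(0.005, lambda))
  expect_lte(sum(counts), qpois(0.995, lambda))
})

test_that("records carry physiologically plausible amplitudes", {
  r <- gen_record(synth_config(duration_s = 300), seed = 8)
  rms <- apply(r$recording$data, 1, sd)
  expect_true(all(rms > 5 & rms < 80))       # background-dominated RMS
  expect_lt(max(abs(r$recording$data)), 1000)
})

test_that("muscle artifacts carry most energy above 20 Hz, some above 80", {
  cfg <- synth_config(duration_s = 900, seizure_rate_per_h = 0,
                      artifact_rates_per_h = c(musc = 60, eyem = 0,
                                               elpp = 0, chew = 0),
                      musc_confusable_frac = 0.5)
  r <- gen_record(cfg, seed = 9)
  e <- r$artifacts$entries
  expect_gt(nrow(e), 5)
  fs <- r$recording$fs
  hi_frac <- vapply(seq_len(nrow(e)), function(i) {
    seg <- r$recording$data[e$channel[i] + 1,
                            (floor(e$start_s[i] * fs) + 1):
                              (floor(e$end_s[i] * fs))]
    above20 <- dft <- fft_highband_energy(seg, fs, 20)
    above20 / sum(seg^2)
  }, numeric(1))
  expect_gt(mean(hi_frac > 0.5), 0.9)        # bursts are >20 Hz dominated
  # and the > 80 Hz feature separates muscle windows from background
  spec <- window_spec(4, fs)
  fm <- build_feature_matrix(r$recording, spec)
  lab <- label_windows(r$artifacts, spec, nrow(fm), 4)
  ffts <- rowMeans(feature_values(fm)[, grep("fft_high",
                                             feature_columns(fm))])
  expect_gt(mean(ffts[lab$bc == 1]), mean(ffts[lab$bc == 0]))
})

test_that("seizure windows dominate background in the 8-31 Hz detail bands", {
  cfg <- synth_config(duration_s = 1200, seizure_rate_per_h = 30,
                      artifact_rates_per_h = c(musc = 0, eyem = 0,
                                               elpp = 0, chew = 0))
  r <- gen_record(cfg, seed = 10)
  spec <- window_spec(4, 250)
  fm <- build_feature_matrix(r$recording, spec)
  y <- label_windows(r$seizures, spec, nrow(fm), 4)$seizure
  expect_gt(sum(y), 20)
  expect_gt(sum(y == 0), 80)
  d34 <- rowMeans(feature_values(fm)[, grep("dwt_d[34]",
                                            feature_columns(fm))])
  expect_gt(mean(d34[y == 1]), mean(d34[y == 0]))
})

test_that("dataset substreams are isolated and ids distinct", {
  cfg <- synth_config(duration_s = 60)
  ds <- gen_dataset(cfg, 3, seed = 4)
  ids <- vapply(ds, function(r) r$recording$record_id, character(1))
  expect_equal(length(unique(ids)), 3)
  # record 2 is identical whether or not records 1/3 are generated
  solo <- gen_record(cfg, seed = eeggate:::record_substream_seed(4, 2),
                     record_id = "synth02")
  expect_identical(ds[[2]]$recording$data, solo$recording$data)
  total <- sum(vapply(ds, function(r) duration(r$recording), numeric(1)))
  expect_equal(total, 3 * 60)
})

test_that("the synthetic path exercises the EDF and CSV readers end-to-end", {
  cfg <- synth_config(duration_s = 120, seizure_rate_per_h = 60)
  ds <- gen_dataset(cfg, 1, seed = 12)
  dir <- withr::local_tempdir()
  paths <- write_synthetic_dataset(ds, dir)
  back <- read_edf(paths$edf[1])
  expect_equal(back$fs, 250)
  expect_equal(n_channels(back), 4)
  # 16-bit round trip keeps the signal essentially intact
  expect_gt(cor(back$data[1, ], ds[[1]]$recording$data[1, ]), 0.999)
  sz <- read_annotations(paths$seizures[1])
  expect_equal(nrow(sz$entries), nrow(ds[[1]]$seizures$entries))
  ar <- read_annotations(paths$artifacts[1])
  expect_equal(ar$entries$label, ds[[1]]$artifacts$entries$label)
})

test_that("a patient-level focus makes events share morphology", {
  focus <- sample_seizure_focus(99)
  cfg <- synth_config(duration_s = 1800, seizure_rate_per_h = 20,
                      artifact_rates_per_h = c(musc = 0, eyem = 0,
                                               elpp = 0, chew = 0),
                      seizure_focus = focus)
  r <- gen_record(cfg, seed = 13)
  expect_gt(nrow(r$seizures$entries), 2)
  # channels with zero focus gain carry no ictal rhythm: compare ictal RMS
  # lift between involved and uninvolved channels
  fs <- 250
  on <- r$seizures$entries$start_s[1]; off <- r$seizures$entries$end_s[1]
  seg <- (floor(on * fs) + 50):(floor(off * fs) - 50)
  lift <- apply(r$recording$data[, seg], 1, sd) /
    apply(r$recording$data[, 1:(fs * 10)], 1, sd)
  if (any(focus$gains == 0)) {
    expect_gt(min(lift[focus$gains > 0]), max(lift[focus$gains == 0]) * 0.9)
  }
  expect_s3_class(r$recording, "eeg_recording")
})
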