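#' Synthetic EEG generator configuration
#'
#' Parameters of the jointly-labeled 4-channel synthetic EEG: ongoing
#' background activity (1/f-shaped noise with intermittent alpha bursts),
#' global rhythmic spike-wave seizures with growing amplitude, and four
#' per-channel artifact morphologies — muscle (broadband 20 Hz-to-Nyquist
#' bursts, a configurable fraction with a seizure-like 3–5 Hz rhythmic
#' envelope so the standalone seizure detector has something to confuse),
#' ocular (slow high-amplitude deflections on the frontal-adjacent
#' derivations), electrode pop (step plus exponential decay on one channel)
#' and chewing (1–3 Hz bursts amplitude-modulating a 25–60 Hz carrier).
#' Amplitudes are µV, calibrated to plausible scalp values (background RMS
#' ~15 µV, seizures 50–150 µV, ocular 100-200 µV on these temporal derivations).
#'
#' @param duration_s record length in seconds.
#' @param fs sampling rate (Hz).
#' @param seizure_rate_per_h expected seizures per hour (Poisson). The
#'   default (6/h) is calibrated for hour-scale study records: each carries
#'   several events, so a detector trained on ~2 synthetic hours sees enough
#'   ictal variety to generalize, and event-level metrics on a single
#'   held-out hour rest on more than one or two events. (Clinical rates are
#'   far lower; emulating them needs correspondingly longer records.)
#' @param seizure_meanlog,seizure_sdlog log-normal seizure duration
#'   parameters (default median 60 s).
#' @param seizure_band seizure fundamental frequency range (Hz).
#' @param seizure_amp seizure amplitude range (µV).
#' @param artifact_rates_per_h named per-type artifact rates; names from
#'   `musc`, `eyem`, `elpp`, `chew`. Set all to 0 for artifact-free records.
#' @param musc_confusable_frac fraction of muscle artifacts given a 3–5 Hz
#'   rhythmic envelope (seizure-confusable).
#' @param bg_rms background RMS (µV).
#' @param bg_exponent 1/f spectral exponent of the background.
#' @param alpha_rate_per_min alpha-burst rate.
#' @param theta_rate_per_min rate of physiological slow-wave (delta/theta,
#'   2–7 Hz, 20–60 µV) bursts; part of the labeled background, as in real
#'   EEG, so detectors cannot equate "large low-band energy" with artifact
#'   or seizure.
#' @param noise_sd white sensor-noise sd (µV).
#' @param seizure_focus optional patient-level seizure morphology from
#'   [sample_seizure_focus()]: a fixed epileptogenic focus (per-channel gain
#'   pattern) and per-patient fundamental frequency that all events of this
#'   "patient" share, with per-event jitter. `NULL` draws every event's
#'   morphology independently. Subject-specific detection rests on ictal
#'   morphology recurring within a patient, so multi-record studies of one
#'   synthetic patient should share one focus.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(duration_s = 3600, fs = 250,
                         seizure_rate_per_h = 6,
                         seizure_meanlog = log(60), seizure_sdlog = 0.4,
                         seizure_band = c(3, 5), seizure_amp = c(50, 150),
                         artifact_rates_per_h = c(musc = 20, eyem = 30,
                                                  elpp = 6, chew = 10),
                         musc_confusable_frac = 0.5,
                         bg_rms = 15, bg_exponent = 1,
                         alpha_rate_per_min = 4, theta_rate_per_min = 6,
                         noise_sd = 2, seizure_focus = NULL) {
  stopifnot(duration_s > 0, fs >= 200,  # components reach ~120 Hz
            seizure_rate_per_h >= 0, all(artifact_rates_per_h >= 0),
            musc_confusable_frac >= 0, musc_confusable_frac <= 1)
  structure(as.list(environment()), class = "synth_config")
}

#' Draw a patient-level seizure focus
#'
#' A per-patient ictal morphology: the set of involved channels with their
#' relative gains (the spatial field of the focus) and the patient's
#' spike-wave fundamental frequency. Events generated under this focus jitter
#' around it rather than redrawing morphology from scratch.
#'
#' @param seed RNG seed (the "patient" identity).
#' @param band fundamental frequency range (Hz).
#' @return A list `(f0 =, gains = length-4 vector, zero on uninvolved
#'   channels)`.
#' @export
sample_seizure_focus <- function(seed, band = c(3, 5)) {
  set.seed(seed)
  nch <- 4L
  chans <- sort(sample(seq_len(nch), sample(2:4, 1, prob = c(0.5, 0.3, 0.2))))
  gains <- rep(0, nch)
  gains[chans] <- stats::runif(length(chans), 0.5, 1)
  list(f0 = stats::runif(1, band[1], band[2]), gains = gains)
}

# place `k` events of durations `durs` without same-channel overlap;
# occupied: list per channel of (start, end) matrix. Returns onsets (NA when
# no slot found after `tries`).
place_events <- function(k, durs, duration_s, occupied, channels_list,
                         tries = 50) {
  onsets <- rep(NA_real_, k)
  for (i in seq_len(k)) {
    for (t in seq_len(tries)) {
      on <- stats::runif(1, 0, max(duration_s - durs[i], 0.001))
      ok <- TRUE
      for (ch in channels_list[[i]]) {
        occ <- occupied[[ch]]
        if (nrow(occ) > 0 &&
            any(on < occ[, 2] & on + durs[i] > occ[, 1])) {
          ok <- FALSE
          break
        }
      }
      if (ok) {
        onsets[i] <- on
        for (ch in channels_list[[i]]) {
          occupied[[ch]] <- rbind(occupied[[ch]], c(on, on + durs[i]))
        }
        break
      }
    }
  }
  list(onsets = onsets, occupied = occupied)
}

# 1/f^beta-shaped Gaussian noise of length n, unit RMS
colored_noise <- function(n, fs, beta) {
  w <- stats::fft(stats::rnorm(n))
  freq <- c(0, pmin(seq_len(n - 1), n - seq_len(n - 1))) * fs / n
  shape <- c(0, freq[-1]^(-beta / 2))
  x <- Re(stats::fft(w * shape, inverse = TRUE)) / n
  x / stats::sd(x)
}

# white noise band-limited to [lo, hi] Hz, unit RMS
band_noise <- function(n, fs, lo, hi) {
  w <- stats::fft(stats::rnorm(n))
  freq <- c(0, pmin(seq_len(n - 1), n - seq_len(n - 1))) * fs / n
  keep <- freq >= lo & freq <= hi
  x <- Re(stats::fft(w * keep, inverse = TRUE)) / n
  x / stats::sd(x)
}

hann_env <- function(n) 0.5 - 0.5 * cos(2 * pi * seq(0, 1, length.out = n))

# flat-topped (tukey) envelope with 10% tapers
tukey_env <- function(n, frac = 0.1) {
  m <- max(2L, round(n * frac))
  e <- rep(1, n)
  ramp <- 0.5 - 0.5 * cos(pi * seq(0, 1, length.out = m))
  e[seq_len(m)] <- ramp
  e[seq(n - m + 1, n)] <- rev(ramp)
  e
}

#' Generate one jointly-labeled synthetic EEG record
#'
#' Returns a 4-channel recording (temporal bipolar naming) together with a
#' global seizure label track and a per-channel artifact label track, both in
#' the annotation-CSV vocabulary. Identical configuration and seed reproduce
#' the record bitwise.
#'
#' @param cfg a [synth_config()].
#' @param seed integer RNG seed.
#' @param record_id record identity string.
#' @return A list `(recording =, seizures =, artifacts =)`.
#' @examples
#' r <- gen_record(synth_config(duration_s = 120), seed = 1)
#' r$recording
#' r$seizures$entries
#' @export
gen_record <- function(cfg, seed = 0, record_id = "synth") {
  stopifnot(inherits(cfg, "synth_config"))
  set.seed(seed)
  fs <- cfg$fs
  n <- round(cfg$duration_s * fs)
  nch <- 4L
  ch_names <- c("F7-T7", "T7-P7", "F8-T8", "T8-P8")
  tt <- (seq_len(n) - 1) / fs
  # --- background: 1/f + alpha bursts + sensor noise
  data <- matrix(0, nch, n)
  for (ch in seq_len(nch)) {
    data[ch, ] <- cfg$bg_rms * colored_noise(n, fs, cfg$bg_exponent) +
      stats::rnorm(n, sd = cfg$noise_sd)
  }
  # alpha runs and sleep-spindle-like bursts: pure 8-16 Hz sinusoids, at
  # times high-voltage — the physiological occupant of the 8-16 Hz detail
  # band, without the harmonic stack that marks a spike-wave discharge
  n_alpha <- stats::rpois(1, cfg$alpha_rate_per_min * cfg$duration_s / 60)
  for (i in seq_len(n_alpha)) {
    dur <- stats::runif(1, 0.5, 4)
    on <- stats::runif(1, 0, max(cfg$duration_s - dur, 0.001))
    f <- stats::runif(1, 8, 16)
    amp <- stats::runif(1, 8, 55)
    i0 <- floor(on * fs) + 1L
    i1 <- min(n, i0 + round(dur * fs) - 1L)
    seg <- i0:i1
    burst <- amp * hann_env(length(seg)) *
      sin(2 * pi * f * tt[seg] + stats::runif(1, 0, 2 * pi))
    gains <- stats::runif(nch, 0.4, 1)
    data[, seg] <- data[, seg] + outer(gains, burst)
  }
  # physiological slow waves: high-amplitude low-frequency background, NOT
  # labeled — the reason large low-band energy alone identifies neither
  # artifact nor seizure
  n_theta <- stats::rpois(1, cfg$theta_rate_per_min * cfg$duration_s / 60)
  for (i in seq_len(n_theta)) {
    dur <- stats::runif(1, 1, 4)
    on <- stats::runif(1, 0, max(cfg$duration_s - dur, 0.001))
    f <- stats::runif(1, 2, 7)
    amp <- stats::runif(1, 20, 60)
    i0 <- floor(on * fs) + 1L
    i1 <- min(n, i0 + round(dur * fs) - 1L)
    seg <- i0:i1
    wave <- sin(2 * pi * f * tt[seg] + stats::runif(1, 0, 2 * pi))
    burst <- amp * hann_env(length(seg)) * wave
    gains <- stats::runif(nch, 0.3, 1)
    data[, seg] <- data[, seg] + outer(gains, burst)
  }
  occupied <- replicate(nch, matrix(numeric(0), 0, 2), simplify = FALSE)
  # --- seizures: global rhythmic spike-wave with growing amplitude
  n_seiz <- stats::rpois(1, cfg$seizure_rate_per_h * cfg$duration_s / 3600)
  seiz_entries <- NULL
  if (n_seiz > 0) {
    durs <- pmin(stats::rlnorm(n_seiz, cfg$seizure_meanlog, cfg$seizure_sdlog),
                 cfg$duration_s / 2)
    foci <- lapply(seq_len(n_seiz), function(i) {
      if (is.null(cfg$seizure_focus)) {
        list(f0 = stats::runif(1, cfg$seizure_band[1], cfg$seizure_band[2]),
             gains = {
               chans <- sort(sample(seq_len(nch),
                                    sample(2:4, 1, prob = c(0.5, 0.3, 0.2))))
               g <- rep(0, nch); g[chans] <- stats::runif(length(chans), 0.5, 1)
               g
             })
      } else {
        # per-event jitter around the patient's focus
        list(f0 = min(max(cfg$seizure_focus$f0 + stats::runif(1, -0.3, 0.3),
                          cfg$seizure_band[1]), cfg$seizure_band[2]),
             gains = cfg$seizure_focus$gains *
               stats::runif(nch, 0.85, 1.15))
      }
    })
    pl <- place_events(n_seiz, durs, cfg$duration_s, occupied,
                       replicate(n_seiz, seq_len(nch), simplify = FALSE))
    occupied <- pl$occupied
    for (i in seq_len(n_seiz)) {
      on <- pl$onsets[i]
      if (is.na(on)) next
      i0 <- floor(on * fs) + 1L
      i1 <- min(n, i0 + round(durs[i] * fs) - 1L)
      seg <- i0:i1
      m <- length(seg)
      u <- seq(0, 1, length.out = m)
      f0 <- foci[[i]]$f0
      # frequency evolves downward ~20% across the event; phase by integration
      finst <- f0 * (1.1 - 0.2 * u)
      phase <- 2 * pi * cumsum(finst) / fs
      # spike-wave complex: slow "wave" (fundamental + 2nd harmonic) plus a
      # sharp "spike" each cycle whose ~25 ms width - not the repetition
      # rate - sets its bandwidth, so 3 Hz and 5 Hz discharges are equally
      # visible in the upper detail bands
      wave <- sin(phase) + 0.4 * sin(2 * phase + stats::runif(1, 0, 2 * pi))
      spike_w <- stats::runif(1, 0.02, 0.035)
      cyc <- phase %% (2 * pi)
      spike <- exp(-0.5 * ((cyc - pi) / (2 * pi * finst * spike_w))^2)
      wave <- wave + 1.8 * (spike - mean(spike))
      amp <- stats::runif(1, cfg$seizure_amp[1], cfg$seizure_amp[2])
      env <- (0.35 + 0.65 * u) * tukey_env(m)   # growing amplitude
      data[, seg] <- data[, seg] +
        outer(foci[[i]]$gains, amp * env * wave / max(abs(wave)))
      seiz_entries <- rbind(seiz_entries,
                            data.frame(start_s = on, end_s = on + durs[i],
                                       label = "seizure", channel = NA_integer_))
    }
  }
  # --- artifacts
  art_entries <- NULL
  add_art <- function(entries, on, dur, label, ch0based) {
    rbind(entries, data.frame(start_s = on, end_s = on + dur, label = label,
                              channel = as.integer(ch0based)))
  }
  rates <- cfg$artifact_rates_per_h
  for (type in names(rates)) {
    if (rates[[type]] <= 0) next
    k <- stats::rpois(1, rates[[type]] * cfg$duration_s / 3600)
    if (k == 0) next
    durs <- switch(type,
      musc = stats::runif(k, 2, 8),
      eyem = stats::runif(k, 0.5, 2),
      elpp = stats::runif(k, 3, 10),
      chew = stats::runif(k, 3, 8))
    chans <- switch(type,
      musc = lapply(seq_len(k), function(i) sample(seq_len(nch), 1)),
      eyem = replicate(k, c(1L, 3L), simplify = FALSE),   # frontal-adjacent
      elpp = lapply(seq_len(k), function(i) sample(seq_len(nch), 1)),
      chew = lapply(seq_len(k), function(i) sort(sample(seq_len(nch), 2))))
    pl <- place_events(k, durs, cfg$duration_s, occupied, chans)
    occupied <- pl$occupied
    for (i in seq_len(k)) {
      on <- pl$onsets[i]
      if (is.na(on)) next
      i0 <- floor(on * fs) + 1L
      i1 <- min(n, i0 + round(durs[i] * fs) - 1L)
      seg <- i0:i1
      m <- length(seg)
      u <- seq(0, 1, length.out = m)
      wavem <- switch(type,
        musc = {
          if (stats::runif(1) < cfg$musc_confusable_frac) {
            # seizure-confusable: sharp EMG bursts repeating at spike-wave
            # rates (the rhythmic chewing/patting artifact). Full surface-EMG
            # band (reaching ~10 Hz, so the bursts carry energy in the same
            # 8-16 Hz detail band as an ictal spike) at temporalis-proximity
            # amplitudes.
            amp <- stats::runif(1, 60, 150)
            base <- band_noise(m, fs, 10, min(fs / 2 - 1, 120))
            f_env <- stats::runif(1, 3, 5)
            bw <- stats::runif(1, 0.03, 0.06)
            ph <- (f_env * u * durs[i]) %% 1
            env <- 0.1 + exp(-0.5 * ((ph - 0.5) / (f_env * bw))^2)
          } else {
            amp <- stats::runif(1, 40, 80)
            base <- band_noise(m, fs, 20, min(fs / 2 - 1, 120))
            env <- tukey_env(m)
          }
          amp * env * base
        },
        eyem = {
          # blink-like deflections: asymmetric triangles (fast rise, slower
          # fall) whose corners put energy into the upper detail bands;
          # amplitudes as seen on TEMPORAL derivations, i.e. attenuated
          # relative to the frontal-pole blink field
          amp <- stats::runif(1, 100, 200) * sample(c(-1, 1), 1)
          n_blinks <- sample(1:3, 1)
          y <- numeric(m)
          tloc <- sort(stats::runif(n_blinks, 0.1, 0.9)) * durs[i]
          for (b in seq_len(n_blinks)) {
            width <- stats::runif(1, 0.25, 0.5)
            rise <- 0.3 * width
            tb <- u * durs[i] - tloc[b]
            y <- y + pmax(0, pmin(tb / rise + 1, 1 - tb / (width - rise)))
          }
          amp * y
        },
        elpp = {
          # step + exponential recovery, with contact "crackle" riding the
          # decay (the broadband signature of an unstable electrode)
          amp <- stats::runif(1, 200, 400) * sample(c(-1, 1), 1)
          tau <- stats::runif(1, 0.5, 2)
          env <- exp(-(u * durs[i]) / tau)
          amp * env + stats::runif(1, 8, 15) * (0.3 + 0.7 * env) *
            band_noise(m, fs, 8, min(fs / 2 - 1, 120))
        },
        chew = {
          amp <- stats::runif(1, 40, 100)
          f_env <- stats::runif(1, 1, 3)
          f_car <- stats::runif(1, 25, 60)
          carrier <- sin(2 * pi * f_car * u * durs[i]) +
            0.3 * band_noise(m, fs, 20, min(fs / 2 - 1, 100))
          amp * abs(sin(pi * f_env * u * durs[i])) * carrier
        })
      for (ch in chans[[i]]) {
        gain <- if (length(chans[[i]]) > 1) stats::runif(1, 0.6, 1) else 1
        data[ch, seg] <- data[ch, seg] + gain * wavem
        art_entries <- add_art(art_entries, on, durs[i], type, ch - 1L)
      }
    }
  }
  rec <- eeg_recording(data, fs, ch_names, record_id)
  seiz_voc <- tibble::tibble(code = 0:1, label = c("bckg", "seizure"))
  seizures <- label_track(
    if (is.null(seiz_entries)) {
      data.frame(start_s = numeric(), end_s = numeric(),
                 label = character(), channel = integer())
    } else seiz_entries,
    vocabulary = seiz_voc, record_id = record_id)
  artifacts <- label_track(
    if (is.null(art_entries)) {
      data.frame(start_s = numeric(), end_s = numeric(),
                 label = character(), channel = integer())
    } else art_entries,
    vocabulary = artifact_vocabulary(), record_id = record_id)
  list(recording = rec, seizures = seizures, artifacts = artifacts)
}

#' Generate a multi-record synthetic dataset
#'
#' Each record draws from an independent seeded substream, so record i's
#' content depends only on the base seed and i, never on how many other
#' records are generated.
#'
#' @param cfg a [synth_config()].
#' @param n_records number of records.
#' @param seed base seed.
#' @param id_prefix record ids are `sprintf("%s%02d", id_prefix, i)`.
#' @return A list of [gen_record()] results.
#' @export
gen_dataset <- function(cfg, n_records, seed = 0, id_prefix = "synth") {
  lapply(seq_len(n_records), function(i) {
    gen_record(cfg, seed = record_substream_seed(seed, i),
               record_id = sprintf("%s%02d", id_prefix, i))
  })
}

# deterministic per-record substream seed, kept below 2^31
record_substream_seed <- function(seed, i) {
  (as.numeric(seed) + 104729 * as.numeric(i)) %% 2147483647
}

#' Write a synthetic dataset as EDF + annotation CSV
#'
#' Emits `<id>.edf`, `<id>_seizures.csv` and `<id>_artifacts.csv` per record,
#' so the synthetic path exercises the EDF/CSV readers end-to-end.
#'
#' @param dataset a [gen_dataset()] result.
#' @param dir output directory (created if needed).
#' @return Tibble of written paths, invisibly.
#' @export
write_synthetic_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(dataset, function(r) {
    id <- r$recording$record_id
    edf <- file.path(dir, paste0(id, ".edf"))
    sz <- file.path(dir, paste0(id, "_seizures.csv"))
    ar <- file.path(dir, paste0(id, "_artifacts.csv"))
    write_edf(r$recording, edf)
    write_annotations(r$seizures, sz)
    write_annotations(r$artifacts, ar)
    tibble::tibble(record_id = id, edf = edf, seizures = sz, artifacts = ar)
  })
  invisible(dplyr::bind_rows(rows))
}
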