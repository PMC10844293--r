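Package: eeggate
Title: Artifact-Gated Seizure Detection for Low-Channel Wearable EEG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A combined seizure and artifact detection signal chain for
    low-channel (four temporal bipolar derivations) wearable EEG. Provides EDF
    and annotation-CSV readers, bipolar montage construction and polyphase
    resampling, windowed Haar wavelet detail-energy and FFT high-band-energy
    features, class-weighted gradient-boosted tree detectors for seizures and
    for artifacts (binary, per-channel and per-channel multiclass labelings),
    majority-vote prediction smoothing, an artifact gate that suppresses
    artifact-induced seizure false alarms, minimal cost-complexity pruning of
    tree ensembles to a byte budget, a compact three-array (7 bytes per node)
    embedded inference format with a reference interpreter, window- and
    event-level evaluation around the false-alarms-per-hour metric with
    record-level cross-validation schemes, and a jointly-labeled synthetic EEG
    generator so the full cascade can be studied without external datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    xgboost,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
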