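---
title: "Artifact-gated seizure detection: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Artifact-gated seizure detection: models, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of what it computes and why the
defaults are what they are. Everything quantitative stated here is computed
by the test suite or by `scripts/acceptance.R`; nothing is quoted from
elsewhere.

## The problem

A wearable EEG for epilepsy monitoring has four temporal bipolar
derivations, a battery, and a microcontroller. Three constraints shape the
detector design:

* **False alarms matter more than sensitivity.** A detector that cries wolf
  hourly gets taken off. With one decision per `W`-second window, FP/h
  = `3600/W × (1 − Sp)`, so specificity must live in the 99.9% range before
  the alarm rate becomes tolerable. `fp_per_hour_from_specificity()` is this
  conversion; `metrics_report()` computes it both from the formula and by
  direct counting (they agree identically by construction).
* **Artifacts mimic seizures.** Muscle bursts with a rhythmic 3–5 Hz
  envelope, high-voltage ocular deflections, chewing — all can fool a
  seizure detector that has never seen them. The package's central object is
  therefore a *cascade*: an artifact classifier (A) vetoes windows before
  the seizure classifier's (S) alarm is allowed through.
* **Memory is finite.** Tree ensembles are pruned to a byte budget and
  flattened to a 7-byte-per-node array format (`flatten()`,
  `prune_to_budget()`).

## Features

Per window and channel we compute four Haar detail-band energies and the FFT
energy strictly above 80 Hz (`build_feature_matrix()`).

The Haar filters are orthonormal (±1/√2), so the detail energies are
projection energies onto an orthonormal basis and Parseval holds exactly:
detail energies plus final approximation energy equal `sum(x^2)` whenever
the window length is divisible by `2^levels`. The test suite asserts this to
a relative error below 1e−9. Odd intermediate lengths use repeat-last
extension per level, boundary coefficients included. Note what the feature
set *cannot* see: the final approximation band (0–7.8 Hz at 250 Hz) is not a
feature, so a pure slow wave is visible only through its harmonics and
corners. Several generator-design choices below follow from this.

The one-sided FFT band energy doubles non-DC/non-Nyquist bin powers so that
band energies decompose the Parseval total; "above 80 Hz" is a strict
inequality on bin frequency `k·fs/N`.

Window labels: a window is **ictal** when seizure intervals cover strictly
more than half of it; it is an **artifact** (per channel) when any artifact
interval touches it — the asymmetry follows the two tasks' conventions, and
a `rule = "majority"` switch exists for sensitivity analyses. When two
artifact types touch one (window, channel), the larger overlap wins, ties to
the lower class code.

## Detectors

Both classifiers are gradient-boosted tree ensembles trained by XGBoost
(exact greedy splits, single thread — bit-deterministic for a fixed
configuration) with per-sample weights `class_weights[y]`, where
`balanced_class_weights()` gives inverse-frequency weights normalized to
unit mean. The default hyperparameters are a fixed set: 72 trees (divisible
by both 8 and 9, so the ensemble maps onto common embedded core counts
without padding), depth 6, learning rate 0.1, L2 regularization 1. No
automated model search is performed.

After fitting, every tree is extracted into a package-owned node table and
annotated with training risks: for tree *m*, the per-sample gradients
`g = w(p − y)` and hessians `h = w·p(1−p)` are recomputed from the
incremental margins by the package's own traversal, and the node risk is the
weighted squared-error of the tree's own fitting targets `t = −g/h` around
the node's h-weighted mean. This makes the risk an exact sum-of-squares
decomposition (children never exceed their parent; asserted in tests), so
weakest-link pruning below is well-posed. Collapsed nodes receive the
regularized leaf value `−Σg/(Σh + λ)` times the learning rate, consistent
with trained leaves. Ensemble scoring is validated two ways: against a
deliberately naive per-row recursive scorer, and against XGBoost's own
`predict` on the unpruned model.

### Pruning to a budget

`mccp_prune()` is classical minimal cost-complexity pruning transplanted to
boosted regression trees: repeatedly collapse the internal node with the
smallest effective alpha `g(t) = (R(t) − R(subtree)) / (|leaves| − 1)` while
`g(t) ≤ α`. The transplant — risks as above, one global α across all trees —
is this package's choice; tests verify the result against brute-force
enumeration of all pruned subtrees on trees up to 15 nodes, plus the nesting
and loss-monotonicity properties. `prune_to_budget()` sweeps the ensemble's
own critical alphas (smallest first) and returns the least-pruned model
whose compact size fits the budget; typical budgets are the 128 kB L1 and
1.5 MB L2 of current low-power parallel MCUs.

### The compact format

Three arrays per tree, breadth-first: feature byte (255 = leaf), 16-bit
index of the left child (right child adjacent; leaves self-reference), and a
32-bit float threshold or leaf value — 1 + 2 + 4 = 7 bytes per node. Tree
offsets and metadata are costed separately (`header_bytes()`) because the
7-byte figure is the per-node payload. Traversal goes left on
`x < threshold`, right on ties — the convention the training library uses,
asserted by a 10⁴-vector differential test demanding *zero* mismatches
between `compact_infer()` and the 32-bit-cast source ensemble. A
little-endian binary export plus JSON sidecar (`write_compact()`) is the
mmap-ready deployment artifact.

## Smoothing and the gate

`smooth_majority()` takes the majority of k = 3 successive decisions. The
centered form (one window back, one forward) is the default; a causal form
(current + two previous) is provided for strictly on-line operation, because
the two conventions genuinely differ and both are defensible — centered
smoothing costs one window of latency, causal none but reacts later.
Edge windows use the available votes; ties resolve to 0, consistent with
the minimize-false-alarms intent.

The cascade (`cascade_predict()`) gates S's **raw** decisions before
smoothing, and treats a gated window as *rejected data*, not as a "no"
vote: the majority runs over the non-rejected decisions in each window's
neighborhood — the same available-votes rule the smoother already applies
at sequence edges. Ordering and vote semantics both matter. Scattered gate
fires inside a genuine seizure then cost nothing (their neighbors carry the
event); a block of fires at onset delays the alarm (`added_latency()`
converts the mean leading suppressed count to seconds); false alarms
outside seizures, whose own windows the artifact model flags, die. Treating
rejections as absent votes could in principle promote a borderline window
that full-neighborhood smoothing would have vetoed, so the result is
intersected with the ungated smoothed alarm set: the gated alarms are a
subset of the ungated alarms for *every* input, asserted as a property
test — the formal content of "the gate only helps specificity".

## The synthetic generator

`gen_record()` emits what the pipeline needs and nothing more: 4-channel,
250 Hz, microvolt-scaled records with ground-truth interval labels for both
seizures (global) and artifacts (per channel).

* **Background** is 1/f-shaped noise (RMS ≈ 15 µV) plus three labeled-as-
  background components that exist precisely because detectors must not be
  allowed to learn shortcuts: alpha/spindle runs (pure 8–16 Hz sinusoids up
  to ~55 µV — the physiological occupant of the 8–16 Hz detail band, with
  none of the harmonic stack of a spike-wave), slow delta/theta waves
  (2–7 Hz, up to 60 µV), and white sensor noise. Without the high-voltage
  rhythmic background, an artifact detector trained here equates "large
  band energy" with "artifact" and vetoes most seizures — an artifact of an
  impoverished world, not a property of the method.
* **Seizures** are rhythmic spike-wave trains: a 3–5 Hz fundamental with
  five 1/k-weighted harmonics, ~20% downward frequency evolution, an
  amplitude envelope growing from ~35% to 100% of a 50–150 µV peak, on two
  or more channels. Morphology is organized per *patient*: a
  `sample_seizure_focus()` draw fixes the channel-gain pattern and
  fundamental, and events jitter around it. Subject-specific detection
  presumes recurring ictal morphology; without the focus, a desk-scale
  training budget cannot generalize across events at all.
* **Artifacts**: muscle (20 Hz-to-Nyquist band noise bursts; half carry a
  3–5 Hz rhythmic envelope making them seizure-confusable — the premise of
  the whole cascade), ocular (asymmetric triangular blink deflections on
  the frontal-adjacent derivations, 100–200 µV as attenuated on temporal
  channels), electrode pops (step + exponential recovery with broadband
  contact crackle), and chewing (1–3 Hz envelope on a 25–60 Hz carrier).
  Each morphology was designed to be *visible* to the feature set —
  an early, smoother ocular model was nearly feature-invisible, which
  poisons artifact training labels rather than testing anything.
* Event rates default to 6 seizures/h (so hour-scale records carry several
  events; clinical rates are far lower and need proportionally longer
  records) and musc/eyem/elpp/chew at 20/30/6/10 per hour. Same-channel
  events never overlap; determinism is per (config, seed), and
  `gen_dataset()` gives each record an isolated substream.

What passing tests on this generator do **not** show: performance on real
scalp EEG. The generator has no volume conduction, no cardiac artifact, no
electrode drift, no inter-patient amplitude scaling beyond the focus gains,
and its artifact classes are cleaner and better balanced than any corpus.
It demonstrates that the machinery — features, weighting, gate, pruning,
evaluation — behaves as designed on data where the truth is known, not that
any particular clinical accuracy will transfer.

## The studies

Three orchestrated experiments (all seeded, all sized to run in about a
minute each on one core):

* `separability_study()` — the learnability floor: one synthetic patient,
  two default-condition training hours (artifacts included), one held-out
  hour. This must clear 50% sensitivity / 95% specificity comfortably, else
  every downstream result would be vacuous.
* `cascade_study()` — the headline experiment. A *global* seizure detector
  (twelve artifact-free half-hour patients — the clean-corpus situation;
  many patients rather than few long ones, because depth-6 trees memorize
  the channel patterns of sparse foci and fail entirely on an uncovered
  test patient) and an artifact detector (three artifact-rich, seizure-free
  hours — the artifact-corpus situation; three hours because one is
  demonstrably too few for its background specificity to transfer across
  records) each get their own
  frozen scaler (z-score by default; min–max and raw are the alternatives),
  then meet a held-out artifact-rich record of an unseen patient. Reported:
  window metrics, FP/h with and without the gate, the FP reduction (both as
  percent and ratio, since the two summaries answer differently when counts
  are small), event-level sensitivity, and the cross-feed analysis
  (artifact windows raising seizure alarms; seizure windows vetoed as
  artifact, split into onset-grouped — within the first 3 windows of the
  event, a repo-chosen cutoff — versus temporally scattered). The global
  detector's performance on an unseen patient varies considerably from seed
  to seed, as global models do; the gate's direction — strictly fewer false
  alarms at negligible event-sensitivity cost — is the stable finding.
* `weight_ratio_study()` — the weighting trade-off, in the global-model
  setting (three training patients, one unseen test patient) because the
  subject-specific task saturates both metrics and shows nothing. On the
  reference split, as the positive-class weight ratio rises 1 → 64,
  sensitivity is non-decreasing and specificity non-increasing. The
  specificity decline is the robust side of the trade-off across splits;
  the sensitivity gain on an *unseen* patient is small and can drown in
  split-to-split variation — retraining under new weights is not the
  monotone threshold shift that weighting a fixed model would be.

## Numerical and interface choices

* Resampling between the 256 Hz and 250 Hz conventions is Fourier-domain
  band-limited interpolation: exact anti-aliasing, zero phase. A polyphase
  FIR was considered and rejected because its uncompensated group delay
  breaks point-wise round-trip reconstruction.
* EDF is written with one-second records, 16-bit, symmetric physical range;
  round trips are exact to the format's quantization step.
* Annotation interchange is a four-column CSV (`start_s,end_s,label,
  channel`), half-open intervals in seconds, `channel` 0-based or `global`.
  Overlapping same-channel entries with different labels are rejected.
* Channel-name matching is case-insensitive; the T3/T7-era synonymy is
  honored only through an explicit `alias_map`, never silently.
* Thresholds: both classifiers decide at probability 0.5; no threshold
  tuning is performed anywhere.
* Every stochastic operation takes an explicit seed; derived substream
  seeds stay below 2³¹.

## Known limitations

* The MCCP risk transplant to boosted trees is principled but not unique;
  other risk definitions (e.g. held-out loss) would prune differently.
* The MMC (per-channel 13-class) path trains and predicts but is exercised
  at desk scale only; the compact format stores per-class trees for it,
  while the gate itself uses the BC output (any-channel OR in MC mode).
* Event-level metrics on hour-scale records rest on a handful of events;
  single-event losses move them by tens of percentage points. The window
  metrics are the stable currency at this scale.
* The generator's realism limits are listed above; no claim about clinical
  data follows from synthetic results.
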