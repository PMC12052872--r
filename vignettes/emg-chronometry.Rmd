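---
title: "EMG-based chronometric decomposition: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{EMG-based chronometric decomposition: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(emgchrono)
```

## The measurement problem

A button-press reaction time (RT) in a two-choice task confounds two very
different intervals: the time the brain takes to commit to a response, and
the time the hand takes to execute it. Surface EMG recorded over the
response muscles (here, the thenar eminence of each hand) makes the
boundary observable: the burst of muscle activity that precedes the press
splits RT into a **premotor time** (PMT: stimulus onset to EMG burst
onset) and a **motor time** (MT: EMG onset to the registered press), with
PMT + MT = RT by construction. The same recordings expose **partial
errors** — covert bursts of the *incorrect* hand on trials that end with a
correct press — which are invisible in button data yet central to how
response control trades speed against accuracy.

`emgchrono` implements this measurement chain end to end for a 3
(speed–accuracy instruction: neutral / accuracy / speed) × 2 (lexicality:
word / pseudoword) lexical-decision design, together with a synthetic-data
generator that provides ground truth for validation.

## The processing chain and its assumptions

1. **Filtering** (`highpass_filter()`, `notch_filter()`): a 10-Hz order-2
   Butterworth high-pass and a 50-Hz notch run on the *continuous*
   recording, before epoching. Filters are applied forward–backward by
   default, so onsets are not displaced by group delay; the effective
   magnitude response is the squared single-pass response. The notch is a
   second-order IIR with a 2-Hz −3 dB bandwidth (the bandwidth is a free
   design choice; it is configurable).
2. **Epoching** (`epoch_stimulus_locked()`): epochs run from 500 ms before
   stimulus onset to 1000 ms past the condition's response deadline
   (deadlines 1500 / 5000 / 800 ms), i.e. 2500 / 6000 / 1800 ms
   post-stimulus, so even the slowest admissible burst is contained whole.
   Epochs that would overrun the recording are flagged, not fatal.
3. **Onset detection** (`integrated_profile_onset()`): the cumulative sum
   of rectified amplitudes minus the chord joining its endpoints; the
   minimum marks the burst onset. The argmin convention is followed
   literally: on an ideal step it lands on the last quiescent sample, a
   documented bias of at most one sample. Ties break toward the earliest
   index; a flat profile (constant rectified amplitude) is a degenerate
   input and raises an error. The search spans the full epoch, baseline
   included.
4. **Activity windows** (`detect_windows()`): samples exceeding
   mean + 3.5 SD of rectified baseline activity (−500 to 0 ms, SD with
   n − 1) are grouped into runs; runs separated by gaps *strictly* shorter
   than 25 ms are merged; merged windows shorter than 50 ms, or starting
   at/after the press, are discarded — in that fixed order.
5. **Validation** (`validate_onset()`): an onset is kept only if it marks
   the *last* activity window before the press, within a 10-ms tolerance
   before the window start (absorbing the argmin bias and filter
   ringing). This replaces the trial-by-trial visual inspection used in
   laboratory practice with an explicit, reproducible criterion; at the
   default generator conditions it excludes roughly 2–3% of epochs, the
   order of magnitude practitioners report. The criterion is an
   approximation of human judgement, and the per-trial reason codes in
   `trials.tsv` serve as the review export.
6. **Covert activations** (`detect_partial_activations()`): the same
   threshold/merge/duration/pre-press rules run on the non-responding
   channel; each retained window yields a partial error (correct press)
   or partial correct (overt-error press), with its onset re-estimated by
   the integrated profile on a local segment starting 50 ms before the
   window.
7. **Classification and summaries**: trials partition into pure-correct,
   overt-error, partial-error, partial-correct, no-response and excluded
   classes. Conditional accuracy functions (CAF) bin responded trials
   into K = 5 equal-count RT quantiles per cell; conditional
   incorrect-activation functions (CIAF) pool overt-response latencies
   with partial-error onsets and track the proportion of incorrect
   activations per latency bin. Rates: partial-error rate =
   partial-error trials / correct-response trials; correction likelihood
   = partial-error trials / (partial-error + overt-error trials).
8. **Curve metrics** (`average_curve()`, `curve_amplitude()`,
   `curve_slope()`): onset-locked (−500 to 1000 ms) segments of
   pure-correct trials are rectified and averaged per cell, ignoring
   pad-masked samples. The amplitude metric is the mean from onset until
   the falling flank first returns to ≤ 30% of the absolute peak
   (peak searched at t ≥ 0; a monotone curve sets a no-return flag); the
   slope metric is the OLS coefficient over 0–30 ms inclusive, in µV/ms.
9. **Inference helpers**: `morey_ci()` implements the two-step
   within-participant CI (participant-mean centering plus the
   √(J/(J−1)) bias correction); `bic_bayes_factor()` implements
   exp(ΔBIC/2). Model fitting itself is out of scope — the pipeline
   exports model-ready long-format tables (centered quantiles,
   orthogonal-polynomial columns of degree ≤ 2) for lme4-class tools.

### Numerical and convention choices

- Times are ms; samples are addressed 1-based in R code; all windows are
  half-open `[start, end)`. Onset-locked segments have inclusive
  endpoints (1501 samples at 1 kHz).
- Quantile bins are rank-based equal-count (trial with 0-based stable
  rank r goes to bin ⌊rK/n⌋ + 1), so the functions are invariant to
  monotone latency transforms; ties keep input order, making every
  summary deterministic.
- "Merged when separated by less than 25 ms" is read strictly: a gap of
  exactly 25 ms does not merge.
- Curve averaging uses rectified signals: a signed mean would cancel
  across motor-unit phase and make amplitude/slope meaningless. A config
  switch (`rectify_curves`) exposes signed averaging for comparison.
- Degenerate inputs error loudly (flat integrated profile, empty
  baseline, slope window with fewer than two samples) rather than
  returning silent values; per-trial failures downgrade to exclusion
  flags so a dataset-level run never aborts.

## What the generator emulates — and what it does not

`generator_spec()` encodes the study conditions:

- **Latencies.** PMT and MT are shifted log-normal (positive support,
  right skew); condition effects are additive shifts patterned on the
  design's fixed-effect structure: PMT 524.27 ms base, +61.64 pseudoword,
  +172.41 accuracy, −94.87 speed, interactions +29.71/−25.06; MT
  132.59 ms base, +5.94/+23.07/−24.37 with no lexicality-by-SAT
  interaction (the design's null). Random structure is crossed:
  participant intercepts (SD 60/18 ms), an item-pair difficulty component
  (SD 70 ms) shared between a word and its matched pseudoword trial —
  mirroring the psycholinguistic matching of the stimulus sets — and
  independent trial noise (SD 20/22 ms).
- **Signal.** 1000-Hz two-channel Gaussian baseline (SD 2 µV) with the
  response burst as a raised-cosine rise (30 ms) – plateau (until
  MT + 20 ms) – decay (80 ms) envelope over a Gaussian carrier. The
  default burst SNR (carrier RMS / baseline SD) is 25: thenar bursts at
  the ~500-g press forces used with handheld buttons sit one to two
  orders of magnitude above a well-prepared baseline, and at this SNR the
  last-window validation excludes the realistic ~2% of epochs. The
  onset-accuracy unit test separately probes the detector at SNR 5.
- **Events.** Overt errors per SAT condition (6/3/10%), with half of the
  speed-condition errors drawn from a fast-guess component (PMT reduced
  by 200 ms) — the source of the first-quantile CIAF enrichment under
  speed pressure. Partial errors on 5% of correct trials (sub-press
  bursts, 0.7 × burst amplitude, 120 ms, onset 60–250 ms before the
  PMT); partial corrects on 15% of overt-error trials (~1% of epochs).
  RTs that miss the condition deadline become no-response trials; these
  are generated without any burst, on the reading that the response was
  never initiated. No-response trials are their own class, not errors.

Not emulated, hence not demonstrated by passing tests: real motor-unit
waveforms (the carrier is Gaussian noise, not recorded EMG templates),
tonic baseline drift and electrode artifacts, condition effects on burst
*shape* (one envelope family serves all cells, so SAT effects on curve
amplitude/slope are deliberately absent from the synthetic data),
sequential effects across trials, and the lexical decision process
itself (no evidence-accumulation model — latencies are drawn, not
generated by a decision mechanism).

## Validation design and problem sizes

The package validates itself in three tiers, all run by the test suite:

- **Exact oracles**: the onset detector against exhaustive argmin
  evaluation (1000 random segments, length ≤ 200); the window rules
  against a scan-based brute-force implementation (1000 random masks,
  length ≤ 3000); Morey CIs against a long-hand two-step computation;
  curve metrics against closed forms (the sampled isoceles triangle has
  mean 95.35A/170 over its [0, 170) ms window).
- **Study-scale recovery** (8 participants × 105 trials/cell, 5040
  trials): PMT + MT = RT on every retained trial; partial-error
  sensitivity ≥ 0.90 at false-alarm rate ≤ 0.02 against generator truth;
  first-bin CIAF enrichment under speed recovered within the binomial
  sampling error of the truth-derived rate.
- **Effect recovery** (40 participants × 100 trials/cell, 24,000
  trials): pipeline-estimated cell-mean differences for the PMT
  lexicality effect, MT lexicality effect and MT speed effect land
  within ±3 ms of the programmed +61.64, +5.94 and −24.37 ms. The
  item-pair sharing in the generator is what makes a ±3 ms check
  meaningful at this size: lexicality contrasts are paired, so their
  Monte-Carlo error comes only from the unshared noise components and
  the onset-estimation error (whose small positive bias — the envelope
  rise crossing the chord slope a few ms after the true onset — is
  common to both cells and cancels in the difference).

`scripts/acceptance.R` reruns a 16-participant × 50-trials/cell version
of the same chain from scratch and reports the recovered rates and
effects as JSON.

## Known limitations

- The integrated profile is a global criterion: a second large burst in
  the same epoch (e.g. a double press) can capture the minimum. The
  last-window validation catches most such epochs, but it rejects rather
  than repairs them.
- Partial-error *latencies* inherit the detector's few-ms late bias;
  CIAF bins are wide (quintiles), so binning is unaffected, but users of
  raw covert latencies should expect that bias.
- The amplitude metric depends on the 30% return rule reaching below
  threshold within the curve; cells averaged from very few epochs can
  set the no-return flag and should be treated as missing, not zero.
- Exclusion behavior is calibrated to the synthetic SNR regime; on real
  recordings with poor skin preparation the 3.5 SD threshold and 10-ms
  validation tolerance may need revisiting (both are `run_config()`
  fields).
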