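# emgchrono

Chronometric decomposition of two-choice reaction times from surface EMG.

A button-press RT mixes the time to *decide* with the time to *act*. With
EMG recorded over the response muscles of both hands (thenar eminence,
one channel per hand), the burst preceding each press splits RT into a
**premotor time** (PMT: stimulus onset → EMG burst onset) and a **motor
time** (MT: EMG onset → press), with PMT + MT = RT. The incorrect hand's
channel additionally reveals **partial errors**: covert incorrect
activations on trials that end with a correct press. `emgchrono`
implements the full measurement chain for a speed–accuracy tradeoff
(SAT: neutral / accuracy / speed) × lexicality (word / pseudoword)
lexical-decision design, for researchers in mental chronometry and
response-control psychophysiology.

## What it computes

- **Preprocessing** — zero-phase 10-Hz order-2 Butterworth high-pass and
  50-Hz notch on the continuous recording; stimulus-locked epochs from
  −500 ms to 1000 ms past each condition's deadline.
- **EMG onset** — the integrated-profile method: with rectified
  amplitudes `|x|`, compute `c_i = Σ_{j≤i} |x_j|` and the chord
  `L_i = c_1 + (c_n − c_1)(i−1)/(n−1)`; the onset is
  `argmin_i (c_i − L_i)`.
- **Activity windows** — samples above `mean + 3.5·SD` of the rectified
  −500–0 ms baseline, merged across gaps < 25 ms, kept if ≥ 50 ms and
  starting before the press; an onset is valid only inside the *last*
  pre-press window. The same rules on the non-responding channel detect
  partial errors and partial corrects.
- **Trial table** — per-trial PMT/MT, analysis class (pure-correct,
  overt-error, partial-error, partial-correct, no-response, excluded)
  and covert-activation latencies.
- **Conditional functions** — CAF (accuracy by RT quantile, K = 5
  equal-count bins) and CIAF (proportion of incorrect activations by
  pooled overt/partial latency quantile); partial-error rate and
  correction likelihood; within-participant 95% CIs with the Morey
  √(J/(J−1)) correction; the BIC Bayes-factor approximation
  `exp(ΔBIC/2)`.
- **EMG curves** — onset-locked rectified averages per cell; mean
  amplitude up to the 30%-of-peak return point and the 0–30 ms
  rising-flank OLS slope.
- **Synthetic data** — `generator_spec()` / `generate_dataset()` produce
  continuous two-channel recordings, event tables and ground truth with
  the study's latency structure (shifted log-normal PMT/MT, crossed
  participant and matched-item components, fast-guess errors under speed
  pressure, 5% partial errors, per-condition deadlines), so every stage
  is testable by parameter recovery without any data download.

## Worked example

The `analysis/` scripts run the whole workflow on a simulated study
(8 participants × 6 cells × 20 trials):

```sh
Rscript analysis/01_simulate.R        # raw TSV recordings + events
Rscript analysis/02_pipeline.R       # filter/epoch/detect/decompose
Rscript analysis/03_chronometry.R    # PMT/MT cell means, Morey CIs, BF
Rscript analysis/04_conditional_functions.R
Rscript analysis/05_emg_curves.R
```

`02_pipeline.R` prints the trial classification:

```
trial classes:
         pure_correct           overt_error   partial_error_trial
                  827                    57                    38
partial_correct_trial           no_response              excluded
                    9                     1                    28
excluded epochs: 2.9%
```

— 38 of 960 trials carried a covert incorrect activation despite a
correct press, and 2.9% of epochs failed the last-window onset check
(the automated stand-in for visual inspection). `03_chronometry.R` then
recovers the programmed latency structure:

```
cell means (pure-correct trials):
      sat lexicality rt_ms pmt_ms mt_ms
 accuracy pseudoword 946.7  785.6 161.1
 accuracy       word 845.3  688.7 156.6
  neutral pseudoword 720.7  585.6 135.2
  neutral       word 650.6  523.0 127.7
    speed pseudoword 582.8  473.7 109.1
    speed       word 540.7  431.4 109.3

lexicality effects (pseudoword - word), ms:
  neutral  PMT   62.6   MT   7.5
  accuracy PMT   96.9   MT   4.6
  speed    PMT   42.3   MT  -0.3

BF for the MT interaction = 0.00841  -> no support for an interaction
```

The pseudoword cost loads on PMT (62.6 ms in neutral blocks) and is
modulated by SAT instructions, while the small MT effect is not — the
pattern the decomposition is designed to expose. `04_conditional_functions.R`
shows the CIAF signature of response capture: under speed instructions
the fastest latency quintile is dominated by incorrect activations
(0.418 vs 0.045 in the slowest).

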