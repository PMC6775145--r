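---
title: "Sleep staging from heart-rate variability: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sleep staging from heart-rate variability: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Polysomnographic sleep staging assigns one of a small set of stages to every
30-second epoch of a night. `hrvstager` performs this four-class staging
(wake `W`, REM `R`, light sleep `N1N2`, deep sleep `N3`) from the cardiac
signal alone: the input is a sequence of inter-beat (RR) intervals, the
output a per-epoch posterior over the four stages. The scientific basis is
that autonomic state varies systematically across sleep stages — heart rate
falls and respiratory sinus arrhythmia (parasympathetically mediated
high-frequency HRV) grows with sleep depth, while sympathetic Mayer-wave
activity near 0.1 Hz moves the opposite way — so a sufficiently rich HRV
description carries stage information, and a sequence model can exploit the
strong temporal structure of sleep architecture.

The pipeline has three stages, each an independent module surface:

1. **Feature extraction**: 132 HRV features per 30-s epoch, computed on
   windows centred on the epoch.
2. **Sequence classification**: a bidirectional LSTM over whole-night
   feature sequences, trained with a soft-label categorical cross-entropy
   that encodes inter-scorer disagreement.
3. **Evaluation**: per-night Cohen's kappa, accuracy and per-stage metrics,
   with demographic and clinical subgroup statistics.

A fourth module, the synthetic cohort simulator, exists so the entire
pipeline is exercisable and testable without clinical data.

## The feature battery

All features are computed per epoch from a window centred on the epoch
(centre `30e + 15` s). The default window is 270 s; windowed detrended
fluctuation analysis uses 330 s and multiscale entropy 510 s, so each window
remains an odd multiple of 30 s and centres exactly. At recording edges
windows truncate; a family's features are missing for an epoch when less
than half the nominal span remains, when fewer than 80% of the window's
beats are valid (`min_valid_fraction`), or when the family's own minimum
beat count is unmet. Missing values are left as `NA` at this stage —
imputation belongs to the model module, so feature files remain an honest
record of what was measurable.

The 15 families (132 columns, fixed registry order):

| family | n | content |
|---|---|---|
| basic | 4 | mean/median RR and HR |
| variability | 12 | SDNN, range, pNN50, RMSSD, SDSD, mean absolute deviation; absolute and detrended |
| percentiles | 28 | 7 percentiles × RR/HR × absolute/detrended |
| dfa | 6 | α(4–64), α(4–16), α(16–64), F(16), windowed and per-segment DFA |
| spectral | 4 | ln VLF/LF/HF power, LF/HF ratio (Welch) |
| spectral-adapted | 4 | the same with a respiration-centred HF band |
| hf-pole | 4 | respiratory frequency/power; AR(9) HF pole phase and modulus |
| mse | 20 | sample entropy, m ∈ {1,2}, scales 1–10 |
| symbolic | 1 | sample entropy of binary RR-change symbols |
| phase-coord | 2 | short/long-range repetition of RR sign patterns |
| phase-sync | 7 | 6:2…9:2 cardiorespiratory locking rates, dominant ratio, episode stats |
| higuchi | 1 | Higuchi fractal dimension |
| teager | 21 | Teager energy; transition-point/maxima statistics on the z-scored IBI and its first EMD mode |
| arousal | 5 | summary statistics of a surrogate arousal-probability signal |
| visibility | 13 | natural and difference visibility-graph descriptors |

Decisions worth recording, because the underlying definitions are used in
several variants in the literature:

* **"Detrended"** means removal of the per-window OLS line of RR against
  beat index. Mean and median of a detrended signal are ≈ 0 and carry no
  information, so the basic family uses the absolute signal only — that is
  how the family count is 4, not 8.
* **DFA** integrates the mean-centred series *including its leading zero*
  and tiles boxes from both ends of the profile. This makes the fluctuation
  function exactly invariant under time reversal (a property the test suite
  asserts at 1e-6) at negligible cost; forward-only tiling of the bare
  cumulative sum is not exactly reversal invariant. Box sizes run 4–64 on a
  log ladder. First-order DFA has
  a known upward bias at the smallest boxes; on white noise the recovered
  α is ≈ 0.53 rather than 0.50, which the analytic-limit tests accommodate
  within their stated ±0.05 band.
* **WDFA** averages the all-scale exponent over 150-s sub-windows stepped
  by 30 s across the 330-s window; **PDFA** averages per-segment exponents
  (scales 4–16) over consecutive non-overlapping 64-beat segments. The
  windowed/progressive variants are specified in the source literature only
  by citation; these are the package's documented conventions.
* **Spectral** features resample valid beats to a 4 Hz tachogram by cubic
  spline (gaps left by rejected beats are bridged by the spline), then use
  Welch's method with 120-s Hann segments at 50% overlap. Band powers are
  `ln(power + 1e-10)` so silent bands stay finite; the LF/HF ratio is
  missing when HF power is numerically zero. The boundary-adapted variant
  re-centres the HF band on the detected respiratory peak ± 0.1 Hz (clipped
  to [0.1, 0.5] Hz) and moves the LF upper edge to the adapted band's lower
  edge. The HF pole comes from an order-9 Burg autoregressive fit: the
  largest-modulus pole whose angle falls in the HF band; if none does, both
  pole features are missing.
* **Multiscale entropy** freezes the tolerance at `r = 0.2 × SD` of the
  scale-1 segment, the canonical choice; scales whose coarse-grained series
  falls under 30 points are missing, and a constant segment (r = 0) yields
  all 20 missing.
* **Sign conventions**: zero RR differences map to the "falling" symbol in
  every sign-based feature, so the alphabet is always binary and behaviour
  on flat segments is defined rather than accidental.
* **Phase synchronization** marks the beats of any window of n difference
  signs (n ∈ 6…9) equal to the canonical two-block template (⌈n/2⌉ rises
  then ⌊n/2⌋ falls). Circular shifts of the template are deliberately *not*
  matched: a phase-shifted locked rhythm still contains the canonical
  window once per period, so persistent locking is detected regardless of
  alignment, while admitting all rotations makes spurious matches on
  unstructured sign sequences common enough to blur the feature's contrast
  (the test suite pins the canonical rule's false-positive rate below 0.3
  on random signs). Episode durations are measured in seconds of RR time;
  the long-term coordination feature is the fraction of window time inside
  episodes of at least 30 s.
* **Teager/EMD**: transition points are sign changes of the first
  difference of a 3-point moving average; local maxima are strict. The
  empirical mode decomposition uses natural-spline envelopes through the
  extrema (endpoints included in both envelopes), a Cauchy stopping
  criterion of 0.3 and at most 100 sifts.
* **The arousal family is a labelled surrogate.** The validated
  arousal-probability model it stands in for is external to this package;
  the surrogate maps 10-s heart-rate surges against a trailing 120-s
  baseline through a logistic `p = 1/(1 + exp(-(z - 2)/0.5))` and emits
  five summary statistics with the same shape. It should be read as
  "HR-surge probability", not as a validated arousal detector.
* **Visibility graphs** use the strict natural-visibility inequality on
  (beat time, RR) points — a collinear intermediate point blocks the edge —
  and the difference graph is built on the first-difference series against
  beat index. The degree-distribution slope is the least-squares line of
  log frequency on log degree.

## The sequence model

The network is five layers: a 32-unit sigmoid perceptron on the 132
features, three bidirectional LSTM layers (64 cells per direction by
default; forward and backward outputs concatenated between layers), a
32-unit sigmoid perceptron and a 4-class softmax. "64 cells" is read as 64
*per direction*: that is the only reading under which the architecture's
widely quoted 2.6 × 10⁵ parameter count holds (the exact count is 255,812;
32 per direction would give ≈ 7.3 × 10⁴). The 32-per-direction reading
remains available through `model_config()`.

Training minimizes the soft-label categorical cross-entropy

$$H(Y,\hat Y) = -\frac{1}{N}\sum_{i=1}^{N}\sum_{c=1}^{4}
  P(Y_i{=}C_c)\,\log \hat P(Y_i{=}C_c)$$

where the targets are the fractions of human scorers who assigned each
class, so the model can learn inter-scorer uncertainty rather than a
hardened consensus. Optimization is RMSprop (lr 1e-3, ρ 0.9, ε 1e-7,
defaults overridable), with dropout 20% on the input features and 50% on
LSTM outputs and recurrent connections, applied per sequence (variational)
during training only. Softmax outputs are clipped to [1e-7, 1-1e-7] inside
the loss; gradients are clipped at global norm 5. The backpropagation-
through-time gradients are verified against central finite differences in
the test suite.

Protocol choices:

* **Whole nights are single sequences.** Batches are realized by gradient
  accumulation over nights (8 by default) rather than zero-padding plus
  masks; for a mean-over-nights batch loss the two are mathematically
  identical, and no computation is spent on pad positions.
* **Early stopping is monitored on an inner validation split** (10% of
  *training* participants, patience 100 passes by default). Monitoring the
  test fold itself — as the protocol this package reimplements describes —
  leaks test information into model selection; the deviation is deliberate,
  and `paper_faithful = TRUE` in `train_config()` restores test-fold
  monitoring for comparability.
* **Folds partition participants, never recordings** (`assign_folds()`:
  seeded shuffle, round-robin deal). Feature imputation (per-feature
  training-set medians) and z-scoring statistics are fitted per fold on the
  training portion only and stored on the model, so prediction is
  leak-free and self-contained.

## Evaluation

Per night: Cohen's κ and accuracy on the 4 × 4 epoch confusion matrix, and
per-stage precision, recall, accuracy and κ on the stage-versus-rest 2 × 2
collapse (per-stage accuracy is one-versus-rest accuracy; a stage absent
from both reference and prediction yields missing values rather than a
fabricated 0 or 1). When chance agreement is exactly 1 (degenerate
marginals), κ is defined as 1 for perfect agreement and 0 otherwise.
Cohort level: mean ± SD over nights; Pearson correlation of κ and accuracy
with age and BMI; two-sided Mann-Whitney U tests between sexes and between
each clinical group and the healthy group, computed on participant-level
averages so participants with two nights are not double-counted. The rank
tests and correlations delegate to `stats::wilcox.test()` and
`stats::cor.test()`; no multiple-testing correction is applied, matching
the reporting convention of the protocol this package follows.

## The synthetic cohort

The simulator exists to make every module testable end to end, with enough
stage-conditional structure that staging from HRV is well-posed, and no
more.

* **Hypnograms** come from a semi-Markov chain: gamma-distributed bout
  durations per stage (shape 2; means 10, 11.5, 13 and 6 minutes for W, R,
  N1N2, N3) and an embedded transition matrix favouring the
  W→N1N2→N3→N1N2→R cycle with sparse awakenings. These values were chosen
  once so that realized nights land near a typical middle-aged
  polysomnography cohort — about 67% N1/N2, 14% N3 and 18% REM of sleep,
  sleep efficiency near 81% — and are not tuned thereafter.
* **IBI series**: an instantaneous RR signal on a 0.25-s grid — per-stage
  mean RR (850, 900, 1000, 1080 ms for W, R, N1N2, N3), a 0.1 Hz Mayer
  sinusoid (amplitudes 40, 35, 25, 15 ms), a 0.25 Hz respiratory sinusoid
  (10, 15, 30, 45 ms; largest in N3, encoding parasympathetic dominance)
  and white noise (30, 25, 20, 15 ms), with stage steps smoothed over
  15 s — is converted to beat times by integral pulse frequency modulation:
  a beat fires whenever ∫dt/RR(t) crosses the next integer. RR intervals
  are therefore exactly consistent with beat times, as the I/O layer's
  validation demands.
* **Annotators** independently relabel each epoch with probability 0.15
  (default) from an adjacent-stage confusion kernel (W↔N1N2, N1N2↔N3,
  N1N2↔R preferred), producing soft labels that are multiples of 1/k.
* Clinical-group metadata are labels only; no pathological physiology is
  simulated. The subgroup statistics code paths are exercised, but nothing
  about real patient groups can be concluded from them.

What the simulator does **not** emulate — and therefore what green tests do
not show about real data: apnea and arousal events, ectopy and artifact
bursts, circadian drift within the night, stage-transition dynamics of HRV
(the simulator changes parameters at boundaries but real autonomic
transitions lead or lag the EEG stage), and any real covariance between
demographics and cardiac dynamics. Held-out performance on this cohort
(mean per-night κ ≈ 0.98 at desk scale) is an *upper* bound scenario showing
the pipeline learns and generalizes when the signal is present; it is not a
claim about clinical performance.

## Problem sizes and numerical choices

The shipped tests and the acceptance script run at desk scale, chosen as
the package's own benchmark sizes: the held-out benchmark simulates 25
participants × 2 nights of 8 h (50 nights, 48,000 epochs), trains the
reduced model (1 BiLSTM layer, 16 units per direction) on 20 participants
for up to 120 passes with patience 20, and evaluates on the 5 held-out
participants. Analytic-limit checks use series of 10⁴ points and 20 seeds;
oracle-equivalence checks use quadratic/cubic brute-force re-implementations
on series up to length 300. All randomness flows from explicit seeds;
extraction is fully deterministic, and training is deterministic given a
seed on a single thread.

## Known limitations

* The arousal family is a surrogate (above), and WDFA/PDFA internals are
  package conventions where the literature specifies them only by citation.
* R-peak detection is out of scope: the package consumes IBI series and
  trusts its cleaning pass (absolute bounds 300–2000 ms, 30% deviation from
  the 5-nearest-valid-beat median; single pass, config-overridable) to
  handle residual artifacts.
* Hypnograms must be fully labelled in the four-class alphabet; movement
  time and unscored epochs are not modelled.
* The full-size model (3 × 64/direction) trains in reasonable time on CPU
  for small cohorts, but the package makes no attempt at GPU acceleration.
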