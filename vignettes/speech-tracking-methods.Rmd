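---
title: "Encoding models of speech tracking: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Encoding models of speech tracking: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(speechTRF)
```

speechTRF implements a complete forward-modelling pipeline for neural
speech tracking: stimulus predictors (acoustic and
information-theoretic linguistic features), temporal response function
(TRF) estimation by boosting, nested model comparison, and
mass-univariate channel statistics, together with a synthetic-data
module that generates every input with known ground truth. This
vignette explains the models, the tunable parameters and their
defaults, the numerical choices, and what the simulation-based tests
do and do not establish about real data.

## The forward model

Each response channel is modelled as a linear convolution of stimulus
features with channel- and feature-specific kernels,

$$y_j(t_n) \;=\; \sum_{f=1}^{F}\sum_{k=1}^{T}
  \beta_{jf}(\tau_k)\,x_f(t_n - \tau_k) \;+\; \varepsilon_j(t_n),$$

sampled on a common analysis grid (default 100 Hz). The default lag
axis runs from −100 ms to 800 ms, left-inclusive, giving `T = 90` lag
points at 100 Hz; negative lags let the model detect spurious
"acausal" structure. Samples outside the recording are treated as
zero (zero-padding), the simplest contract and stated explicitly so
that predictions near the edges are reproducible.

Predictors and responses are normalized by their mean absolute value
(`normalize_channels()`), so kernel magnitudes are comparable across
features. Normalization happens *after* any high/low entropy
condition split, i.e. on the channels exactly as the estimator sees
them.

## Predictors

**Acoustic.** `gammatone_spectrogram()` passes the waveform through a
4th-order gammatone filterbank with 8 center frequencies equally
spaced on the Glasberg–Moore ERB-number scale between 20 and 5000 Hz,
takes the magnitude of each band output, smooths it with a zero-phase
Butterworth low-pass (default cutoff 0.4 × analysis rate), and samples
it on the analysis grid. `acoustic_edges()` is the half-wave-rectified
first temporal difference of the log-compressed envelope,
`log(1 + env/ε)` with ε defaulting to 1e−8 of the envelope maximum.
This edge operator is a deliberately simple, fully declared definition
of "positive change in the band envelope"; it does not attempt to
reproduce any specific auditory edge-detection model, which is why the
package's results for edge predictors are reproducible from the
definition alone.

**Cohort model.** A pronunciation lexicon (word, frequency per million,
space-separated phonemes) is indexed by phoneme prefix. The cohort at
a prefix is the set of words whose pronunciation starts with it; the
probability of the next phoneme is the ratio of the continuation
cohort's summed frequency to the current cohort's. Surprisal is
−log2 of that probability; phoneme entropy is the Shannon entropy of
the next-phoneme distribution at the current prefix (the same
conditioning cohort as the surprisal of the phoneme about to be
heard). Words that terminate exactly at a prefix keep their frequency
in the denominator but head no continuation: continuation
probabilities plus this termination mass sum to one. This is one
literal reading of the cohort-ratio formula; how embedded words (e.g.
*in* inside *internet*) should be treated is genuinely open, and the
choice is isolated in `build_cohort_index()`. All logs are base 2
(bits). Out-of-lexicon stimulus words get missing-value statistics and
a logged count by default — naturalistic stimuli always contain them —
with an opt-in hard-error policy.

**Word entropy.** Contextual constraint is the Shannon entropy of the
next-word distribution given up to 30 preceding words of the same
story part (context never crosses part boundaries, since parts are
presented separately). The probability provider is an abstract
contract; the shipped implementation is a word-level bigram table
whose row entropies are exact, which is what makes the oracle tests
possible. Subword tokenization of neural language models is
deliberately out of scope. `split_by_entropy()` partitions each story
part's words into high/low entropy conditions with a *threshold*
split: words are ordered by entropy (ties by onset), and the single
cut that minimizes the absolute difference in summed durations is
chosen by exhaustive search. The imbalance is therefore bounded by the
duration of the threshold-adjacent word, and the split is a
deterministic function of entropies and durations.

**Condition duplication.** `condition_duplicate()` replaces each
channel by a high- and a low-condition copy: samples inside a word's
half-open `[onset, offset)` interval go to that word's copy. Samples
covered by no word (pauses, the tail after the last offset) inherit
the most recent word's condition, so the two copies sum to the
original channel *exactly* — an invariant the tests assert
sample-exactly. The carry-forward rule is a design choice: it
preserves the partition identity for continuous acoustic channels,
which are nonzero between words.

## TRF estimation by boosting

`boosting_fit()` starts from an all-zero kernel and repeatedly
evaluates, for every (feature, lag) coordinate, adding ±δ times a
Hamming window of 50 ms (5 samples at 100 Hz) centered at that lag,
applying the single update that most reduces the training L1 error.
The Hamming window acts as the *update basis* (rather than post-hoc
smoothing): estimated kernels are sums of these bumps, truncated at
the lag-axis edges. The step size is
δ = `step_fraction` × mean |response| on the training set, default
`step_fraction = 0.005`.

Three mechanisms control overfitting and convergence:

- **Early stopping.** A validation segment distinct from both training
  and test data is monitored; fitting stops once the validation L1
  error has not reached a new minimum for `patience` (default 10)
  steps, and the kernel at the validation minimum is returned.
- **Selective stopping** (default on). An applied update that
  *increases* the validation error is undone and its coordinate
  frozen. Coordinates that only fit training noise are thereby retired
  early; frozen coordinates are released whenever the step size
  anneals. This mirrors the behaviour of established boosting
  implementations for TRFs and markedly reduces the held-out cost of
  irrelevant predictors.
- **Step-size annealing** (default 5 halvings). Fixed-step coordinate
  descent stalls when no ±δ update can reduce the training error even
  though the kernel is still far from the L1 optimum; halving δ at
  that resolution floor and continuing removes the stall. Without
  annealing, noiseless kernel recovery saturates around r ≈ 0.93;
  with it, r > 0.999.

Training error is non-increasing by construction — the tests assert
this on every fit. A response that is identically zero returns a zero
kernel (no update can reduce the L1 error); a constant nonzero
response is rejected as degenerate.

`cross_validate()` splits the time axis into `n_folds` (default 5)
contiguous blocks; for each test fold the cyclically following fold
validates and the rest train. Contiguous folds avoid leakage through
temporal autocorrelation. Held-out predictions are concatenated and
scored as the proportion of explained variance,
`1 − var(y − ŷ)/var(y)`, which may be negative. The L2-based accuracy
is a deliberate choice even though the fit minimizes L1: explained
variance is the conventional comparison scale for these models.

## Model comparison

`incremental_gains()` fits a strictly nested ladder of models — the
standard ladder is acoustic (spectrogram + edges), then adding phoneme
onset, phoneme surprisal, phoneme entropy, and word frequency — on
*identical fold boundaries*, and reports each model's accuracy and its
gain over the previous model. Gains are exactly differences of stored
accuracies; no refitting drift is possible in the bookkeeping.
`exclusion_gain()` quantifies a feature group as full-model accuracy
minus the accuracy without that group, optionally per entropy
condition. `windowed_gains()` repeats the ladder for sliding lag
windows (default: 100 ms windows stepped by 50 ms over −100…800 ms,
giving 17 windows), each labelled by its center time — the center
convention is declared here because edge labels are ambiguous in the
literature.

A caveat the simulations quantify: adding a *causally null* feature to
a model has slightly **negative** expected gain (about −0.002 to
−0.004 in accuracy units under the test conditions), not zero. Any
estimator that can select a junk predictor pays a finite-sample
capacity cost on held-out data; selective stopping reduces this cost
roughly 2.3-fold but cannot eliminate it, because the surviving null
updates are precisely those that improved the validation segment by
chance. Empirical null gains should therefore be referenced against a
simulated or permutation null, not against exactly zero.

## Channel statistics

`paired_t_map()` computes mass-univariate related-samples t statistics
per channel (or channel × time point). `tfce()` applies threshold-free
cluster enhancement: for thresholds `h` in steps of `dh`, every
suprathreshold channel accumulates `extent(h)^E · h^H · dh`, where
extent is the size of its connected component in the channel adjacency
graph; negative values are processed symmetrically on the negated map.
Defaults `E = 0.5`, `H = 2`, `dh = max|stat|/100` are the field's
standard choices and are config-exposed. Both space-only and
space × time cluster modes are supported (time points are chained as
extra graph edges). `cluster_permutation()` corrects for multiple
comparisons by sign-flipping each subject's difference map, using the
maximum absolute TFCE value as the max-statistic; the reported
per-channel p-value is the fraction of permutations whose maximum
reaches that channel's observed score. Under a simulated true null
these p-values are uniform — the calibration test runs 100 null
datasets at 200 permutations each and checks uniformity with a
Kolmogorov–Smirnov test. `smooth_map()` (Gaussian weights over channel
coordinates, rows normalized) and `weight_power()` (squared kernel
coefficients) support condition contrasts of TRF weights.

## The synthetic-data module

`simulate_study()` generates, from a single seed: a Zipfian toy
lexicon (`make_toy_lexicon()`; rank-frequency exponent exactly as
requested, alphabetic words over a letter inventory), a bigram-language
story with uniform phoneme durations of 50–150 ms — a realistic phone
duration band — laid out back-to-back (`make_story()`), the standard
predictor channels (impulse channels for phoneme onset/surprisal/
entropy and word frequency; continuous envelope-like channels of
lightly smoothed rectified noise), smooth ground-truth kernels as
Gabor-like bumps (default: an early bump at 80 ms and a broader
opposite-signed bump at 400 ms, echoing the early/late morphology of
speech TRFs), and responses as kernel convolution plus Gaussian noise
(white by default, AR(1) optional; `"snr0"` sets the noise SD to the
clean-signal SD, i.e. 0 dB). Channels get grid coordinates and
arbitrary "A"/"B" group labels in place of anatomy.

Two generator choices deserve their rationale:

- The continuous envelope stand-in is only *lightly* smoothed
  (2nd-order Butterworth at 30 Hz on rectified noise). A heavily
  low-passed envelope has no power at the frequencies where narrow TRF
  bumps live, and a kernel cannot be recovered — by any estimator —
  from a predictor that never excites it. Real gammatone envelopes
  sampled at 100 Hz retain broadband modulation energy, so the light
  smoothing is also the more realistic choice.
- The language model behind stories is a word-level bigram chain
  because its conditional entropies are available in closed form,
  which turns the word-entropy annotation into an exactly checkable
  oracle test.

What the simulations emulate: event-locked impulse structure at
phoneme/word rate, frequency-rank structure of lexica, exact
contextual entropies, convolutional responses, additive noise. What
they do not: structured (1/f, oscillatory) neural noise beyond AR(1),
correlated acoustic–linguistic features as in real speech, subword
tokenization, head anatomy, or forced-alignment errors. Passing the
parameter-recovery and calibration tests therefore establishes the
*correctness of the machinery*, not the effect sizes or significance
boundaries to expect on recordings.

## Problem sizes used in the shipped tests

Parameter recovery uses 10 response channels, 5 minutes of data at
100 Hz, and 3 predictors (two impulse trains at word- and phoneme-like
rates, one continuous envelope), at 0 dB SNR and noiselessly; mean
truth–estimate kernel correlation is ≥ 0.9 noisy and ≥ 0.99 clean.
Gain calibration uses 20 simulations of 50 s each with a reduced lag
axis (0–300 ms); permutation calibration uses 100 null datasets of 12
subjects × 16 grid channels at 200 permutations; the cohort oracle
sweeps 100 random lexica × 10 prefixes plus every word's telescoping
identity. These sizes were chosen so the full suite completes in a few
minutes while leaving every statistical check well-powered.

## Known limitations

- The acoustic-edge operator is a declared substitute for proprietary
  auditory edge models; absolute edge-TRF shapes are not comparable
  across toolboxes.
- Greedy L1 boosting with a coarse basis cannot perfectly separate
  highly collinear predictors (e.g. surprisal vs. entropy at the same
  onsets); sliding-window model comparison is the more robust way to
  localize such effects in time, which is why it is part of the
  pipeline.
- Null-feature gains are slightly negative in expectation (see above).
- The WAV reader supports 16-bit integer PCM only; the TextGrid parser
  reads the long text format's interval tiers only.
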