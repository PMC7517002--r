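---
title: "Entropy feature fusion and team-collaboration classification: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Entropy feature fusion and team-collaboration classification: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(entrofuse)
```

## The problem

Peripheral physiological signals — electrocardiogram (ECG), electromyogram
(EMG), respiration (RSP), skin conductance (SC/GSR), blood volume pulse
(BVP) — are driven by the autonomic nervous system and carry information
about a person's emotional state that is harder to fake than speech or
facial expression. These signals are non-stationary and nonlinear, so
instead of accumulating dozens of time- and frequency-domain descriptors,
`entrofuse` characterises each channel window by four regularity/complexity
statistics and lets a small committee of classifiers turn them into an
emotion label.

The pipeline is: segment each labelled multi-channel recording into
fixed-duration windows; compute four entropies per channel window; fuse the
per-channel features by concatenation; standardise; classify with a
one-vs-one (OvO) RBF-SVM whose uncertain decisions are arbitrated by a
decision tree (DT) and an extreme learning machine (ELM).

## Segmentation and labelling

Recordings are segmented by *time*, not sample count, because channels have
heterogeneous rates (ECG at 256 Hz next to 32 Hz channels). Windows are
half-open intervals `[t, t + window_s)` starting after an optional
discarded baseline; a trailing partial window is dropped, so `n =
floor((duration - baseline) / window)`. Typical protocols: 120 s music
recordings cut into ten 12 s windows; 63 s video trials with a 3 s baseline
cut into ten 6 s windows. All windows inherit the recording label; windows
are treated as i.i.d. samples thereafter (this mirrors the usual published
protocol — see *Limitations* for the leakage caveat).

Dimensional labels (valence and arousal, each rated 1–9) are mapped to
quadrant classes by `quadrant_label()`: strictly greater than 5 is High,
otherwise Low, so a rating of exactly 5 is Low. The four classes are HVHA,
HVLA, LVLA, LVHA.

## The four entropy features

All four are computed per channel window; `entropy_params()` holds the
tunables.

**Approximate entropy (ApEn).** Templates of length `m` are compared under
the Chebyshev distance; `C_i^m(r)` is the fraction of templates within
tolerance `r` of template `i` (self-matches included, matches counted as `d
<= r`), `Phi_m` is the average of `ln C_i^m`, and `ApEn = Phi_m -
Phi_{m+1}`.

**Sample entropy (SaEn).** The self-match-free refinement in the canonical
Richman–Moorman form: `B` and `A` are the match fractions over the first `N
- m` templates at dimensions `m` and `m + 1` (pairs `i != j`), and `SaEn =
-ln(A/B)`. Some published statements of the algorithm typeset a logarithm
inside the template average, which would make the final ratio ill-formed;
the canonical plain averages are implemented. When no pair matches at
either dimension the statistic is undefined; `sample_entropy()` raises an
error (or returns `NA` on request) rather than inventing a value.

**Fuzzy entropy (FuEn).** Replaces the hard threshold with the smooth
membership `A_ij = exp(-ln(2) (D_ij / r)^2)`, which equals 1/2 exactly at
`D = r`. Per-template means `C_i` (self-pairs excluded) are averaged
plainly into `Phi_m`, and `FuEn = ln Phi_m - ln Phi_{m+1}`. Two deliberate
choices: the template mean is *not* subtracted before the distance (unlike
Chen's original formulation), and the membership exponent is fixed at 2.

**Wavelet packet entropy (WpEn).** A full wavelet-packet filter bank
(orthonormal, periodic boundary) decomposes the window to level `depth`;
each of the `2^depth` terminal bands contributes its coefficient energy
`E_j`, and `WpEn` is the Shannon entropy of the proportions `p_j = E_j /
sum(E)` with `0 ln 0 = 0`. Bounded by `ln(2^depth)`; exactly 0 when the
energy sits in one band.

**Parameter defaults and why.** `m = 2` and `r = 0.2 * sd(window)` sit in
the ranges the entropy literature recommends (`m` 2–5, `r` 0.1–0.25 sd) for
short physiological windows; `r` is recomputed from each individual segment
channel, which makes ApEn/SaEn/FuEn invariant to amplitude scaling (WpEn is
invariant by construction, since the `p_j` are ratios). The wavelet family
(`db4`) and depth (3) are common choices for biosignal band analysis; none
of the four is prescribed by the protocols this package emulates, so all
are exposed in `entropy_params()`. Matches are counted as `d <= r`
(canonical; the strict `<` variant differs only on measure-zero ties).
Zero-variance windows return 0 for the template entropies (perfect
regularity) and raise for WpEn (no energy distribution).

## Fusion and scaling

`fuse()` concatenates the per-channel quadruples in declared channel order
— 16 dimensions for four channels, features ordered (ApEn, SaEn, FuEn,
WpEn) within each block. Nothing else happens at fusion time, so
single-channel feature tables are exact column subsets of the fused table;
any accuracy gain from fusion is attributable to channel complementarity,
not preprocessing.

A z-score scaler (`fit_scaler()`/`apply_scaler()`) is fitted on training
rows only and applied to both splits. The source protocols are silent on
scaling, but the RBF-SVM and the ELM are scale-sensitive, so an explicit,
disableable scaler is part of the evaluation loop (`run_experiment(...,
scale = FALSE)` turns it off). Zero-variance columns pass through
untouched.

## The three base learners

**OvO RBF-SVM** (`train_svm()`), the main decider. One soft-margin binary
machine per class pair — `k(k-1)/2` of them — each solved in the dual with
`quadprog` (the package's contribution is the OvO structure, decision-value
access and grid search, not the QP solver). `(C, gamma)` are chosen by
stratified cross-validated accuracy over a log2 grid; ties go to the
smallest `C`, then the smallest `gamma`. Each pairwise machine contributes
one vote by the sign of its decision value `f_ij` (the boundary `f = 0` is
counted for the first class of the pair; it occurs with probability zero);
classes are ranked by vote count with ties broken by the sum of signed
decision values in the class's favour.

**Gain-ratio decision tree** (`train_dt()`). The classical gain-ratio
recursion assumes categorical attributes; entropy features are continuous,
so the standard C4.5 adaptation is used — binary threshold splits at
midpoints of consecutive sorted unique values, scored by `GR =
Gain/SplitInfo` (base-2), stopping on purity or when the best gain ratio
falls below `epsilon` (default `1e-7`), with a majority-class leaf. No
pruning.

**ELM** (`train_elm()`). Hidden weights and biases are drawn once from a
seeded uniform(−1, 1); output weights solve `H beta = Y` (one-hot targets)
by the Moore–Penrose pseudo-inverse, the exact least-squares minimiser.
Published descriptions of ELM sometimes mention a Gaussian kernel in the
same breath as random hidden layers; both variants are provided
(`activation = "sigmoid"` random-feature form, default; `"rbf"` radial
units), and the default hidden size is `min(10 * n_features, n_train)`.

## The team-collaboration strategy

The SVM is accurate but its mistakes concentrate on samples near pairwise
boundaries or with ambiguous votes. `is_referral()` flags such samples:

* **condition (a)** — the top vote count is tied; or
* **condition (b)** — the margin predicate holds: with `u_min`/`h_max` the
  smallest/largest `|f|` among the machines involving the top-voted class
  and `v_min`/`s_max` the same for the second-ranked class,
  `u_min > v_min` and `h_max u_min > s_max v_min` and `t1 < h_max v_min`
  and `u_min s_max < t2` (defaults `t1 = 1.5`, `t2 = 3.0`).

Flagged samples are re-diagnosed by the DT and the ELM under three
principles (`team_decide()`): **I** — not referred, the SVM decides; **II**
— referred and at least one auxiliary agrees with the SVM's top class, the
top class stands (majority); **III** — both auxiliaries disagree with the
top class and at least one matches the SVM's second-ranked class, the
second class is output. A referred sample matching none of these keeps the
SVM label and is tagged `FALLBACK` — a case the principles do not cover but
which a batch classifier must resolve deterministically.

Three readings were genuinely open and are resolved as follows. The printed
form of the margin predicate runs its inequalities together; the
implemented conjunction uses all four named quantities and both thresholds
and is isolated in one internal function so alternative readings can be
swapped. "Three votes"/"two votes" is interpreted as the full-vote winner
(3 of 3 for four classes) versus the second-ranked class, whose margin set
is taken over its three machines regardless of its actual vote count —
note the pair (top, second) belongs to both sets. The predicate is
evaluated for every non-tied sample, not only full-vote winners. With four
classes a 3–3 top tie is arithmetically impossible (the pair between the
two would-be winners can only go one way); the achievable top tie is a 2–2
vote cycle, which condition (a) catches.

## Evaluation protocol

`holdout_split()` implements repeated hold-out: optional uniform
subsampling (e.g. 500 of 1000 samples, redrawn fresh each repetition),
then a stratified split at the training fraction (80 % or 75 % in the
emulated protocols). Stratification stabilises small test sets and can be
disabled. `acc_mean_std()` summarises per-repetition accuracies on the
percent scale as `Acc* = mean` and `sigma = sd` with the `N - 1`
denominator — the "mean ± sd" convention of published tables.
`run_experiment()` wires feature views (fused or single-channel) and
classifiers into arms and is a pure function of its inputs and seed.

## The synthetic world

`synth_spec_*()` generate labelled recordings whose *class information
lives in signal complexity, not amplitude*: each channel is a sinusoid at
the channel's base frequency plus a class-specific logistic-map component
(`x_{n+1} = a x_n (1 - x_n)`, `a` in \[3.5, 4\], burn-in of 1000 iterates
discarded, generated at 32 Hz and resampled to the channel rate) plus
Gaussian noise at a class noise-to-signal ratio. Amplitude is randomised
per recording and channel precisely so that trivial statistics cannot
separate the classes and the entropy features must. The four default
classes use `a` = 3.5/3.7/3.9/4.0 with NSR = 0.05/0.15/0.30/0.50 — chosen
once to give a monotone complexity ordering (3.5 is periodic; 3.57 is the
chaos onset; larger `a` has a larger Lyapunov exponent) with separations a
4-class classifier can exploit but not saturate trivially at every
channel.

Presets mirror the two corpus structures: `synth_spec_augsburg()` (4
discrete emotions × 25 recordings × 120 s; ECG-like 256 Hz + three 32 Hz
channels; 1000 segments at 12 s) and `synth_spec_deap()` (40 rating-
labelled trials × 63 s at 128 Hz; 400 segments after baseline removal).
`synth_spec_demo()` keeps the same class structure at 32 Hz/30 s for fast
end-to-end runs; the test suite uses it for pipeline-level checks purely
for runtime, and uses the full-size presets for structure counts.

What a green end-to-end test establishes: the pipeline recovers designed
complexity differences through entropy features and the committee logic is
internally consistent. What it does not establish: performance on real
physiological data — the generator has no PQRST morphology, no skin-
conductance response events, no inter-subject variability, and its class
differences are cleaner than real affective signals.

## Numerical choices

* Dual QPs get a `1e-8` ridge; multipliers are clipped to `[0, C]`; the
  intercept averages over on-margin support vectors, falling back to all
  support vectors.
* The wavelet step handles odd lengths by repeating the last sample;
  energies are exactly preserved for even lengths (orthonormal circular
  filter bank), which the tests assert via Parseval.
* Tree split ties resolve to the first (lowest-index) feature and smallest
  threshold reaching the maximal gain ratio; majority-leaf ties resolve to
  the first class level.
* Per-repetition seeds are derived as `(seed * 7919 + rep * 104729) mod
  (2^31 - 1)` so every repetition is reproducible in isolation and all
  seeds stay in integer range; model fits save and restore the caller's
  RNG state.

## Limitations

* Segment-level splitting follows the published protocol: windows of one
  recording may land in both train and test, which inflates absolute
  accuracies on real data. A group-aware split is the obvious extension
  (split by `parent_id` before windowing); the provenance columns carry
  what it needs.
* The team strategy is specified for four classes; the vote arithmetic
  generalises, but the "three votes of three" reading of the margin
  predicate is 4-class-specific.
* Absolute accuracies from the original corpora are not reproduced here —
  they require the corpora themselves; the package reproduces the method,
  the protocol arithmetic, and the published summary statistics from the
  printed per-experiment values.
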