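---
title: "Dictionary pair learning with genetic hyperparameter search: models, solvers and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dictionary pair learning with genetic hyperparameter search}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gapdpl)
```

# The problem

EEG decoding models generalize poorly to unseen subjects: spectral
features drift between individuals far more than between conditions
within one individual. A classifier meant to work subject-independently
is therefore evaluated by *leave-one-subject-out* (LOSO) cross-validation
— every subject in turn is the test set — and any hyperparameter search
that feeds on test accuracy must be read as an optimistic protocol
(see *Fitness and leakage* below).

`gapdpl` implements the full stack for one such approach: per-class
projection dictionary pairs for representation and discrimination, a
genetic algorithm over the model's four hyperparameters, band-power
feature extraction from raw trials, and synthetic generators that make
every stage testable offline.

# Projection dictionary pair learning

## Model and objective

With training columns grouped by class, `F = {F_1, ..., F_K}`,
`F_k` of size p x n_k, the model couples a synthesis block
`D_k` (p x m) and an analysis block `P_k` (m x p) per class and minimizes

$$\sum_{k=1}^{K} \|F_k - D_k A_k\|_F^2 + \tau \|P_k F_k - A_k\|_F^2
  + \lambda \|P_k \bar F_k\|_F^2, \quad \text{s.t. } \|d_i\|_2^2 \le 1,$$

where `A_k` is a relaxation variable standing in for the code `P_k F_k`
and `\bar F_k` collects all training columns outside class k. The
`\lambda` term is the discriminative part: it drives off-class samples
toward the null space of `P_k`, so that at test time the reconstruction
`D_k P_k f` is accurate only for class-k queries. The atom-norm
constraint rules out the trivial solution `P = 0, D` unbounded.

One typographic note for readers comparing against the published
formulation: the printed relaxed objective garbles its third term; the
surrounding derivation (the un-relaxed objective and both closed-form
updates) makes clear it is `\lambda \|P_k \bar F_k\|_F^2`, and that is
what this package implements. The printed analysis-update formula also
contains a stray index (`F_i` where only `F_k` is dimensionally
possible).

## Alternating solver

* **Codes** (`update_codes`): per class, a ridge-regularized least
  squares problem with the closed form
  `A_k = (D_k'D_k + \tau I)^{-1}(\tau P_k F_k + D_k'F_k)`. For
  `\tau > 0` the system is always well posed; at `\tau = 0` a
  rank-deficient `D_k` raises an error suggesting a positive `\tau`.
* **Analysis dictionary** (`update_analysis`):
  `P_k = \tau A_k F_k'(\tau F_k F_k' + \lambda \bar F_k \bar F_k' + \gamma I)^{-1}`.
  `\gamma > 0` guarantees invertibility; it is one of the four tuned
  hyperparameters, not a fixed jitter.
* **Synthesis dictionary** (`update_synthesis`): the constrained problem
  is split via an auxiliary copy `S` (ADMM with scaled dual `T`, penalty
  `\rho`): a ridge solve for `D`, the exact column-wise projection
  `s_i = \tilde d_i / \max(1, \|\tilde d_i\|_2)` for `S`, then
  `T \leftarrow T + D - S`. The feasible iterate `S` is returned.

Training (`pdpl_train`) initializes both dictionaries as random matrices
rescaled to unit Frobenius norm (standard-normal entries; the reference
description says only "random"), then alternates the three updates until
the objective changes by less than `outer_tol` (default 0.01, the
published convergence rule) or `max_outer = 50` alternations — the cap is
ours, to bound runtime on adversarial inputs.

Classification (`pdpl_classify`, `predict_batch`) computes
`r_i = \|f - D_i P_i f\|_2^2` and takes the argmin; ties break toward the
smallest class index (the reference is silent; squared vs unsquared norms
do not change the argmin).

## Numerical choices

* **ADMM stopping.** No inner criterion is published. We stop when
  *both* scaled residuals fall below `inner_tol` (default 1e-4):
  primal `\|D-S\|_F/\|D\|_F` and dual `\rho\|S_t-S_{t-1}\|_F/\|D\|_F`.
  The dual test matters: the ridge solve biases `D` toward the interior
  of the feasible set, so the primal residual can vanish at the first
  iteration while `S` is still far from the constrained optimum. With
  only a primal test the solver would silently return that biased point.
* **Penalty adaptation.** `\rho` starts at 1 and, when `rho_adapt` is on
  (default), is doubled/halved when one residual exceeds ten times the
  other, with the dual variable rescaled accordingly — standard residual
  balancing; the reference says only that `\rho` is updated "if
  appropriate".
* **Descent.** The code and analysis steps are exact minimizers of their
  sub-objectives; the ADMM step is approximate, so the objective is
  guaranteed non-increasing only up to an allowance proportional to
  `inner_tol`. The tests assert a per-alternation increase of at most
  `10 * inner_tol`.
* **Degenerate inputs.** `m` may exceed `n_k` or `p`; rank deficiency is
  absorbed by the `\tau` and `\gamma` ridges. `A_k = 0` leaves the
  synthesis objective flat and the solver returns a feasible dictionary.

# The genetic optimizer

## Encoding

`(m, \tau, \lambda, \gamma)` are packed into a 36-bit chromosome: four
9-bit Gray-coded substrings with arithmetic scaling onto
`(1, m_ub]`, `(0, 0.1]`, `[0, 0.01]`, `[0, 0.001]` (`m_ub` is 310, or 70
for small-channel-count recordings). Gray coding makes single-bit
mutations local parameter moves. Bound-exclusion flags are honoured by
shifting the 512-level quantization grid one step inward on the excluded
side, so e.g. the all-zero `\tau` substring decodes to `0.1/512`,
strictly positive. `m` is rounded half-up and floored at 1. The decoded
value is monotone in the underlying binary integer; note that the
chromosome reaching the upper bounds is the Gray encoding of binary 511
(`100000000`), not the all-ones word.

## Search loop

Per generation: evaluate (with a bit-string-keyed cache so duplicate
chromosomes never re-trigger a LOSO run), select
`round(0.9 * 20) = 18` parents by stochastic universal sampling (SUS
guarantees each individual a selection count between the floor and
ceiling of its expectation), single-point crossover at rate 0.7,
mutation at probability 0.7 *per individual* spread across the 36 loci
(per-bit 0.7/36 — a literal per-bit 0.7 would randomize the genome each
generation; a per-bit mode exists behind `mut_per_bit`), then elitist
reinsertion: parents and offspring pooled, the 20 fittest kept, ties by
insertion order. Best-ever fitness is therefore non-decreasing, which the
tests assert. The published configuration omits the crossover operator
and rate; single-point at 0.7 is the convention of the GA toolbox the
reference pipeline used, and both are configurable.

## Fitness and leakage

Fitness of a decoded parameter set is the mean LOSO accuracy over *all
subjects of the provided dataset* — exactly the published protocol, and
the package's default. That protocol lets test subjects influence
hyperparameter choice; for a leakage-free estimate, run the GA on a
training subset (`subset_subjects()`) and score the held-out subjects
once. A fold whose training fails scores 0 with a warning, so one
pathological parameter set cannot abort a search.

# Feature extraction

Raw trials (channels x samples at sampling rate `fs`) are band-pass
filtered per band and channel with an order-8 zero-phase Butterworth
design, reduced to RMS over non-overlapping 1 s windows, then logged
(natural log by default; the base is configurable because only "the
logarithm" is specified). Rows are ordered band-major and recorded in
`feature_index`, so written datasets are bit-reproducible.

Implementation notes:

* No IIR design routine ships with the pre-installed R stack, so the
  filter is designed from the analog prototype (low-pass-to-band-pass
  transform, bilinear transform with pre-warping) and factored into
  second-order sections for stability at order 8; "order 8" is the
  prototype order of the band-pass design. The magnitude response was
  cross-checked against an independent scientific-computing
  implementation during development; the shipped tests verify half-power
  edges, pass-band flatness, stop-band attenuation and the zero-phase
  property numerically.
* Zero-phase application: forward and reversed passes over an
  odd-reflection-padded signal with steady-state initial conditions per
  section; the effective response is the squared magnitude, and the lag-0
  cross-correlation peak of a filtered in-band sine confirms zero group
  delay.
* **Nyquist clipping.** A band's upper edge is clipped to 0.99 x fs/2; a
  band whose lower edge survives no pass-band (e.g. 70-100 Hz at
  fs = 128) is dropped with a warning, and extraction errors only when no
  band survives. The reference is silent on how its lowest-rate device
  was handled; this rule is our choice and is logged.
* Zero-power windows are floored at RMS 1e-12 before the log, so silent
  synthetic channels yield finite features. Exact log-homogeneity
  (scaling a trial by `\alpha` shifts every feature by `log \alpha`)
  holds for signals with content in every band; stop-band outputs of a
  pure sinusoid sit at the double-precision noise floor where no such
  identity can survive floating point — the tests therefore verify
  homogeneity on broadband trials.

# Synthetic worlds

`make_subspace_dataset` emulates the structure the classifier assumes:
each class spans an r-dimensional orthonormal basis (rejection-sampled
until every pair of subspaces is at least `class_separation` apart in
smallest principal angle), each subject adds one fixed random offset of
chosen norm (the minimal model of between-subject variability), and
isotropic Gaussian noise perturbs every sample. It does **not** emulate
band-limited spectra, volume conduction, artifacts, non-stationarity or
label noise — a green test establishes correctness of the algorithms on
their own model assumptions, not performance on real EEG.

Defaults (K = 3, p = 60, r = 8, 10 subjects, 40 samples/class/subject,
noise 0.05) are the configuration under which subspace recovery is
expected to be essentially perfect with `m = r`; they double as the
recovery acceptance setting. `make_oscillatory_trials` gives raw trials
whose classes differ by which frequency band carries an elevated
sinusoid, exercising the extractor end to end.

The pinned adversarial fixture (`make_adversarial_default_dataset`) is a
deliberately hostile world for the conventional hand-set parameters
(m = 32, tau = 0.03, lambda = 0.003, gamma = 1e-4): true class subspaces
are 2-dimensional in only 16 ambient dimensions with overlapping subject
offsets and noise 0.45, so a 32-atom dictionary — twice the ambient
dimension — reconstructs everything and discriminates poorly, while
smaller decodable dictionary sizes do better. Calibration (performed
once, then pinned at seed 2023): the defaults score 0.597 mean LOSO
accuracy, the best of 16 random decodable parameter sets 0.685. The
GA-beats-defaults test runs the search at a reduced budget (population
10, 10 generations, solver capped at 12 alternations / 30 ADMM
iterations per fitness call) to stay inside its time box; the reduced
solver budget applies identically to the defaults and to every GA
candidate, so the comparison is fair.

# Evaluation conventions

* Subjects are ordered lexicographically by id everywhere, so fold
  numbering is machine-independent.
* The 95% confidence interval over per-subject accuracies is the
  Student-t interval `mean ± t_{0.975, n-1} sd/\sqrt n`, clipped to
  `[0, 1]`; the reference never states its construction, and published
  intervals are not recomputable without per-subject raw values. Both sd
  and the standard error of the mean are reported, explicitly labelled.
* `run_loso(...)$mean` and `evaluate_fitness(...)` share one code path
  and agree bit-for-bit; all generators and the GA are pure functions of
  their seeds.

# Known limitations

* The default fitness inherits the published protocol's optimism (see
  *Fitness and leakage*).
* ADMM returns the feasible iterate `S`, not a certified global optimum
  of the constrained subproblem (the subproblem is convex, so with tight
  tolerances the gap is negligible — the tests bound it against
  closed-form and brute-force oracles).
* Differential-entropy features consumed by some databases are accepted
  as precomputed inputs only; their computation is out of scope.
* Runtime scales with `K * max_outer * max_inner` matrix solves; the
  pure-R implementation is adequate for feature-space sizes (p of order
  a few hundred) but is not tuned for raw-signal-dimension dictionaries.
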