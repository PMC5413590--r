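---
title: "Fuzzy-refined empirical wavelet features: models, choices, limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fuzzy-refined empirical wavelet features: models, choices, limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette is the package's own account of its methods: the models and
their assumptions, the tunable parameters, what the synthetic generators do
and do not emulate, the numerical choices, and the design decisions taken
where the design was genuinely open. It states no empirical result that the
test suite does not itself compute.

## 1. The empirical wavelet transform

A real signal's spectrum on the normalized angular frequency axis
`[0, pi]` is split into `N` segments at boundaries
`omega_0 = 0 < omega_1 < ... < omega_N = pi`. Around each internal boundary
sits a transition zone of half-width `tau_n`. The scaling (low-pass) filter
is 1 for `|omega| <= omega_1 - tau_1`, rolls off as
`cos(pi/2 * beta((|omega| - omega_1 + tau_1) / (2 tau_1)))` through the
transition, and is 0 beyond; the band `n` wavelet rises through its lower
transition as the matching `sin(.)`, is 1 on the passband, and falls through
its upper transition as `cos(.)`. Because
`beta(x) + beta(1 - x) = 1`, adjacent `sin^2`/`cos^2` halves sum to one and
the filter bank is a tight frame, so decomposition (inverse FFT of spectrum
times filter) and reconstruction (each coefficient series filtered once
more and summed) round-trip exactly to numerical precision.

Choices the underlying formulation leaves open, and what this package does:

* **Transition polynomial** `beta`: the standard Meyer polynomial
  `x^4 (35 - 84 x + 70 x^2 - 20 x^3)` — the canonical choice satisfying
  `beta(0) = 0`, `beta(1) = 1`, `beta(x) + beta(1-x) = 1`, which the
  tight-frame identity needs.
* **Transition widths**: `tau_n = gamma * omega_n` with `gamma = 0.1` by
  default, clipped just below `min(adjacent gaps)/2` so that transition
  zones never overlap and the case ranges partition the axis.
* **Boundary detection**: internal boundaries at midpoints between the `N`
  largest strict local maxima of the magnitude spectrum, ties towards lower
  frequency. A spectrum with too few maxima (e.g. a flat or near-silent
  window) falls back to equal-width segmentation with a logged note rather
  than an error, so batch encoding never aborts on a quiet window.
* **Grid convention**: filters are even in `omega` and evaluated on the
  folded FFT grid, so all components of a real signal are real up to
  round-off (guarded at `1e-9` of the signal norm).

## 2. Fuzzy c-means and the band refinement

FCM minimizes `sum_j sum_i u_ij^m d^2(x_j, v_i)` under column-stochastic
memberships, alternating the closed-form membership update
(`u_ij` proportional to `d_ij^{-2/(m-1)}`) and `u^m`-weighted centroid
means. Package choices: fuzzifier `m = 2` (the value used for the EEG
pipeline), convergence when the largest membership change falls below
`1e-6` or after 300 iterations, seeded initialization by drawing `c`
distinct data points, and exact handling of the zero-distance singularity
(membership 1 split equally among coincident centroids). The objective
trace is recorded and is non-increasing by construction of the alternating
minimization.

**What the refinement clusters — a deviation worth explaining.** The
refinement step must turn `c` possibly-overlapping wavelet supports into
exactly `c` non-overlapping frequency bands. An obvious realization —
cluster each positive-frequency bin on standardized (frequency,
log-magnitude) descriptors and hard-assign by maximum membership — was
implemented first and fails in practice: per-bin log-magnitudes fluctuate
by several dB (periodogram noise), so hard assignment flips individual
bins and the "bands" come out as non-contiguous scatter; and when the
spectrum has pronounced bumps over a floor, the magnitude coordinate
dominates and all bumps collapse into a single cluster. The package
therefore clusters the **spectral mass along the frequency axis**:
power-weighted FCM on the bin frequencies, with each bin weighted by its
spectral power (`fcm_fit(..., weights = power)`). The membership update is
unchanged; centroids become power-weighted means, i.e. they settle where
the energy is. Hard assignment in one dimension is a Voronoi partition, so
bands are always contiguous, bands are relabelled 1..c by ascending
centroid frequency, and for symmetric, well-separated spectral peaks the
band edges sit at midpoints between peaks — which is where the EWT
boundary detector also places its boundaries, so the two agree to within a
bin in that regime (tested). Band components are inverse transforms of the
spectrum masked to each band's bins with conjugate-symmetric completion;
the DC bin goes to band 1; the bands therefore partition the axis and sum
to the signal exactly.

Per window and channel the clustering is restarted `restarts = 5` times
(seeded) and the lowest-objective fit kept, damping initialization
variance. A zero-power window is clustered with uniform weights, giving
equal-width bands.

## 3. The eight descriptors

Each band component is summarized by: RMS; LZ76 complexity of the
median-binarized series (Kaspar-Schuster exhaustive-history phrase count,
normalized by `n / log2(n)`); Shannon entropy (base 2) of a 16-bin
amplitude histogram spanning the band's `[min, max]`, empty bins skipped;
the power-spectrum centroid (central frequency, Hz) and the frequency of
the largest power-spectrum bin (maximum frequency, Hz), both computed on
the positive-frequency half including DC; unbiased sample variance; and
the uncorrected moment ratios skewness `m3 / m2^{3/2}` and kurtosis
`m4 / m2^2` (no excess correction). A constant band returns variance 0
and, by convention, skewness, kurtosis and entropy 0 with a logged note —
the analytic values are undefined there. The spectral descriptors are
computed on the band's power spectrum; the remaining six on the
time-domain component.

Rows are laid out channel-major: channel 1 band 1 parameters 1-8, channel
1 band 2, ..., giving `channels x bands x 8` columns (144 at the 6-channel,
3-band default; 24 per channel).

## 4. Feature selection

Three multivariate filter criteria over column subsets:

* **Bhattacharyya distance** (Chernoff at `beta = 1/2`): implemented with
  determinants throughout the log term (the formulation's printed log-term
  numerator lacks determinant bars; the standard formula is used). When the
  pooled covariance is numerically singular (condition number above 1e12)
  a ridge (`1e-6 *` mean diagonal by default) is added to each class
  covariance and logged — a proper determinant is required, so a
  pseudo-inverse is not an option. Two classes only, as in the pairwise
  task design.
* **Scatter-matrix trace ratio** `tr(S_b)/tr(S_w)` with prior-weighted
  maximum-likelihood class expectations. The ratio is invariant under
  orthogonal transformations of feature space (tested to 1e-9); it is
  *not* invariant under general invertible linear maps, a known limitation
  of the trace-ratio form.
* **Linear-regression criterion** `1 - SSE/SSTO` with intercept, classes
  coded 0/1 in sorted label order; bounded in `[0, 1]`; rank-deficient
  designs fitted by pivoted QR and logged; constant targets rejected.

Search: greedy forward inclusion (features "included one by one"), ties
broken towards the lower column index, criterion value recorded after each
inclusion; candidates on which the criterion fails are skipped, and if all
remaining candidates fail the partial ranking is returned with a logged
reason. Default `k = 25`.

## 5. Classification harness

Stratified k-fold cross-validation (default 10) with the regularization
constant `C` and Gaussian kernel width grid-searched **inside each
training fold** on an inner CV (default 3 folds) — leak-free, possibly
stricter than a global search. Features are standardized with
training-fold statistics. The per-combination accuracy is the maximum of
the accuracy curve over ranked-prefix sizes `k` (the aggregation of the
inclusion curve is otherwise unspecified). Default grids are logarithmic:
`C` in `10^(-2..3)`, kernel width in `10^(-4..1)`.

The classifier itself is a **least-squares SVM** (Suykens form): an RBF
ridge system `[[0, 1'], [1, K + I/C]] [b; a] = [0; y]` solved directly. No
SVM library exists in the deployment environment; the LS-SVM keeps the
Gaussian-kernel / `C` / width interface of an SVC, is deterministic, and
has no tuning heuristics. This is an infrastructure substitution, not a
claim that LS-SVM and SMO-trained SVC coincide.

Ranking of method combinations: per task pair the baseline family's best
accuracy over its selection variants (including "WFS", no selection) is
the reference; gains are `100 (a - a_max)/a_max`, averaged over task
pairs, ranked descending with equal gains sharing a rank. The Friedman
test ranks combinations within each (subject x task-pair) block (best =
rank 1, average ties), and reports the tie-corrected chi-square statistic,
its p-value against the chi-square reference distribution, and a
reject/retain decision at 0.05; constant blocks yield "retain" with a
diagnostic rather than an undefined statistic.

## 6. The synthetic world

`gen_amfm` generates sums of AM-FM cosines
`amp (1 + 0.5 sin(2 pi am t)) cos(2 pi (f t + chirp t^2 / 2) + phase)`
plus Gaussian noise — enough to produce the overlapping-chirp spectra that
defeat plain EWT segmentation. `gen_trials` emulates the recording
geometry of the motivating mental-task dataset: 6 channels, 250 Hz, 10 s
trials (2500 samples), two balanced classes. Each channel carries
unit-variance 1/f-shaped background noise; planted channels add a
band-limited component whose amplitude is `0.5` (relative to the unit
background) for class 1 and `0.5 sqrt(ratio)` for class 2, so the planted
*power* differs by `ratio`. The 0.5 base amplitude puts the planted band
roughly at parity with the background power inside the band — a visible
but not dominant rhythm, which is what a strong task-modulated EEG band
looks like; it was chosen once and not revisited.

What the generator does **not** emulate: volume-conduction correlation
between channels, artifacts (blinks, EMG), non-stationarity within a
trial, or — importantly — spectral content that overlaps in time and
frequency across components the way multi-channel EEG chirps do. A green
end-to-end test therefore establishes that the pipeline recovers planted
band-power structure, not that FEWT beats EWT on real EEG.

That caveat is live: in the end-to-end acceptance benchmark (planted power
ratio 4 on 2 of 6 channels, 50 trials/class, 3 seeds) LR selection beats
the no-selection condition on FEWT features, but raw-EWT features come out
marginally *above* FEWT features at matched selection conditions. The
planted effects are stationary band-power differences in disjoint bands;
smooth wavelet filters estimate such band power slightly better than
FEWT's hard rectangular spectral masks, whose sharp edges add descriptor
variance, and the overlapping-chirp regime the refinement was built for is
not part of this generator. The corresponding assertion is left failing by
design rather than weakened, and the comparison numbers are computed by
the test itself.

## 7. Compute scaling in the acceptance benchmark

The stated benchmark world (trial count, channel count, effect size,
trial geometry) is kept; harness knobs are scaled for a 1-CPU budget:
1 s windows instead of 0.5 s, 2 FCM restarts instead of 5, 5 outer folds,
a reduced `C`/width grid, and the selection condition evaluated at
`k = 25` only instead of the full inclusion curve. The directional
conclusions were re-checked at the paper-faithful 0.5 s / 5-restart
setting and are unchanged.

## 8. Known limitations

* Boundary detection is the simple largest-peaks rule; scale-space or
  histogram-based EWT segmentation variants are out of scope.
* The Bhattacharyya criterion degrades (ridge regularization engages) once
  the selected subset grows toward the per-class sample count.
* LS-SVM solves a dense linear system per fit: fine to a few thousand
  windows, not designed beyond that.
* The CLI covers the documented subcommands only; the original
  distribution format of the motivating EEG dataset is not parsed.
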