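---
title: "Methods: brain-state clustering and pupil decoding from rs-fMRI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: brain-state clustering and pupil decoding from rs-fMRI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The model

`pupilstate` analyzes paired recordings: per trial, a masked voxel x time
fMRI matrix `X` (TR-sampled, default 1 s, 925 frames per ~15-min trial) and a
pupil diameter trace `p(t)` at the same rate. The working model is that a
small number of latent spatial components `C_k(v)` with slow time courses
`s_k(t)` drive both modalities:

```
x_v(t) = sum_k C_k(v) s_k(t) + eps_v(t)
p(t)   = sum_k w_k   s_k(t)  + eta(t)
```

A *brain state* is a regime with its own coupling vector `w` (and, in the
synthetic world, its own ultra-slow pupil oscillation frequency). Two
complementary analyses follow:

- **State identification.** The voxel-wise correlation map of a trial is a
  fingerprint of its coupling pattern; clustering per-trial maps recovers the
  states.
- **Decoding.** A decoder from PCA component time courses to `p(t)`
  re-weights fMRI components by their pupil information; back-projecting the
  weights yields a voxel-wise pupil-information map that is sensitive to
  superimposed sources which plain correlation mixes together.

# Stage-by-stage choices

## Pupil signal conditioning

- Landmark-to-diameter: the mean of two chord lengths between tracked edge
  points, divided by eye size, so values land in (0, 1]. Invariant to rigid
  motion of the eye in the frame.
- Binning: non-overlapping windows of `round(tr/dt)` samples, trailing
  partial window dropped. Deterministic output length; a 29.97 fps camera
  track therefore carries a ~0.1% clock drift relative to true seconds that
  the rule ignores (the synthetic landmark generator emits an integer number
  of frames per bin so round trips are exact).
- HRF kernels: `f(t) = t^(a-1)e^(-t)/Γ(a) - 0.3 t^11 e^(-t)/Γ(12)`, sampled
  at the TR, unit peak (amplitude is irrelevant because every trace is
  re-standardized). `a` must exceed 1: the positive lobe's nominal peak
  `t = a-1` sits at the boundary at `a = 1`, so "peak at 0 s" is reachable
  only as a limit; `hrf_peak_time()` / `solve_hrf_a()` expose the numeric
  map between `a` and peak time, which covers (0, 5] s for `a` in (1, ~6.4].
- Welch PSD: 512-point DFT, Hann window, 50% overlap, constant detrend per
  segment, one-sided density scaling (total power of a unit-variance trace
  integrates to ~1). Series shorter than 512 samples become one zero-padded
  segment. Frequency resolution is 1/512 Hz ~ 0.002 Hz, enough to separate
  the 0.011 / 0.018 Hz state signatures by several bins.

## Correlation maps and surrogates

Per-voxel Pearson correlation with the pupil trace; constant voxels score 0
(not dropped) so map length is stable. The all-trial map standardizes each
trial's signals before concatenation — whether the original analysis did so
is not stated; on synthetic cohorts the two variants differ negligibly
because per-trial variances are already near 1.

Surrogate maps keep a map's exact value multiset and its spatial
autocorrelation while randomizing the pattern: values are permuted, blended
with a k-nearest-neighbor smoothed copy, and rank-remapped to the original
multiset. The blend weight and neighborhood size are fitted once per map to
the empirical variogram (Matheron estimator, 25 equal-count distance bins,
<= 50k seeded voxel pairs); because permutations are exchangeable the fit
transfers to every surrogate. Acceptance band: mean relative variogram
deviation <= 20%, spatial correlation with the original < 0.8.

## Clustering

- Embedding: UMAP (via uwot) with `n_neighbors = 7`, `min_dist = 0`,
  `D = min(72, n_trials - 2)`, spectral initialization where the
  implementation permits (PCA initialization above `D > n/2`, random beyond
  the input rank). A deterministic PCA embedding is selectable
  (`method = "pca"`) for bitwise-reproducible tests; the stochastic method is
  the protocol default and its run-to-run variability is aggregated by the
  consensus step.
- GMM: full covariance, EM with k-means initialization, covariance
  regularization 1e-6, tolerance 1e-3 on mean log-likelihood, 100 iterations
  max, one initialization per run. Degenerate covariances trigger a bounded
  re-seeded retry, then an error.
- Model selection: mean silhouette (Euclidean, on embedding coordinates)
  over repeated embed+cluster runs for k in 3..7.
- Consensus: runs aligned to the first by exhaustive optimal label matching
  (k <= 8), per-trial majority vote, ties broken toward the lowest aligned
  label; per-trial stability = fraction of agreeing runs.
- Half-split battery: random halves re-clustered from scratch and compared
  to the full-data consensus by aligned match ratio; under label
  randomization the expected ratio is the largest cluster's share, which is
  the null baseline the tests check against.

A caution the synthetic experiments surfaced: with strongly separated,
internally exchangeable clusters, UMAP at `min_dist = 0` can tear a large
cluster into tight sub-clumps, and the silhouette criterion then sometimes
prefers k one above the planted count. Real cohorts, whose within-state
trials are heterogeneous, sit in a regime where the criterion is better
behaved; the acceptance battery therefore requires the planted k and
consensus ARI >= 0.9 in 8 of 10 seeded cohorts rather than in every one.

## Decoding

- PCA on time-concatenated training voxel matrices only (default n = 300
  components, capped by the data rank); component signs fixed so each map's
  max-|loading| voxel is positive. Held-out trials are projected on the
  training mean/basis and each component time course is variance-normalized
  per trial (rows carrying only numerical residue are flagged and zeroed).
- Template baseline: spatial correlation of the training concatenated map
  with each volume; predictions bounded to [-1, 1], hence all methods are
  compared by per-trial Pearson r.
- Linear variants: ridge (default, alpha = 19861, the published winning
  hyperparameter) solved in closed form from the normal equations on
  centered data; OLS via QR with a singularity error advising ridge; lasso /
  elastic-net via glmnet with `lambda = alpha / n_samples`.
- GRU: standard reset/update/new gates, `y(t) = w_out . h(t)`, `h(0) = 0`,
  correlation loss `1 - r` with an eps = 1e-8 variance guard, Adam with L2
  weight decay, gradients clipped by global norm (reading of "max gradient
  1"), batch size 12, 7 epochs — the published configuration. Trials share a
  common length in this package, so no padding/masking path exists.
- Cross-validation: fourfold over training trials; the PCA basis *and* the
  template map are rebuilt per fold (the stricter, leak-free reading; the
  alternative — one template from all training trials — is available by
  fitting on the full set explicitly). A disjoint test set is scored by a
  final model fitted on all training trials.
- Shift sweep: the pupil trace is advanced/delayed by whole frames with the
  overhang trimmed, full cross-validation per shift.

## Prediction maps and significance

- Back-projection: `m(v) = (1/K) sum_k w_k C_k(v)`. The 1/K scale makes
  "sum then mean" concrete; every downstream statement (significance,
  cluster discrimination, GRU/linear agreement) is about the pattern, not
  the amplitude.
- GRU maps: per trial, the gradient of `sum_t y(t)` w.r.t. the input
  sequence, averaged over the input time axis and over trials, replaces `w`.
  For a GRU that implements a static linear readout this equals the linear
  weights exactly, which pins down the reduction the original description
  leaves open (any other reduction differs only by a global scale).
- Randomization test: whole pupil traces are reassigned across trials
  (pairing shuffle — not within-trial rotation), the decoder is refitted and
  the map rebuilt per permutation (desk default 1000; 10000 by config).
  Two-sided empirical p with the (b+1)/(n+1) correction; quantile flags at
  alpha/2, 1 - alpha/2; Benjamini–Hochberg FDR at q = alpha (0.01). Note an
  interaction worth knowing: with n_perm = 1000 the smallest attainable p is
  2/1001, so BH at q = 0.01 over thousands of voxels can only select voxels
  at full-scale permutation counts — exactly the conservative behavior the
  type-I acceptance check verifies.
- Explained variance per component: all *other* component rows are
  time-shuffled (fresh per fold), ridge refitted under fourfold CV, and the
  out-of-fold explained variance of the pupil recorded; values can be
  negative for uninformative components. Shuffling per fold (rather than
  once) was an open choice; per fold is the higher-variance but unbiased
  reading, and the repeat count is exposed through the seed.

## Pipeline and filtering

The 0.002–0.15 Hz band-pass is applied per voxel as an FFT-domain filter
with the squared magnitude response of a 4th-order Butterworth band-pass,
i.e. exactly zero phase. A time-domain second-order-sections filter was the
original design intent, but no signal-processing package is available in the
target environment and at a 0.002 Hz cutoff the FFT route is also the
numerically safer one. Only the fMRI is filtered; the pupil trace is left
unfiltered, matching the acquisition description (the asymmetry is
deliberate).

# The synthetic world

The generator emulates: ~15-min trials at TR = 1 s (925 frames), a masked
3-D grid (desk default 24 x 24 x 12 ellipsoid, ~3.6k voxels; tests use
16 x 16 x 8), K = 6 latent components (smoothed random fields with a compact
blob, unit spatial variance, pairwise |spatial correlation| <= 0.3), four
states with trial counts 8/30/24/12 mirroring the real cohort's cluster
sizes, state oscillation peaks at 0.018 / 0.008 / 0.006 / 0.011 Hz, latent
time courses = white noise low-passed below 0.1 Hz (zero-phase,
variance-normalized) plus a unit-amplitude sinusoid on coupled components,
and independent Gaussian noise.

Free parameters the source does not constrain, chosen once: `noise_sd_fmri
= 1.0` (voxel SNR near 1 in component-loaded voxels, typical of rs-fMRI) and
`noise_sd_pupil = 0.3` (pupillometry is much cleaner than BOLD). Per-trial
counter-based RNG substreams make cohorts bit-reproducible and extensible
without perturbing earlier trials.

What a green test does *not* establish: the generator has no spatially
correlated noise (available behind a flag is out of scope here), no motion,
no vascular confounds, no eye blinks, and within-state trials are
exchangeable — so recovery results quantify the pipeline's correctness, not
its performance on real recordings.

# Numerical notes and limitations

- All label-alignment operations are exhaustive over permutations (k <= 8)
  and therefore optimal and deterministic; ties in consensus voting go to
  the lowest aligned label index.
- Ridge at a fixed alpha is not invariant to duplicating trials (the data
  term doubles, the penalty does not); maps keep their pattern under
  duplication but not their scale.
- In the exact noise-free limit the correlation map equals the *sign*
  pattern of a single component (every voxel correlates at +/-1), so
  amplitude-pattern recovery is asserted in the noise-dominated linear
  regime instead.
- GRU training in base R is practical at desk scale (hidden size <= 300,
  tens of trials); the published hidden size 300 with 300 components and 64
  trials trains in minutes, and tests use smaller capacities since the
  directional claims do not depend on capacity.
- The NIfTI interchange format is not implemented (no NIfTI-capable package
  in the target environment); CSV/JSON writers cover the documented
  voxel <-> flat-index mapping (x fastest, then y, then z, 1-based).
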