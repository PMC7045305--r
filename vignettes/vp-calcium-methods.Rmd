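---
title: "Methods: single-cell calcium imaging and spatial analyses of ventral pallidum subtypes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: single-cell calcium imaging and spatial analyses of ventral pallidum subtypes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vpcalcium)
```

# Scope and design

`vpcalcium` re-implements, as tested and reusable code, the analysis chain
used to study ventral pallidum (VP) neuron subtypes — glutamatergic
(VP~Glu~), GABAergic (VP~GABA~) and enkephalin-expressing (VP~Penk~) — with
one-photon miniscope calcium imaging during cocaine self-administration,
extinction and cue-induced reinstatement, together with the spatial and
count analyses applied to histology (RNAscope densities, k-NN clustering,
rabies input fractions). Because no recording dataset is publicly deposited,
every stage is exercised on synthetic data with exported ground truth; the
generators are first-class, tested code, and their defaults define the
study conditions under which the package validates itself.

The pipeline order is fixed and enforced: spatial downsampling (factor 4) →
rigid-body motion correction → ΔF/F normalization → PCA/ICA source
extraction → component QC → event detection / peri-event analysis. Stages
refuse inputs that are already ΔF/F-normalized, so the order cannot be
permuted by configuration.

# File formats

No HDF5 interface is available to this package, so containers use plain
formats: traces, event trains, behavior logs, centroid and label tables are
CSV (comma-separated, header row, UTF-8, '.' decimal) with a small JSON
metadata sidecar (`<path>.meta.json`) holding the sampling rate, session
type and duration; movies use R native serialization, which round-trips the
frame array bit-exactly. Statistics are emitted as JSON.

Time is measured in seconds from session start, 0-based; sample *i* (0-based)
covers time *i*/`frame_rate_hz` (left-edge convention), which gives an
unambiguous mapping between sample indices and timestamps.

# Reproducibility

Every stochastic operation takes an explicit integer seed. One global seed
is split into per-stage substreams by `split_seed(seed, stage, index)`: the
stage name is hashed with a base-31 polynomial rolling hash modulo
2^31 − 1 and combined with the seed through Lehmer-style multipliers.
Identical seed and configuration give bit-identical outputs everywhere.

# Synthetic data: what it emulates, and what it does not

`gen_traces()` draws homogeneous Poisson event times per cell, adds a
double-exponential GCaMP6f-like transient per event (rise τ 0.2 s, decay τ
0.6 s, unit-normalized peak) with lognormal amplitudes (mean 0.25 ΔF/F,
sdlog 0.25 — positive, right-skewed, as in real recordings), and white
Gaussian baseline noise scaled so that peak amplitude / noise SD equals the
requested `snr`. The kernel shape and amplitude model are this package's
own choices: published analyses report rates and amplitudes but not
transient shape parameters, and no per-session cell counts or per-type
amplitudes are printed; defaults are therefore stated, documented values,
not fitted ones.

`gen_movie()` renders each cell as a 2-D Gaussian footprint (SD 2 px) with a
static resting-fluorescence component (`static_gain`, default 0.3 of
background) plus a dynamic component modulated by the cell's trace, over a
constant background with white pixel noise, optionally drifting rigidly
along a known zero-mean sinusoidal schedule. The static component matters:
it supplies the persistent spatial structure registration locks onto.

`gen_behavior()` draws nose pokes from a renewal process (exponential
inter-poke intervals with a 1-s refractory floor — the simplest process
with a plausible burstiness constraint) at per-session intensities:
self-administration 1.0, first extinction day 1.5, late extinction 0.4 and
cued reinstatement 1.2 active pokes/min (inactive 0.2/min), sessions of
7200 s with analyses restricted to the first 3600 s. Under FR1 with a 20-s
cue timeout, every active poke outside the timeout triggers the tone/light
cue (plus infusion during self-administration) and restarts the timeout.
The late-extinction intensity is set well below 40% of day-1 extinction so
simulated subjects satisfy the extinction criterion (responding < 40% of
Ext1, strict inequality).

`gen_point_pattern()` produces either complete spatial randomness (CSR,
the clustering test's null) or a Thomas-type parent–offspring process with
exactly `n` points; `gen_input_labels()` draws i.i.d. Bernoulli D1/D2
labels; `gen_marker_field()` draws Vglut2/Vgat/Penk markers at the
published marginals (23/73/16%) with Penk nested in Vgat (95%
co-expression) and Vglut2 essentially Vgat-negative (3%).

What the generators deliberately do **not** emulate: neuropil and shared
background fluctuations, correlated network activity, photobleaching,
non-rigid tissue deformation, biophysical calcium dynamics, or
within-session behavioral nonstationarity. Passing tests therefore
demonstrate correctness of the algorithms under clean, known-truth
conditions — not end-to-end performance on real miniscope data.

# Preprocessing and source extraction

Downsampling is exact block-mean pooling; non-divisible frames are cropped
to the largest divisible region (top-left anchored) with a message.

Motion correction estimates per-frame translations from the peak of the FFT
cross-correlogram against the temporal mean image, with parabolic subpixel
refinement and a `max_shift` search bound (default 10 px). Because a
drifting movie smears its own mean, a second pass re-registers against the
mean of the corrected movie; on planted ±3 px drift this recovers shifts to
better than 0.1 px (the tests require 0.5 px). Correction is applied by
bilinear resampling, out-of-frame pixels filled with the frame median.

ΔF/F uses `(F − F0)/F0` with `F0` a running 20th percentile over a 30-s
window (evaluated on a 1-s grid and linearly interpolated, which makes the
estimator cheap without changing it materially), or a global temporal mean.
Non-positive baselines are an error naming the offending cell or pixel.

Source extraction follows the PCA/ICA approach standard for one-photon
data: PCA reduction to `n_components` (recommended 1.5× the expected cell
count — over-extract, then QC), then ICA on the concatenation of temporal
and spatial principal components weighted by `ica_weight` (default 0.1,
mostly temporal; the upstream software's setting is not recoverable, so the
weight is documented and configurable). The ICA rotation is computed by a
symmetric fixed-point iteration with the logcosh contrast and applied to
both domains; component signs are fixed so temporal traces have
non-negative skewness (calcium transients are positive-going), spatial maps
are rectified, and centroids are computed with squared-map intensity
weighting. Because manual component curation cannot be reproduced, QC is an
automated surrogate: accept components with positively skewed traces,
footprint area (pixels ≥ half max) within bounds, and footprint energy
concentrated near the centroid. Equivalence with the original workflow is
claimed only at the level of planted-ground-truth recovery (≥ 90% of
planted cells matched at spatial correlation > 0.8, trace correlation
> 0.7).

# Event detection

The published workflow names a peak-finder without parameters, so the
definition here is the package's own, calibrated against its stated design
goal (a null false-event rate below 0.1/min on pure noise):

1. smooth the ΔF/F trace with a 5-sample centered moving average
   (0.33 s at 15 Hz);
2. find local maxima; an event requires prominence (peak minus preceding
   trough) ≥ 6 × MAD of the smoothed trace, with trough-to-peak rise time
   ≤ 2 s;
3. merge events with onsets closer than 0.35 s (about one transient rise
   time), keeping the larger peak;
4. report amplitude as the prominence — peak minus preceding trough (the
   published "amplitude (a.u.)" does not say whether it is
   baseline-subtracted; subtracting the trough is the documented choice
   here) — and time as the transient onset (the last sample below trough +
   20% of prominence), which is what peri-event latencies need.

Measured on the generator's regime at snr 8: null false-event rate
0.022/min, precision 0.997, recall 0.978, mean amplitude 0.249 against a
planted 0.25. A prominence threshold of 5 MAD on the raw trace — a natural
first guess — gives a ~0.5/min null rate and was rejected during
calibration; similarly a 1-s merge radius undercounts genuinely adjacent
Poisson events.

One limitation is intrinsic: at 15 Hz with a 0.6-s decay kernel,
transients closer than ~0.3–0.4 s are not separable by any peak finder, so
detected rates undercount by roughly `rate × 0.4 s` (≈1% at 1.58
events/min, ≈3% at 2.88 events/min). Spike-train deconvolution would be
required to go further and is out of scope. The acceptance suite reflects
this honestly: rate recovery at the grand-average regime (1.58 events/min)
passes within 2 SEM of a 300-cell cohort, while the same check at the
2.88 events/min regime fails its 2-SEM tolerance by design of the detector
class, with the bias fully explained by unresolvable overlaps.

Rates are computed over the first 60 min of each session only ("spikes/min"
and "events/min" are treated as the same quantity); cumulative event curves
honor longer recordings only when full-length data exist.

# Peri-event analysis

Trials are active nose pokes: during extinction, pokes at least 20 s from
both neighbors (preventing cross-contamination between responses); during
self-administration or reinstatement, cued pokes only (pokes outside the
20-s timeout, reconstructed by a forward scan of the poke sequence); always
within the first 60 min. For each cell and trial the −10 to +20 s window is
extracted, smoothed with a running 10-point moving average, and z-scored to
the mean and SD of that same windowed segment. Design choices where the
published description is ambiguous:

- the smoothing window is centered, shrinking at the window edges —
  centered filters avoid phase lag in peri-event latencies;
- smoothing precedes z-scoring (following the order in which the steps are
  described); the z-score uses the within-window mean and SD, read from
  "normalized to the average activity within that window";
- the pre/post comparison windows are half-open, right-closed — (−2, 0] and
  (0, 2] — so the poke instant belongs to exactly one interval;
- the baseline SD for responder classification is computed on the
  trial-averaged trace (the rule is stated per cell); a per-trial variant
  would be stricter but is not the default reading.

Population magnitude takes absolute values of the trial-averaged z trace so
increases and decreases both register. Responder classification uses the
signed average: increased if the post mean exceeds baseline mean + 2 ×
baseline SD, decreased if below −2 SD, else unchanged; zero-variance
baselines are flagged unchanged. Because smoothing and averaging correlate
the bins, the rule's null rate is far from the nominal two-sided Gaussian
4.6%; the suite therefore validates the implementation against a
brute-force restatement of the rule and measures its null rate by Monte
Carlo rather than asserting a theoretical value. Classification is
invariant to affine rescaling of the raw traces (z-scoring removes scale),
and heatmap ordering (increased, unchanged, decreased; magnitude
descending within class; ties broken by cell id) is invariant to input row
permutation.

# Spatial clustering and counting

The clustering statistic is the mean over cells of the Euclidean distance
to the k-th nearest neighbor (k = 10). "k-nearest neighbor value" is read
as one distance per cell — the k-th — rather than the mean of the k
nearest; the alternative is available via `value = "mean_k"`. The null is
the same statistic on 1000 redraws of equally many uniform points in the
pattern's field bounds (or the observed bounding box — the minimal
assumption-free region — when no bounds are known). Distances are in
pixels; no physical calibration is applied since none is given.

The test's primary p value is the one-sided permutation p,
`(1 + #{null ≤ observed})/(B + 1)`; a pattern is called clustered when the
observed statistic falls below the null mean with p < α. A one-sample t of
the null sample against the observed value is also reported (`t`, `df`,
`p_t`) because that is how the comparison is commonly summarized, but it is
deliberately **not** used for the call: its standard error shrinks with the
number of shuffles, so as a single-pattern test it rejects almost always
under the null. The permutation form is exactly calibrated — under CSR the
rejection rate sits at α (verified over 200 fields × 1000 shuffles in the
acceptance suite).

Colocalization counting tabulates marginal percentages and the disjoint
marker-combination partition (which must sum to the total). Input-fraction
tables count D1/D2 upstream labels per starter type and compare types with
pairwise 2×2 Pearson chi-square tests without continuity correction (none
is mentioned in the published statistics; Yates is available via option),
Bonferroni-adjusted across the number of pairs. The derived subpopulation
arithmetic divides the Penk marginal by the Vgat marginal (16/73 → 22%,
complement 78%), rounding to integer percentages as printed.

# Inferential statistics

Paired and one-sample t tests are two-sided with df = n − 1; degenerate
zero-variance inputs return t = 0, p = 1 when the effect is exactly zero
(and ±∞, p = 0 otherwise) instead of erroring. Repeated-measures ANOVA
supports one-way within designs and two-way mixed designs (cell type
between subjects × session within); Greenhouse–Geisser ε is computed from
the double-centered (pooled) covariance of the repeated measures, clamped
to [1/(k−1), 1], and applied to the degrees of freedom of every
within-subject test, with corrected (possibly fractional) df always
reported when correction is on. Designs must be balanced and complete — no
imputation. "Neumann-Keuls" is interpreted as the Student–Newman–Keuls
stepwise procedure: means sorted, extreme pair of each span tested against
the studentized-range distribution (`ptukey`), recursing inward only where
the enclosing span rejects, so non-significance propagates to enclosed
pairs. Classical gating applies: post hoc tests are meant to follow a
significant omnibus F. Bonferroni adjustment is `min(1, m·p)`.

# Validation scale and known limitations

The test suite and acceptance script size their simulations to run on one
CPU in minutes: event-rate recovery uses 300 cells × 60 min at 15 Hz;
clustering calibration uses 200 CSR fields of 200 points with 1000
shuffles each; extraction tests use movies of ~30–40 px frames with 6–10
planted cells. These sizes are the package's validation choices; all
scale-dependent tolerances (2 SEM bands, binomial intervals) are computed
from the sizes actually used.

Known limitations, beyond the generator realism noted above: rate
undercount from unresolvable transient overlaps (quantified above);
PCA/ICA assumes approximately space–time separable, sparsely overlapping
cells and will split or merge components outside that regime; the
responder rule's null rate depends on the smoothing and trial counts and
should always be referenced against its Monte-Carlo null; and none of the
published real-data F/t statistics can be reproduced here because the
recordings are not deposited.
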