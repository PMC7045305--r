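# vpcalcium

Single-cell calcium-imaging and spatial/count analyses for ventral pallidum
(VP) neuron subtypes — glutamatergic (VP<sub>Glu</sub>), GABAergic
(VP<sub>GABA</sub>) and enkephalin-expressing (VP<sub>Penk</sub>) — during
cocaine self-administration, extinction, and cue-induced reinstatement.

The package is aimed at researchers analyzing one-photon miniscope
recordings together with operant behavior and histology. It provides, as
tested R code with seed-deterministic synthetic generators for every input:

- **Preprocessing & extraction** — spatial downsampling (block mean, factor
  4), rigid-body motion correction (FFT cross-correlation with subpixel
  refinement), ΔF/F normalization (running 20th-percentile or global-mean
  baseline), and PCA/ICA cellular source extraction with automated
  component QC.
- **Event analysis** — Ca²⁺ transient detection (prominence ≥ 6 × MAD of
  the smoothed trace, rise-time gate, merge rule), per-cell rates
  (events/min) and amplitudes over the first 60 min, cumulative event
  curves, and the extinction criterion (responding < 40% of the first
  extinction day).
- **Peri-event analysis** — nose-poke-aligned tensors over −10…+20 s
  (10-point moving average, within-window z-score), population response
  magnitude (|z|, pre (−2, 0] vs post (0, 2]), and responder
  classification: a cell is *increased*/*decreased* if its post-poke mean
  deviates by more than 2 SD from the pre-poke baseline.
- **Spatial & counts** — the k-nearest-neighbor clustering test (k = 10;
  observed mean k-NN distance vs 1000 uniform shuffles, permutation p),
  marker colocalization/density tables, rabies D1/D2 input fractions with
  pairwise chi-square, and the derived subpopulation arithmetic.
- **Statistics** — paired/one-sample t tests, one-way and mixed two-way
  repeated-measures ANOVA with Greenhouse–Geisser correction,
  Student–Newman–Keuls post hoc comparisons, chi-square with Bonferroni
  adjustment.

The central quantities, in the field's notation: ΔF/F = (F − F₀)/F₀;
event rate r = N(t < 60 min)/60 in events/min; peri-event z(t) =
(s(t) − μ_w)/σ_w with μ_w, σ_w from the smoothed −10…+20 s window;
responder rule |post − μ_pre| > 2 σ_pre; clustering statistic
D̄ₖ = mean over cells of the Euclidean distance to the k-th nearest
neighbor, tested against a uniform-redraw null.

## Worked example

```r
library(vpcalcium)

# a VP_Glu-like cohort: 40 cells, 60 min at 15 Hz, 2.88 events/min, snr 8
g  <- gen_traces(40, 3600, 2.88, snr = 8, cell_type = "Glu",
                 session = "Ext10", seed = 42)
es <- event_stats(detect_events(g$traces), limit_min = 60)
es
#> <event_stats> first 60 min
#>   cell_type session n_cells rate_mean   rate_sem  amp_mean      amp_sem
#> 1       Glu   Ext10      40    2.7975 0.03672659 0.2510955 0.0007854137
```

The cohort was generated at 2.88 events/min with mean amplitude 0.25 ΔF/F;
detection recovers 2.80 ± 0.04 events/min and 0.251 ΔF/F (the small rate
deficit comes from transients too close to resolve at 15 Hz).

```r
b      <- gen_behavior("Ext1", seed = 42)   # first extinction day
trials <- select_trials(b)                  # pokes >= 20 s from neighbors
cl     <- classify_cells(build_perievent(g$traces, trials))
cl$fractions
#>   cell_type     class fraction n_cells
#> 1       Glu increased    0.100      40
#> 2       Glu decreased    0.125      40
#> 3       Glu unchanged    0.775      40
```

These traces carry no poke-locked modulation, so the ~22% modulated cells
measure the rule's Monte-Carlo null rate (well above the nominal Gaussian
4.6%, because smoothing and averaging correlate the bins).

```r
pp <- gen_point_pattern(200, "clustered",
                        cluster_params = list(n_parents = 6, sigma = 0.03),
                        bounds = c(0, 1, 0, 1), seed = 42)
knn_clustering_test(pp, seed = 43)
#> <knn_result> observed 0.0366 vs null 0.1358 (k=10, 1000 shuffles):
#>   t(999) = 1227.150, p = 0.000999 -> clustered

derive_subpopulation_fractions(penk_pct = 16, vgat_pct = 73)
#> $penk_share_of_gaba
#> [1] 22
#> $complement
#> [1] 78
```

A Thomas-process field is called clustered (observed mean 10-NN distance
0.037 against a uniform null of 0.136; permutation p ≈ 0.001), and the
printed marker densities (Penk 16%, Vgat 73%) give the 22%/78% split of
the GABAergic population.

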