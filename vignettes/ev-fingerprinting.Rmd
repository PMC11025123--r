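---
title: "EV fingerprinting: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{EV fingerprinting: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's account of its science: the measurement model
it assumes, the statistics it computes, the parameters that matter, what the
bundled simulator does and does not emulate, and the choices made where the
design was genuinely open.

## The measurement model

Single extracellular vesicles (EVs) are detected by fluorescence-triggered
flow cytometry after staining with the lipophilic, environment-sensitive dye
di-8-ANEPPS (di8). The dye is essentially non-fluorescent in water and
becomes fluorescent upon intercalating into a lipid bilayer, which gives two
useful signals per vesicle:

* **Brightness scales with membrane area.** Larger particles carry more
  lipid, bind more dye, and yield proportionally more total fluorescence.
  The pipeline's size proxies are the median 488-611 intensity of a
  population (`mfi_611`) and the per-event total fluorescence `tFL`, the sum
  of the five 488 nm-excited intensity channels. Both are *relative* size
  measures; mapping them to nanometers is only done against liposome sizing
  standards (`standard_ladder()`), never absolutely.
* **The emission spectrum reports membrane order.** In disordered (Ld)
  membranes di8 peaks near 702 nm; with increasing lipid order (Lo,
  e.g. rising cholesterol content) the peak shifts toward 611 nm. The
  two-channel generalized polarization
  \[ GP = \frac{I_{611} - I_{702}}{I_{611} + I_{702}} \in [-1, 1] \]
  summarizes this shift per event. GP is scale invariant, so it is
  independent of particle size, and it is computed on raw (untransformed)
  intensities. Events with both channels at zero have undefined GP; they are
  excluded from GP summaries but still counted.

Each event carries 20 dye-derived features: four image features
(`Intensity`, `RawMaxPixel`, `Area`, `AspectRatio`) at five emission bands
(528, 583, 611, 702, 773 nm) under 488 nm excitation. The canonical column
order is feature kind (Intensity, RawMaxPixel, Area, AspectRatio) by
ascending emission; a fixed order is required for reproducible embeddings.
The 456 nm band belongs to the 405 nm-excited antibody channel (BV421) and
is never part of the dye block; the second antibody channel is 642ex/702em
(APC). Spillover compensation is deliberately not modeled or applied
anywhere.

## The workflow

1. **QC** (`qc_dilution_series()`, `lysis_check()`): the quantitative range
   is the contiguous set of dilutions where events/min is linear in
   1/dilution (R² ≥ 0.98 by default) and the 488-611 MFI is stable
   (CV ≤ 20%). Below that range the detector saturates — coincident small
   particles merge into fewer, brighter events (the swarm effect), which
   simultaneously depresses counts and inflates MFI — so saturated points
   are excluded. Detergent lysis must abolish detection (default ceiling:
   lysed/stained rate ratio ≤ 0.10); counts are compared time-normalized.
2. **Gating** (`gate_events()`): events whose 488-611 intensity exceeds the
   0.99 quantile of the buffer control are retained.
3. **Transform**: `asinh(x / cofactor)` on the 20 features, cofactor 1 by
   default (plain asinh). The transform is used for embedding and display
   only; MFI, GP and tFL are computed on the raw scale.
4. **Stage 1 — exploration** (`run_fingerprint()`): a seeded random
   subsample of every sample (default 20%) is embedded jointly in 2-D with
   UMAP (defaults `n_neighbors = 15`, `min_dist = 0.1`, Euclidean) and
   clustered with HDBSCAN. Joint embedding matters: cluster identities and
   the pairwise T-REX comparison must live in one coordinate system.
   Clusters whose time-normalized event share from buffer controls reaches
   50% are removed as background populations.
5. **Stage 2 — re-examination** (`reexamine_clusters()`): a gradient-boosted
   tree classifier (XGBoost, single-threaded, seeded) is trained on the
   subsample's features against its cluster labels (noise included as a
   class) and applied to *all* events, so population statistics come from
   the full data. Prediction ties go to the lowest cluster id.
6. **Population metrics** (`profile_clusters()` and friends): per-cluster
   counts (dilution-corrected to particles/mL via
   `count / (minutes × flow µL/min) × dilution × 1000`), MFI, GP quartiles,
   tFL, abundance, size rank; populations holding ≥ 1% of pooled events are
   examined by default. S-EV/L-EV calls use pellet enrichment: a cluster
   with ≥ 50% of its corrected counts in the 100,000g pellet *and* MFI in
   the lower quartile of the cluster MFI range is S-EV; < 50% is L-EV;
   anything else is unclassified. Condition effects are reported as
   percent-of-control on corrected counts.
7. **T-REX** (`run_trex()`): the pair is balanced by seeded downsampling,
   embedded, and each event receives the fraction *f* of its k = 60 nearest
   neighbors (self excluded) from sample 2. Events with f ≥ 0.95 (or
   ≤ 0.05) are 95%-hotspots, f ≥ 0.85 (≤ 0.15) 85%-hotspots; the ≥ 95%
   events of each direction are grouped into regions with DBSCAN
   (eps = 1 in embedding units, minPts = 1, i.e. eps-connected components).
   Region clustering applies to the ≥ 95% events only; the 85% tier is a
   display/reporting tier.
8. **Multiplex cargo** (`positivity_threshold()`, `classify_cargo()`): an
   event is antibody-positive above a threshold that at most 1% of events in
   *every* negative control exceed (the empirical 0.99 order statistic of
   the worst control). Two-channel status is negative / single A / single B
   / dual, and per-population partitions feed an unweighted least-squares
   regression of percent positive against population size.

## The synthetic event generator

Every downstream stage is testable without instrument data through
`simulate_sample()` and `simulate_scenario()`. The generator draws, per EV
event, a population by abundance, a total brightness
`B ~ Lognormal(meanlog, sdlog)` (membrane-area proxy), and a per-event GP
from a truncated normal around the population's `gp_target`. The emission
spectrum realizing that GP is the convex mixture `α·w_Lo + (1−α)·w_Ld` of
two simplex basis spectra, inverted in closed form by `alpha_for_gp()`. The
default bases,

* `w_Lo = (0.10, 0.12, 0.45, 0.15, 0.18)` (peak 611 nm, GP = +0.5) and
* `w_Ld = (0.08, 0.10, 0.15, 0.45, 0.22)` (peak 702 nm, GP = −0.5),

are simulator conventions, not measured spectra: they reproduce the 702→611
peak-shift phenomenology and make GP targets across (−0.5, 0.5) reachable,
which the benchmark scenario (targets ±0.4) requires. Channel intensities
are `B × spectrum × ` multiplicative log-normal noise with median 1 (CV
0.08 by default), so population *median* GP stays exactly on target under
noise. `RawMaxPixel` follows intensity with a packing factor (0.3), `Area`
scales as `B^0.5`, `AspectRatio` is 1 plus half-normal jitter (sd 0.08),
and `SSC` scales as `B^0.7`. Antibody channels draw from a log-normal noise
floor or, with the population's `cargo_probs`, a positive log-normal mode.

Nuisance events are rate-based (events/min, not diluted): dim spectrally
incoherent background (150/min, lognormal around 6 a.u.) and free dye near
the detection floor (75/min). Controls derive from the same spec: buffer =
background only; lysed = background + free dye (lysis removes all
vesicles); isotype = the full sample with positivity at a 0.5% floor.
Dilution thins EV counts binomially by 1/dilution while nuisance rates stay
fixed; an optional saturation model merges random pairs of events above a
configured events/min ceiling, reproducing the swarm artifact (count
deficit + MFI inflation) that QC must reject.

Default widths were chosen once, as study conditions, and are not tuned:
log-brightness sd 0.15 (15% CV) models populations as *resolved* size
modes — the regime the method is designed for, where populations appear as
clearly separated clusters; `gp_sd = 0.05` keeps neighboring membrane-order states (0.3 GP
apart) distinct. What the generator does **not** emulate: optics and pixel
noise of the detector, dye photochemistry and staining kinetics,
compensation/spillover, overlapping or long-tailed size distributions, and
concentration-dependent staining. Passing the bundled benchmarks therefore
demonstrates that the *algorithms* recover what the model puts in — not
that any particular instrument or sample will separate as cleanly; real
samples with continuous size distributions can merge neighboring
populations.

## Clustering internals

No HDBSCAN implementation is part of the package's dependency stack, and
density clustering is the core of the method, so `hdbscan_clusters()`
implements HDBSCAN* directly: core distances from the `min_samples`-nearest
neighbor (kd-tree), a minimum spanning tree of the mutual-reachability
graph by Prim's algorithm in C++ (O(n²) time, O(n) memory — ample for the
exploration subsample), single-linkage condensation at `min_cluster_size`,
and excess-of-mass cluster extraction. Duplicate points (zero distances)
are handled by capping λ = 1/h; a hierarchy with no surviving split returns
a single cluster rather than all-noise. `min_cluster_size` defaults to
`max(50, 0.1% of events)`, well below the 1% abundance floor used for
reporting, so populations at the reporting threshold are never lost to the
clusterer; `min_samples` is capped at 25, which only smooths the density
estimate without changing which splits survive condensation. Cluster ids
are always relabeled by decreasing size (a pure permutation), with 0 as the
noise label. `dbscan_clusters()` is the classic radius-search DBSCAN used
for hotspot regions; with minPts = 1 it reduces to connected components of
the eps-neighborhood graph, so no hotspot event is ever noise.

## Numerical and tie-breaking conventions

* KNN distance ties at rank k are broken by lowest event index (the exact
  search fetches a small surplus of neighbors and re-sorts by (distance,
  index)), making `knn_fraction()` deterministic and equal to the all-pairs
  oracle on tie-free data.
* XGBoost class-probability ties go to the lowest cluster id; training is
  single-threaded with a fixed seed, so stage 2 is bit-reproducible.
* UMAP runs single-threaded with a seeded RNG; identical input, parameters
  and seed give identical coordinates.
* The positivity threshold is the empirical order statistic
  `sort(x)[ceiling(0.99 n)]` per control, the smallest measured intensity
  with ≤ 1% exceedance, and the final threshold is the maximum across
  controls.
* A constant response in `status_vs_size_regression()` returns slope 0 and
  R² = 0 by convention (the R² of a zero-variance response is undefined).
* The QC window search prefers, among equal-length windows, the one at
  higher dilutions — farther from saturation.
* Every stage derives its RNG stream from one global seed recorded in the
  run manifest, and CSVs (not figures) are the artifacts of record, so a
  run is exactly reproducible from its archived config.

## Problem sizes used in the bundled checks

The benchmark scenario is four populations with GP targets −0.4/−0.1/
+0.2/+0.4, brightness ratios 1/2/4/8, fractions 0.4/0.3/0.2/0.1 at 50,000
events plus a buffer control; recovery is assessed on the 20%-subsample
embedding with stage-2 re-examination of the full data. T-REX calibration
uses 50 replicate null pairs of 1,000 + 1,000 events and a detection pair of
5,000 + 5,000 with an emergent 5% population; cargo checks use 50,000
events. These sizes were chosen so the complete check suite represents the
method's operating regime while remaining convenient to run on a laptop.

## Known limitations

* The GP and tFL definitions are reconstructions of the field's standard
  two-channel GP and summed-intensity statistics; cluster GP is the median
  of event GPs (event-level boxplots imply event-level distributions), not
  the GP of median intensities.
* Absolute sizing is out of scope: MFI and tFL order populations by size
  and are anchored only by liposome standards.
* The multiplex interface accepts exactly two antibody channels; larger
  panels would need spectral unmixing, which the pipeline does not attempt.
* At exactly 10-fold enrichment a population's local sample-2 fraction is
  10/11 ≈ 0.91, below the 0.95 hotspot threshold at k = 60, so T-REX's
  ≥95% tier detects *emergent or strongly enriched* populations; moderate
  fold changes surface in the 85% tier and in percent-of-control instead.
* UMAP coordinates are not metric: eps = 1 for hotspot regions is a
  convention in embedding units, recorded with every run.
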