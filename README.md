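# evfingerprint

Deconvolution of heterogeneous **extracellular vesicle (EV) populations**
from single-particle flow cytometry of lipophilic-dye (di-8-ANEPPS, "di8")
stained samples — for labs running fluorescence-triggered small-particle
cytometry who want population-level answers (how many kinds of vesicles, how
big, how ordered their membranes, which ones change between conditions, and
which cargo they carry) rather than bulk averages.

## The method

Each detected vesicle contributes 20 dye-derived features: four image
features (Intensity, RawMaxPixel, Area, AspectRatio) at five emission bands
(528/583/611/702/773 nm, 488 nm excitation). Two physical signals drive the
analysis:

* **Size** — total di8 fluorescence scales with membrane lipid content, so
  the 488–611 median fluorescence intensity (MFI) and the summed
  total fluorescence (tFL) order populations by relative size.
* **Membrane order** — di8's emission peak shifts from ~702 nm (disordered,
  Ld) toward ~611 nm (ordered, Lo), summarized per event by the generalized
  polarization

  GP = (I₆₁₁ − I₇₀₂) / (I₆₁₁ + I₇₀₂) ∈ [−1, 1].

The workflow: dilution-series QC of the quantitative range and a detergent
lysis specificity check → buffer-based gating → asinh transform → joint 2-D
UMAP embedding of a randomized subsample → HDBSCAN population calling (with
buffer-derived clusters removed) → XGBoost re-examination of the selected
clusters on the full data → per-population profiles (dilution-corrected
counts, MFI, GP, tFL, S-EV/L-EV class, percent-of-control) → pairwise
change detection (T-REX: per-event k = 60 nearest-neighbor sample fractions,
85%/95% hotspots, DBSCAN regions) → multiplexed antibody cargo partitioning
(CD63/CD81-style negative / single / dual gating with ≤1%-in-controls
thresholds). HDBSCAN and DBSCAN are implemented in the package (Rcpp MST +
condensed-tree extraction); UMAP comes from uwot, gradient boosting from
xgboost.

A fully seeded synthetic single-EV simulator (spectral mixture model for the
Lo/Ld emission shift, log-normal brightness for size, background/free-dye/
lysed/isotype controls, dilution series with an optional swarm-saturation
artifact, antibody cargo) generates ground-truth data for every stage, so
the whole pipeline is testable without instrument files. FCS 3.0/3.1 I/O is
built in.

## Worked example

Simulate the bundled four-population benchmark (GP targets −0.4/−0.1/
+0.2/+0.4, brightness ratios 1/2/4/8, abundances 0.4/0.3/0.2/0.1, plus a
buffer control) and run the two-stage pipeline:

```r
library(evfingerprint)

tabs <- simulate_scenario(demo_scenario(n_events = 20000), seed = 11)
fp <- run_fingerprint(tabs, default_config(seed = 7))
fp
#> <ev_fingerprint> 2 samples, 4178 subsampled events, 4 clusters

dplyr::select(filter_minor_clusters(fp$profiles)$pooled,
              cluster, n_pooled, mfi_611, gp_median, abundance, size_rank)
#>   cluster n_pooled mfi_611 gp_median abundance size_rank
#> 1       1     7978    72.5    -0.398    0.3900         4
#> 2       2     5947   216.1    -0.098    0.2907         3
#> 3       3     4082   577.3     0.199    0.1996         2
#> 4       4     1989  1332.4     0.395    0.0972         1
```

Reading the table: the pipeline found the four simulated populations;
`abundance` recovers the generator fractions (0.39/0.29/0.20/0.10 vs
0.4/0.3/0.2/0.1 — the remainder is background), `gp_median` recovers the
membrane-order targets to ±0.005, and `size_rank` (1 = brightest = largest)
inverts cluster order exactly as the 1/2/4/8 brightness ratios dictate.

Quantitative-range QC of a clean dilution series accepts every point:

```r
qc <- qc_dilution_series(simulate_dilution_series(
  list(population_spec("ev", 1, log(800), gp_target = 0)),
  16000, c(1, 2, 4, 8), seed = 3,
  defaults = scenario_defaults(background_rate = 0, free_dye_rate = 0)))
qc
#> accepted window: 1, 2, 4, 8 (R2 = 0.9998, MFI CV = 0.006)
```

Pairwise change detection and cargo gating follow the same pattern — see
`?run_trex`, `?positivity_threshold` and the vignette
(`vignettes/ev-fingerprinting.Rmd`) for the models, parameter meanings and
design choices.

A thin command-line wrapper over these functions ships at
`inst/cli/evfingerprint.R` with subcommands `simulate`, `qc`, `fingerprint`,
`profile`, `trex`, `multiplex` and `report`.

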