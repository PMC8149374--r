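# ramanmark

Multivariate analysis of hyperspectral Raman maps of vessel-wall tissue,
aimed at one question: **does a tissue cohort carry a disease-specific
spectral signature, and where does it live?** The motivating application is
ascending thoracic aortic aneurysm, where extracellular-matrix remodeling
(elastic fiber damage, abnormal collagen) produces Raman-detectable
molecular changes long before any stain is applied.

The package is written for spectroscopists and computational biologists who
have per-pixel Raman spectra of layered tissue and want a tested,
reproducible path from raw maps to group-level statistics.

## What it does

Given maps `A` (channels x pixels, one spectrum per pixel):

1. **Preprocess** — cosmic-ray spike removal, asymmetric-least-squares
   background subtraction, cropping to the 400–1800 cm⁻¹ fingerprint
   region, per-spectrum total-intensity normalization.
2. **Unmix** against a library of reference component spectra (elastic
   fiber, collagen fiber, nuclei, aggrecan, versican, lipid, residual ECM)
   by per-pixel non-negative least squares, yielding abundance heatmaps.
3. **Extract ROI spectra** where a chosen fiber component is strong.
4. **PCA (NIPALS)** on the ROI dataset, with per-animal mean scores for
   statistics.
5. **Sparse MCR-ALS** — the core method. The ROI dataset is factorized as

   ```
   minimize  ‖A − WH‖²_F + λ·‖H‖₁   subject to  W ≥ 0, H ≥ 0
   ```

   (W: component spectra, columns scaled to max 1; H: per-spectrum
   abundances; λ = 0.002 by element-holdout cross-validation; SVD
   initialization; warm-start transfer of components between cohorts).
   The l1 penalty concentrates rare, sample-specific signal into sparse
   components instead of smearing it across dense ones — that is what makes
   a disease-only signature separable.
6. **Statistics** — per-map mean abundances compared between groups through
   a Shapiro-Wilk-gated battery (Student t / one-way ANOVA with Bonferroni
   pairwise comparisons, or Mann-Whitney / Kruskal-Wallis).

A synthetic generator (`simulate_map()`, `simulate_cohort()`) builds layered
vessel-wall maps — intima, elastic lamellae, interlamellar matrix,
adventitia — from literature band assignments, with fluorescence baseline,
noise, cosmic rays, animal-level variability, and focal disease lesions,
returning exact ground truth. Every stage of the pipeline is validated
against it.

## Worked example

Simulate a murine cohort (6 wild-type maps, 6 aneurysm-model maps whose
collagen carries an aneurysm-specific signature), run the whole chain, and
ask whether the pipeline finds the disease component:

```r
library(ramanmark)

cfg <- list(
  seed = 3,
  cohorts = list(
    murine = list(
      species = "mouse", region = "ascending",
      groups = list(
        list(name = "WT", n_maps = 6),
        list(name = "Fbln4SMKO", n_maps = 6,
             disease_components = c("ce1_like", "cc6_like"))))),
  mcr = list(max_iter = 120))
res <- run_all(cfg)

collagen <- res$cohorts$murine$fibers$collagen_fiber
cat("disease-matched component:", collagen$disease_component,
    sprintf("(cosine %.2f vs the cc6-like source)\n",
            collagen$disease_match_cosine))
print(collagen$abundance_stats$disease)
print(collagen$abundance_stats$native)
ax <- res$cohorts$murine$maps[[1]]$wavenumber
w <- collagen$mcr$W[, collagen$disease_component]
cat("recovered phenylalanine bands:",
    find_band_center(w, 1003, 20, wavenumber = ax), "and",
    find_band_center(w, 1613, 20, wavenumber = ax), "cm-1\n")
```

Output:

```
disease-matched component: Cc02 (cosine 0.80 vs the cc6-like source)
<test_report> mann_whitney: statistic = 36, p = 0.002165 (alpha = 0.05)
<test_report> mann_whitney: statistic = 10, p = 0.2403 (alpha = 0.05)
recovered phenylalanine bands: 1002 and 1612 cm-1
```

Reading it: one MCR component (`Cc02`) matches the planted aneurysm
signature; its per-map mean abundance separates the groups (exact
Mann-Whitney p = 0.0022 — complete separation at n = 6 per group), while
the *native* collagen component does not differ (p = 0.24); and the
component's strongest phenylalanine bands localize to 1002 and 1612 cm⁻¹,
one channel from the assigned 1003 and 1613 cm⁻¹. That is the package's
core claim, demonstrated end to end: a signature present only in diseased
tissue is isolated as its own sparse component, flagged as significant, and
its chemistry is readable off the recovered spectrum.

`run_all(cfg, out_dir = "out/")` additionally writes heatmap PNGs/CSVs,
PCA scores and loadings, MCR component spectra, abundance means, statistics
reports, and a run manifest; everything is reproducible byte for byte from
the seed.

## Package layout

- `R/spectral_core.R`, `R/io.R` — domain types (maps, component sets,
  abundance stacks, spectral datasets) and lossless plain-text I/O.
- `R/synthetic.R` — the ground-truth generator.
- `R/preprocessing.R`, `src/als_baseline.cpp` — the preprocessing chain.
- `R/tca.R`, `R/nnls.R` — reference-seeded unmixing and ROI extraction.
- `R/pca.R` — NIPALS PCA.
- `R/mcr.R`, `R/hungarian.R` — sparse MCR-ALS, cross-validation,
  warm-start transfer, component matching.
- `R/stats.R` — gated group statistics.
- `R/pipeline.R`, `R/heatmaps.R` — orchestration and rendering.
- `vignettes/ramanmark-methods.Rmd` — models, assumptions, design choices.
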