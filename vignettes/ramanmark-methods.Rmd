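---
title: "Models and methods behind ramanmark"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind ramanmark}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(ramanmark)
```

`ramanmark` analyzes hyperspectral Raman maps of vessel-wall cross-sections
to find disease-specific spectral signatures of the extracellular matrix.
This vignette explains the models the package implements, the parameters
that matter, the design choices that were genuinely open, and what the
synthetic benchmark does and does not establish.

## The analysis chain

A map holds one spectrum per pixel on a shared wavenumber axis (Raman shift,
cm^-1). The chain is:

1. **Preprocessing** — cosmic-ray removal, background subtraction, cropping
   to the 400–1800 cm^-1 fingerprint region, per-spectrum total-intensity
   normalization.
2. **Reference-seeded unmixing** (`fit_tca()`) — per-pixel non-negative
   least squares against a library of fixed reference spectra (elastic
   fiber, collagen fiber, nuclei, aggrecan, versican, lipid, residual ECM),
   producing abundance heatmaps.
3. **ROI extraction** (`extract_roi_spectra()`) — pixel spectra with high
   abundance of one fiber type form a labelled spectral dataset.
4. **NIPALS PCA** (`fit_pca_nipals()`) with per-animal score means for
   group statistics.
5. **Sparse MCR-ALS** (`fit_mcr_als()`) — the core decomposition. Per-map
   mean abundances of its components are the biomarker readout, compared
   between groups through a normality-gated test battery.

## Sparse MCR-ALS

The data matrix `A` (channels x spectra, non-negative after preprocessing)
is factorized as `A ≈ W H` by minimizing

```
f(W, H) = ||A - W H||_F^2 + lambda * sum(H),    W >= 0, H >= 0,
```

where the l1 term (linear because `H >= 0`) drives rare, sample-specific
sources into their own sparse components instead of being smeared across
dense ones. Defaults follow the intended study design: `lambda = 0.002`
(cross-validated; see below), 16 components for elastic-fiber datasets and
12 for collagen-fiber datasets, SVD initialization restricted to the
fingerprint region.

Solver details:

* **Block coordinate descent.** `H` is updated by cyclic coordinate descent
  with an exact soft-threshold-and-clip minimum per coordinate, vectorized
  over all spectra; `W` by the same machinery without penalty. Both are
  exact coordinate minimizations, so the objective trace is non-increasing
  by construction (asserted in tests on random instances).
* **Scale gauge.** `W H` is invariant to rescaling a column of `W` against
  its `H` row, which would let the factorization defeat the l1 penalty by
  inflating `W`. The usual fix — renormalizing `W` columns every sweep — can
  transiently *increase* the penalized objective (the rescale pushes scale
  into `H`), breaking monotonicity. We instead constrain `W` to `[0, 1]`
  during the alternation (still an exact coordinate minimization, hence
  monotone) and rescale columns to maximum exactly 1 once at convergence;
  that final rescale factor is `<= 1`, so it cannot increase the objective
  either.
* **Tolerances.** Inner coordinate sweeps stop at a relative update of
  1e-10; the outer loop stops when the relative objective change falls
  below `tol` (default 1e-8) or at `max_iter` (default 500). On noisy,
  over-factorized data the ALS tail is slow and the fit routinely runs to
  `max_iter`; component spectra stabilize long before the objective
  formally converges, which is why the pipeline configuration caps sweeps
  at 150.
* **Dead components.** A component whose spectrum collapses to zero is
  reseeded once from the leading SVD direction of the residual (its
  abundance row is zero at that moment, so the objective is unchanged),
  then allowed to die.
* **Penalty selection.** `cross_validate_lambda()` implements Wold-style
  element holdout: a random fraction (default 10%) of matrix entries is
  hidden per fold, the factorization is fitted on the observed entries by
  EM-style imputation (hidden entries replaced by the current `W H` between
  fits), and the mean squared error on the hidden entries scores each
  penalty; ties go to the smaller penalty. Holding out entries rather than
  columns is what makes the criterion sensitive to overfitting of noise by
  surplus components. On synthetic data the selected penalty need not equal
  any particular value; the regime where a positive penalty wins is a rank
  chosen above the dense signal rank.
* **Warm starting.** `warm_start_fit()` transfers components across cohorts:
  `W` is initialized from a base component set plus extra columns from the
  SVD of the initial residual, all columns refine freely, and outputs are
  mapped back to base names by maximal cosine (Hungarian assignment).

## Reference-seeded unmixing and ROI extraction

With all references fixed, unmixing is pixel-separable non-negative least
squares (coordinate descent; verified in tests against an independent
active-set solver). Free components, when requested, are refined by
alternating non-negative updates from a random non-negative start while the
references stay frozen.

ROI extraction thresholds a component's heatmap at a quantile `q` of its
positive values (ties included). The function default is `q = 0.9`; the
pipeline uses `q = 0.6`. The difference matters: after total-intensity
normalization, abundances are *compositional* (shares of a unit-sum
spectrum). A diseased fiber pixel carries extra, disease-specific spectral
mass, so its host-fiber share is necessarily lower than a healthy fiber
pixel's; the top decile therefore contains only the purest healthy fiber
pixels and systematically excludes lesions. Sampling from the top 40% keeps
the dataset fiber-dominated while retaining diseased fiber pixels. The
pipeline also subsamples at most 150 ROI spectra per map (seeded,
deterministic) to keep factorization sizes proportionate.

## NIPALS PCA

PCA is computed by NIPALS — power iteration with deflation, one component
at a time — on mean-centered spectra. Data are never variance-scaled:
loadings are read as spectral shapes, and unit-variance scaling would
distort them. Convergence is a relative score change below 1e-9 (at most
500 iterations per component); the sign of each loading is fixed so its
largest-magnitude element is positive. Tests verify agreement with a direct
SVD to 1e-6 on random matrices, including reconstruction error
(Eckart–Young). Scores are averaged per animal before statistics — the
animal, not the pixel, is the unit of inference. Which principal component
separates groups is data-dependent; the package reports all components and
never hard-codes an index.

## Group statistics

Per-unit summaries (per-animal mean scores, per-map mean abundances) enter
a normality-gated battery mirroring standard practice in this field:
Shapiro-Wilk per group at alpha = 0.05; if every group passes, Student t
(two groups) or one-way ANOVA with all-pairs Bonferroni-adjusted t
comparisons; otherwise Mann-Whitney (exact for n <= 8 without ties) or
Kruskal-Wallis with Bonferroni-adjusted pairwise Mann-Whitney. Bonferroni
adjustment is `min(1, raw * n_comparisons)` with the family being the
pairwise comparisons of one analysis. Two open calls were resolved as
follows: groups too small to test (n < 3) pass the gate (the test has no
power there and the field's default at such n is parametric); constant
groups, where W is undefined, fail it. Note that an exact Mann-Whitney test
at n = 3 per group cannot produce p < 0.1, a hard floor worth remembering
when reading 3-vs-3 comparisons.

## The synthetic generator

The generator builds layered vessel-wall maps: intima at the luminal side,
alternating medial elastic lamellae and interlamellar matrix, adventitia.
Component spectra are sums of Gaussian bands (FWHM 12 cm^-1, a typical
condensed-phase protein bandwidth) at literature-assigned positions —
elastin crosslinks (desmosine/isodesmosine) at 528/957/1108 cm^-1,
collagen proline/hydroxyproline at 855/878/921/938 cm^-1, and so on —
with relative amplitudes chosen by the generator (only positions are
literature-backed). Two disease-only components exist: an elastic-fiber
substructure lacking the crosslink bands, and a collagen signature rich in
amino-acid residue bands (phenylalanine, tyrosine, tryptophan, cysteine,
aspartate/glutamate).

Geometry follows the two scan formats (100 x 200 um at 2 um pixels;
10 x 150 um at 1 um pixels). Nuisance structure: a smooth non-negative
per-pixel polynomial baseline (degree 3) standing in for tissue
autofluorescence, additive Gaussian noise (SD 0.01 of unit band height),
signal-proportional noise, and Poisson-counted single-channel cosmic-ray
spikes at 20-100x the spectrum maximum. Human maps differ from murine ones
by a systematic +2 cm^-1 band shift and one low-level human-only component.

Three realism choices deserve emphasis, because without them the benchmark
would mislead:

* **Animal-level variability.** Every component's level is jittered per map
  by a lognormal factor (CV 0.2). Cohorts without between-animal scatter
  make any systematic compositional shift "significant" at any n.
* **Focal lesions.** Disease components occupy a contiguous patch of about
  half their host zone, not the whole wall — the elastic-fiber marker on
  the lamellae, the collagen marker on the adventitia extending into the
  interlamellar layers (diseased collagen expands into the media). The
  extension into collagen-poor pixels is also what makes the disease
  spectrum identifiable: a signature that only ever co-occurs with its host
  in fixed proportion cannot be separated by any factorization.
* **Fibrotic co-accumulation.** Lesion pixels also gain host-fiber mass (an
  independent random field, scaled by the two spectra's integrated
  intensities), so the host's share of a lesion pixel stays comparable to
  healthy tissue. This reproduces the observed pattern that the *native*
  fiber readout does not differ between groups while the disease signature
  does.

Ground truth (component spectra and per-pixel abundances) is returned with
every simulated map; control groups carry exactly zero disease abundance,
which is what makes specificity tests exact.

What passing tests on this generator shows: the solver recovers known
mixtures, the pipeline detects a component present only in diseased maps
and localizes its bands to the correct channels, and the statistics behave
at their nominal levels. What it does not show: performance on real tissue,
where band shapes vary with molecular environment, baselines are not
polynomial, components are not a fixed library, and disease effects are not
binary presence/absence.

## Problem sizes and determinism

The demo configuration (`default_run_config()`) simulates a murine cohort
(WT, Fbln5KO, Fbln4SMKO; 6 high-resolution maps each) and a human cohort
(3 control, 3 aTAA) whose MCR is warm-started from the murine components;
it completes in a few minutes on one core, with MCR sweeps capped at 150
and at most 150 ROI spectra per map. All randomness is derived from the
single configuration seed (per-map seeds are deterministic functions of
it), so a run is reproducible byte for byte; this is asserted in the test
suite by hashing every written output twice.

## Known limitations

* The unmixing step fixes "fixed" references as bit-frozen; it never
  refines them, and it does not choose the number of free components.
* MCR-ALS non-uniqueness is tamed, not removed, by non-negativity and
  sparsity; matched cosines through the full pipeline are lower (~0.8) than
  direct factorization of pixel data (>0.95) because ROI selection on
  compositional abundances dilutes lesion pixels.
* The ALS background estimator assumes a baseline smoother than the bands;
  sharp fluorescence edges would leak into components.
* The two-way ANOVA named in the statistical battery is exposed but unused
  by the default pipeline, which has no factorial design.
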