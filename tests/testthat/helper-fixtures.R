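# Fixtures built in code, shared across test files.

tiny_axis <- function(n = 5, lo = 400, step = 10) seq(lo, by = step,
                                                      length.out = n)

# a small valid map with deterministic data
tiny_map <- function(n_rows = 2, n_cols = 3, m = 5, meta = list()) {
  ax <- tiny_axis(m)
  data <- matrix(seq_len(m * n_rows * n_cols) / 10, m, n_rows * n_cols)
  raman_map(ax, data, n_rows, n_cols, c(1, 1), meta)
}

# map of two spatially disjoint pure regions built from two gaussian-band
# components: left half pure P, right half pure Q (no noise, no baseline)
pure_two_region_map <- function(n_rows = 6, n_cols = 10) {
  ax <- default_axis()
  refs <- reference_library(ax, c("nuclei", "lipid"))
  n <- n_rows * n_cols
  H <- matrix(0, 2, n)
  left <- rep(rep(c(TRUE, FALSE), each = n_cols / 2), n_rows)
  H[1, left] <- 1
  H[2, !left] <- 1
  list(map = raman_map(ax, refs$spectra %*% H, n_rows, n_cols),
       refs = refs, H = H, left_mask = left)
}

# quick cosine between two vectors
vcos <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))

# cheap noiseless simulation settings
no_noise <- function() noise_model(gaussian_sd = 0, shot_scale = 0,
                                   baseline_coeff_range = c(0, 0),
                                   spike_rate = 0)

# shared small aneurysm-vs-control cohort pipeline run, computed once per
# session and reused by the acceptance checks (band recovery + specificity)
.cohort_cache <- new.env(parent = emptyenv())
cached_two_group_run <- function() {
  if (is.null(.cohort_cache$run)) {
    cfg <- list(
      seed = 3,
      cohorts = list(
        murine = list(species = "mouse", region = "ascending",
                      groups = list(
                        list(name = "WT", n_maps = 6),
                        list(name = "Fbln4SMKO", n_maps = 6,
                             disease_components = c("ce1_like",
                                                    "cc6_like"))))),
      mcr = list(max_iter = 120))
    .cohort_cache$run <- run_all(cfg)
  }
  .cohort_cache$run
}
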