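# Synthetic vessel-wall map generator. Emulates layered aortic cross-sections
# (intima, medial elastic lamellae with interlamellar matrix, adventitia)
# whose pixel spectra mix literature-assigned component spectra, plus the
# nuisance structure real instruments produce: smooth autofluorescence
# baseline, additive and signal-proportional noise, and cosmic-ray spikes.
# Ground truth (component spectra and per-pixel abundances) is returned with
# every map so downstream recovery can be scored exactly.

#' Default synthetic wavenumber axis
#'
#' @param lo,hi Range in cm^-1. The fingerprint region is 400-1800; the
#'   generator often uses 300-2000 so that cropping is exercised.
#' @param step Channel spacing in cm^-1.
#' @return Numeric axis.
#' @export
default_axis <- function(lo = 400, hi = 1800, step = 2) {
  wavenumber_axis(seq(lo, hi, by = step))
}

# run code under a temporary RNG state; restores the caller's stream
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed %% 2147483647))
  force(code)
}

#' Literature band tables for the synthetic tissue components
#'
#' Band centers follow published vibrational assignments for vascular tissue:
#' elastic fibers carry the elastin crosslink (desmosine/isodesmosine) bands
#' at 528, 957 and 1108 cm^-1 plus amide III/I and CH deformation bands;
#' collagen fibers carry proline/hydroxyproline bands (855, 878, 921,
#' 938 cm^-1); nuclei carry nucleotide/phosphate bands; aggrecan, versican,
#' lipid and a residual-ECM protein background complete the healthy wall.
#' Two disease-only components are included: `ce1_like`, an
#' aneurysm-associated elastic-fiber substructure with protein bands
#' (phenylalanine 1002, amide III ~1252, CH 1450, 1613 cm^-1) and, crucially,
#' no desmosine/isodesmosine bands; and `cc6_like`, an aneurysm-specific
#' collagen-fiber signature rich in amino-acid residue bands (phenylalanine
#' 616/1003/1222/1613, tyrosine 642/833/1170, tryptophan 749/1018/1336/1455,
#' cysteine 515, aspartate/glutamate 1412 cm^-1). `human_matrix` is a small
#' human-only extra component. Relative amplitudes and the common 12 cm^-1
#' FWHM are generator choices, not literature values.
#'
#' @return Named list of band tables; each a data.frame with columns
#'   `center_cm1`, `fwhm_cm1`, `amplitude`, `lineshape`.
#' @export
builtin_band_tables <- function() {
  band <- function(centers, amps, fwhm = 12, lineshape = "gaussian") {
    data.frame(center_cm1 = centers, fwhm_cm1 = fwhm, amplitude = amps,
               lineshape = lineshape, stringsAsFactors = FALSE)
  }
  list(
    elastic_fiber = band(c(528, 904, 957, 1108, 1255, 1455, 1666),
                         c(0.70, 0.45, 0.70, 0.60, 0.80, 0.90, 1.00)),
    collagen_fiber = band(c(817, 855, 878, 921, 938, 1670),
                          c(0.50, 0.90, 0.70, 0.60, 0.80, 1.00)),
    nuclei = band(c(787, 1094, 1580), c(1.00, 0.70, 0.80)),
    aggrecan = band(c(947, 1066, 1271, 1382), c(0.70, 1.00, 0.60, 0.70)),
    versican = band(c(848, 918, 1080), c(0.80, 0.70, 1.00)),
    lipid = band(c(1312, 1443, 1748), c(0.70, 1.00, 0.60)),
    residual_ecm = band(c(1459, 1666), c(1.00, 0.90)),
    ce1_like = band(c(1002, 1252, 1450, 1613), c(1.00, 0.70, 0.80, 0.90)),
    cc6_like = band(
      c(515, 616, 642, 749, 833, 1003, 1018, 1170, 1222, 1336, 1412, 1455,
        1613),
      c(0.40, 0.50, 0.50, 0.70, 0.60, 1.00, 0.70, 0.50, 0.60, 0.80, 0.50,
        0.70, 0.90)),
    human_matrix = band(c(680, 1530, 1745), c(0.60, 1.00, 0.50))
  )
}

#' Render a band table into a spectrum
#'
#' Sum of Gaussian or Lorentzian lineshapes; additive in bands. Bands whose
#' center lies outside the axis range are skipped with a warning.
#'
#' @param bands Band table (see [builtin_band_tables()]).
#' @param axis Wavenumber axis.
#' @return A `raman_spectrum` (not normalized).
#' @export
render_reference <- function(bands, axis) {
  axis <- wavenumber_axis(axis)
  y <- numeric(length(axis))
  for (i in seq_len(nrow(bands))) {
    b <- bands[i, ]
    if (b$center_cm1 < min(axis) || b$center_cm1 > max(axis)) {
      rm_warn(sprintf("band at %g cm-1 lies outside the axis; skipped",
                      b$center_cm1), "band_outside_axis")
      next
    }
    if (b$fwhm_cm1 <= 0 || b$amplitude < 0 || !is.finite(b$amplitude)) {
      rm_abort("bands need fwhm > 0 and finite amplitude >= 0", "bad_band")
    }
    d <- axis - b$center_cm1
    y <- y + switch(as.character(b$lineshape),
      gaussian = b$amplitude * exp(-4 * log(2) * d^2 / b$fwhm_cm1^2),
      lorentzian = b$amplitude * (b$fwhm_cm1 / 2)^2 /
        (d^2 + (b$fwhm_cm1 / 2)^2),
      rm_abort(sprintf("unknown lineshape '%s'", b$lineshape), "bad_band"))
  }
  raman_spectrum(axis, y)
}

#' Render a reference component library
#'
#' @param axis Wavenumber axis.
#' @param components Component names from [builtin_band_tables()].
#' @param shift_cm1 Systematic band shift applied to every center (used to
#'   emulate small species differences).
#' @param fixed Logical: mark components as fixed reference signatures.
#' @return A `component_set` (columns max-normalized).
#' @export
reference_library <- function(axis, components = names(builtin_band_tables()),
                              shift_cm1 = 0, fixed = TRUE) {
  tables <- builtin_band_tables()
  unknown <- setdiff(components, names(tables))
  if (length(unknown)) {
    rm_abort(sprintf("unknown component name(s): %s",
                     paste(unknown, collapse = ", ")), "unknown_component")
  }
  W <- vapply(components, function(nm) {
    tb <- tables[[nm]]
    tb$center_cm1 <- tb$center_cm1 + shift_cm1
    render_reference(tb, axis)$intensity
  }, numeric(length(axis)))
  component_set(axis, W, components, rep(fixed, length(components)))
}

#' Layered vessel-wall layout
#'
#' Partitions the pixel grid into intima (luminal side, left), alternating
#' medial elastic lamellae and interlamellar matrix, and adventitia. Layers
#' run along columns; column 1 is the luminal side.
#'
#' @param n_rows,n_cols Grid size.
#' @param n_lamellae Number of elastic lamellae (>= 1).
#' @return Object of class `tissue_layout`: list of logical masks `intima`,
#'   `media_lamellae`, `interlamellar`, `adventitia` that partition the grid.
#' @export
tissue_layout <- function(n_rows, n_cols, n_lamellae = 5) {
  if (n_lamellae < 1) rm_abort("need at least one lamella", "bad_layout")
  zone <- character(n_cols)
  i_int <- max(1L, round(0.06 * n_cols))
  i_med <- max(i_int + 2L * n_lamellae, round(0.64 * n_cols))
  zone[seq_len(n_cols) <= i_int] <- "intima"
  zone[seq_len(n_cols) > i_med] <- "adventitia"
  med_cols <- which(zone == "")
  # alternate lamellae and interlamellar bands of near-equal width
  band_id <- floor((seq_along(med_cols) - 1) / length(med_cols) *
                     (2 * n_lamellae)) + 1
  zone[med_cols] <- ifelse(band_id %% 2 == 1, "media_lamellae",
                           "interlamellar")
  masks <- lapply(c(intima = "intima", media_lamellae = "media_lamellae",
                    interlamellar = "interlamellar",
                    adventitia = "adventitia"), function(z) {
    matrix(rep(zone == z, each = n_rows), n_rows, n_cols)
  })
  structure(c(masks, list(n_rows = n_rows, n_cols = n_cols,
                          orientation = "luminal_left")),
            class = "tissue_layout")
}

#' Noise model for synthetic maps
#'
#' @param gaussian_sd Additive Gaussian noise SD (units of the unit-max
#'   component spectra).
#' @param shot_scale Signal-proportional noise scale: SD = shot_scale *
#'   sqrt(signal).
#' @param baseline_poly_degree Degree of the smooth per-pixel fluorescence
#'   baseline polynomial.
#' @param baseline_coeff_range Range for the (non-negative) baseline
#'   coefficients.
#' @param spike_rate Expected number of cosmic-ray spikes per map (Poisson).
#' @param spike_amp_range Spike amplitude, in multiples of the pixel's
#'   spectrum maximum.
#' @return Object of class `noise_model`.
#' @export
noise_model <- function(gaussian_sd = 0.01, shot_scale = 0.01,
                        baseline_poly_degree = 3,
                        baseline_coeff_range = c(0, 0.2),
                        spike_rate = 5, spike_amp_range = c(20, 100)) {
  stopifnot(gaussian_sd >= 0, shot_scale >= 0, spike_rate >= 0,
            baseline_poly_degree >= 0)
  structure(list(gaussian_sd = gaussian_sd, shot_scale = shot_scale,
                 baseline_poly_degree = baseline_poly_degree,
                 baseline_coeff_range = baseline_coeff_range,
                 spike_rate = spike_rate, spike_amp_range = spike_amp_range),
            class = "noise_model")
}

scan_geometry <- function(scan_kind) {
  switch(scan_kind,
    # 100 x 200 um at 2 x 2 um pixels
    large_area = list(n_rows = 50L, n_cols = 100L, pixel_size_um = c(2, 2)),
    # 10 x 150 um at 1 x 1 um pixels
    high_res = list(n_rows = 10L, n_cols = 150L, pixel_size_um = c(1, 1)),
    rm_abort(sprintf("unknown scan_kind '%s'", scan_kind), "bad_metadata"))
}

# components always present in a healthy wall, with placement and base level
base_component_spec <- function() {
  data.frame(
    component = c("elastic_fiber", "collagen_fiber", "nuclei", "aggrecan",
                  "versican", "lipid", "residual_ecm"),
    placement = c("media_lamellae", "adventitia", "scatter", "interlamellar",
                  "interlamellar_intima", "scatter_sparse", "all"),
    level = c(1.0, 1.0, 0.8, 0.5, 0.5, 0.4, 0.25),
    stringsAsFactors = FALSE)
}

# focal lesion: a contiguous column patch (about half the host zone) inside
# the host mask. Disease signatures concentrate in lesions rather than
# blanketing the wall, which keeps the native-fiber readout comparable
# across groups while the disease readout stays positive in every diseased
# map.
lesion_patch <- function(host, layout, frac = 0.5) {
  cols <- which(colSums(host) > 0)
  width <- max(1L, round(frac * length(cols)))
  start <- sample.int(length(cols) - width + 1L, 1)
  lesion <- matrix(FALSE, layout$n_rows, layout$n_cols)
  lesion[, cols[start:(start + width - 1L)]] <- TRUE
  host & lesion
}

component_abundance <- function(placement, level, layout) {
  nr <- layout$n_rows; nc <- layout$n_cols
  mask <- switch(placement,
    media_lamellae = layout$media_lamellae,
    adventitia = layout$adventitia,
    interlamellar = layout$interlamellar,
    interlamellar_intima = layout$interlamellar | layout$intima,
    disease_elastic = lesion_patch(layout$media_lamellae, layout),
    # the abnormal collagen signature expands from the adventitia into the
    # medial (interlamellar) layers, so its lesion spans both
    disease_collagen = lesion_patch(layout$adventitia | layout$interlamellar,
                                    layout),
    disease = lesion_patch(layout$media_lamellae | layout$interlamellar |
                             layout$adventitia, layout),
    all = matrix(TRUE, nr, nc),
    scatter = matrix(stats::runif(nr * nc) < 0.08, nr, nc),
    scatter_sparse = matrix(stats::runif(nr * nc) < 0.05, nr, nc),
    rm_abort(sprintf("unknown placement '%s'", placement), "bad_layout"))
  ab <- matrix(0, nr, nc)
  n_in <- sum(mask)
  if (n_in > 0) ab[mask] <- level * stats::runif(n_in, 0.5, 1)
  ab
}

#' Simulate one vessel-wall hyperspectral map with ground truth
#'
#' Pixel spectra are `sum_j truth_j * reference_j + baseline + noise +
#' spikes`, clipped at zero. Disease components have nonzero abundance only
#' when named in `disease_components`, and only inside the media/adventitia
#' masks — control maps carry exactly zero disease abundance, which is what
#' makes downstream specificity tests exact.
#'
#' @param group Group name (e.g. "WT", "Fbln4SMKO", "aTAA").
#' @param axis Wavenumber axis (must span at least 400-1800 cm^-1).
#' @param layout A `tissue_layout`; defaults to the scan geometry's grid.
#' @param noise A `noise_model`; use zeroed rates for noiseless maps.
#' @param seed Integer seed; the same seed reproduces the map bit-for-bit.
#' @param disease_components Character vector of disease-only component names
#'   (subset of the band tables).
#' @param disease_level Ground-truth abundance level of disease components.
#' @param level_cv Between-map biological variability: every component's
#'   level in this map is multiplied by a lognormal factor with this
#'   coefficient of variation (mean 1). Real cohorts scatter animal to
#'   animal; without this, within-group variance collapses and any
#'   systematic difference becomes spuriously significant.
#' @param species `"mouse"` or `"human"`. Human maps get a small (+2 cm^-1)
#'   systematic band shift and a low-level human-only extra component.
#' @param region,animal_id,scan_kind Metadata.
#' @param keep_baseline Return the baseline matrix (memory-heavy; used by
#'   tests).
#' @return Object of class `raman_sim`: list with `map` (`raman_map`),
#'   `truth` (`abundance_stack`), `components` (`component_set` actually
#'   mixed), and optionally `baseline`.
#' @export
simulate_map <- function(group, axis = default_axis(), layout = NULL,
                         noise = noise_model(), seed = 1,
                         disease_components = character(0),
                         disease_level = 0.6, level_cv = 0.2,
                         species = "mouse", region = "ascending",
                         animal_id = "a1", scan_kind = "high_res",
                         keep_baseline = FALSE) {
  axis <- wavenumber_axis(axis)
  if (min(axis) > 400 || max(axis) < 1800) {
    rm_abort("simulation axis must span at least 400-1800 cm-1", "bad_axis")
  }
  geom <- scan_geometry(scan_kind)
  if (is.null(layout)) layout <- tissue_layout(geom$n_rows, geom$n_cols)
  spec <- base_component_spec()
  unknown <- setdiff(disease_components, names(builtin_band_tables()))
  if (length(unknown)) {
    rm_abort(sprintf("unknown component name(s): %s",
                     paste(unknown, collapse = ", ")), "unknown_component")
  }
  comp_names <- c(spec$component, disease_components)
  disease_placement <- function(nm) {
    switch(nm, ce1_like = "disease_elastic", cc6_like = "disease_collagen",
           "disease")
  }
  placements <- c(spec$placement,
                  vapply(disease_components, disease_placement,
                         character(1)))
  levels <- c(spec$level, rep(disease_level, length(disease_components)))
  if (identical(species, "human")) {
    comp_names <- c(comp_names, "human_matrix")
    placements <- c(placements, "interlamellar_intima")
    levels <- c(levels, 0.3)
  }
  shift <- if (identical(species, "human")) 2 else 0
  refs <- reference_library(axis, comp_names, shift_cm1 = shift)

  with_seed(seed, {
    nr <- layout$n_rows; nc <- layout$n_cols; npix <- nr * nc
    m <- length(axis)
    if (level_cv > 0) {
      sdlog <- sqrt(log(1 + level_cv^2))
      levels <- levels * stats::rlnorm(length(levels), -sdlog^2 / 2, sdlog)
    }
    truth <- array(0, dim = c(nr, nc, length(comp_names)))
    for (j in seq_along(comp_names)) {
      truth[, , j] <- component_abundance(placements[j], levels[j], layout)
    }
    # fibrotic co-accumulation: aneurysm lesions accumulate host fiber along
    # with the disease signature, so the host's *share* of a lesion pixel
    # stays comparable to healthy tissue (scaled by the spectra's integrated
    # intensities); without this the disease signature would read out as a
    # systematic loss of native fiber, which healthy-vs-aneurysm cohorts do
    # not show
    host_of <- c(ce1_like = "elastic_fiber", cc6_like = "collagen_fiber")
    for (j in seq_along(comp_names)) {
      nm <- comp_names[j]
      if (nm %in% names(host_of) && host_of[[nm]] %in% comp_names) {
        hj <- match(host_of[[nm]], comp_names)
        ratio <- sum(refs$spectra[, nm]) / sum(refs$spectra[, host_of[[nm]]])
        lesion <- truth[, , j] > 0
        # independent per-pixel draw: fibrosis is co-located with the
        # marker but not molecule-for-molecule proportional to it (a
        # proportional boost would make the two spectra unidentifiable)
        boost <- ratio * max(truth[, , j]) * stats::runif(sum(lesion), 0, 1)
        truth[, , hj][lesion] <- truth[, , hj][lesion] + boost
      }
    }
    stack <- abundance_stack(comp_names, truth)
    H <- stack_to_h(stack)
    signal <- refs$spectra %*% H

    # smooth non-negative fluorescence baseline, decreasing toward high shift
    x <- (axis - min(axis)) / (max(axis) - min(axis))
    deg <- noise$baseline_poly_degree
    basis <- outer(1 - x, 0:deg, `^`)                     # m x (deg+1), >= 0
    coef <- matrix(stats::runif(npix * (deg + 1),
                                noise$baseline_coeff_range[1],
                                noise$baseline_coeff_range[2]),
                   deg + 1, npix)
    baseline <- basis %*% coef

    data <- signal + baseline
    if (noise$gaussian_sd > 0) {
      data <- data + matrix(stats::rnorm(m * npix, 0, noise$gaussian_sd),
                            m, npix)
    }
    if (noise$shot_scale > 0) {
      data <- data + matrix(stats::rnorm(m * npix), m, npix) *
        (noise$shot_scale * sqrt(pmax(signal, 0)))
    }
    if (noise$spike_rate > 0) {
      n_spikes <- stats::rpois(1, noise$spike_rate)
      if (n_spikes > 0) {
        px <- sample.int(npix, n_spikes, replace = TRUE)
        ch <- sample.int(m, n_spikes, replace = TRUE)
        amp <- stats::runif(n_spikes, noise$spike_amp_range[1],
                            noise$spike_amp_range[2])
        for (s in seq_len(n_spikes)) {
          data[ch[s], px[s]] <- data[ch[s], px[s]] +
            amp[s] * max(data[, px[s]])
        }
      }
    }
    data <- pmax(data, 0)
    map <- raman_map(axis, data, nr, nc, geom$pixel_size_um,
                     meta = list(group = group, region = region,
                                 species = species, animal_id = animal_id,
                                 scan_kind = scan_kind))
    out <- list(map = map, truth = stack, components = refs, seed = seed)
    if (keep_baseline) out$baseline <- baseline
    structure(out, class = "raman_sim")
  })
}

#' Describe a synthetic cohort
#'
#' @param groups List of group specs; each a list with `name`, `n_maps`, and
#'   optionally `region`, `species`, `disease_components`, `disease_level`.
#' @param scan_kind `"large_area"` or `"high_res"`.
#' @param noise A `noise_model`.
#' @param seed Cohort master seed; per-map seeds are derived from it.
#' @param axis Wavenumber axis.
#' @return Object of class `cohort_design`.
#' @export
cohort_design <- function(groups, scan_kind = "high_res",
                          noise = noise_model(), seed = 1,
                          axis = default_axis()) {
  if (length(groups) < 1) rm_abort("cohort needs at least one group",
                                   "empty_design")
  known <- names(builtin_band_tables())
  for (g in groups) {
    if (is.null(g$name)) rm_abort("each group needs a name", "empty_design")
    if (is.null(g$n_maps) || g$n_maps < 1) {
      rm_abort(sprintf("group '%s' needs n_maps >= 1", g$name),
               "empty_design")
    }
    bad <- setdiff(g$disease_components %||% character(0), known)
    if (length(bad)) {
      rm_abort(sprintf("group '%s': unknown component(s) %s", g$name,
                       paste(bad, collapse = ", ")), "unknown_component")
    }
  }
  structure(list(groups = groups, scan_kind = scan_kind, noise = noise,
                 seed = seed, axis = wavenumber_axis(axis)),
            class = "cohort_design")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

map_seed <- function(master, index) {
  (as.numeric(master) * 1000003 + index * 7919) %% 2147483647
}

#' Simulate a cohort of maps
#'
#' One map per animal/patient per group spec. Per-map seeds are derived
#' deterministically from the design seed, so the same design reproduces the
#' identical cohort.
#'
#' @param design A [cohort_design()].
#' @return List of `raman_sim` objects (length = total n_maps).
#' @export
simulate_cohort <- function(design) {
  stopifnot(inherits(design, "cohort_design"))
  geom <- scan_geometry(design$scan_kind)
  layout <- tissue_layout(geom$n_rows, geom$n_cols)
  sims <- list()
  idx <- 0L
  for (g in design$groups) {
    for (i in seq_len(g$n_maps)) {
      idx <- idx + 1L
      sims[[idx]] <- simulate_map(
        group = g$name, axis = design$axis, layout = layout,
        noise = design$noise, seed = map_seed(design$seed, idx),
        disease_components = g$disease_components %||% character(0),
        disease_level = g$disease_level %||% 0.6,
        level_cv = g$level_cv %||% 0.2,
        species = g$species %||% "mouse",
        region = g$region %||% "ascending",
        animal_id = sprintf("%s_%02d", g$name, i),
        scan_kind = design$scan_kind)
    }
  }
  sims
}
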