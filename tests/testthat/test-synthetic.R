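test_that("band tables carry the published assignments", {
  tb <- builtin_band_tables()
  # elastin crosslink (desmosine/isodesmosine) bands in elastic fiber
  expect_true(all(c(528, 957, 1108) %in% tb$elastic_fiber$center_cm1))
  # collagen proline/hydroxyproline bands
  expect_true(all(c(855, 878, 921, 938) %in% tb$collagen_fiber$center_cm1))
  # the aneurysm elastic component has no desmosine/isodesmosine bands
  expect_false(any(c(528, 957, 1108) %in% tb$ce1_like$center_cm1))
  expect_true(1002 %in% tb$ce1_like$center_cm1)
  # cc6: amino-acid residue bands (phe, tyr, trp, cys, asp/glu)
  expect_true(all(c(616, 1003, 1222, 1613, 642, 833, 1170, 749, 1018, 1336,
                    1455, 515, 1412) %in% tb$cc6_like$center_cm1))
  # all centers inside the fingerprint region
  for (nm in names(tb)) {
    expect_true(all(tb[[nm]]$center_cm1 >= 400 & tb[[nm]]$center_cm1 <= 1800),
                info = nm)
    expect_true(all(tb[[nm]]$fwhm_cm1 > 0 & tb[[nm]]$amplitude >= 0))
  }
})

test_that("render_reference places bands where assigned", {
  ax <- default_axis()
  one <- data.frame(center_cm1 = 1002, fwhm_cm1 = 12, amplitude = 1,
                    lineshape = "gaussian")
  sp <- render_reference(one, ax)
  expect_equal(ax[which.max(sp$intensity)],
               ax[which.min(abs(ax - 1002))])
  expect_true(all(sp$intensity >= 0))

  # empty band list -> zero spectrum
  zero <- render_reference(one[0, ], ax)
  expect_true(all(zero$intensity == 0))

  # additive in bands
  two <- rbind(one, data.frame(center_cm1 = 1500, fwhm_cm1 = 12,
                               amplitude = 0.5, lineshape = "gaussian"))
  expect_equal(render_reference(two, ax)$intensity,
               sp$intensity + render_reference(two[2, ], ax)$intensity)

  # out-of-axis band: warning, skipped
  far <- data.frame(center_cm1 = 3000, fwhm_cm1 = 12, amplitude = 1,
                    lineshape = "gaussian")
  expect_warning(skip <- render_reference(rbind(one, far), ax),
                 class = "ramanmark_warning_band_outside_axis")
  expect_equal(skip$intensity, sp$intensity)

  # elastic fiber reference has local maxima at the crosslink bands
  el <- render_reference(builtin_band_tables()$elastic_fiber, ax)
  for (cc in c(528, 957, 1108)) {
    i <- which.min(abs(ax - cc))
    expect_true(el$intensity[i] >= el$intensity[i - 1] &&
                  el$intensity[i] >= el$intensity[i + 1], info = cc)
  }
})

test_that("simulated maps are reproducible and honor disease placement", {
  s1 <- simulate_map("WT", seed = 11)
  s2 <- simulate_map("WT", seed = 11)
  expect_identical(s1$map$data, s2$map$data)

  # control map: no disease component in the truth at all
  expect_false("cc6_like" %in% s1$truth$names)
  sa <- simulate_map("Fbln4SMKO", seed = 11,
                     disease_components = c("ce1_like", "cc6_like"))
  expect_true(all(c("ce1_like", "cc6_like") %in% sa$truth$names))
  # disease abundance only inside media/adventitia, never intima
  lay <- tissue_layout(10, 150)
  for (dc in c("ce1_like", "cc6_like")) {
    h <- sa$truth$maps[, , dc]
    expect_true(sum(h) > 0)
    expect_true(all(h[lay$intima] == 0), info = dc)
  }
  expect_true(all(sa$map$data >= 0))
  expect_true(all(sa$truth$maps >= 0))
  expect_error(simulate_map("X", disease_components = "nope"),
               class = "ramanmark_error_unknown_component")
})

test_that("with noise off the residual is exactly the baseline and NNLS
          recovers the ground truth", {
  nm <- noise_model(gaussian_sd = 0, shot_scale = 0, spike_rate = 0)
  sim <- simulate_map("WT", noise = nm, seed = 5, keep_baseline = TRUE,
                      level_cv = 0)
  mix <- sim$components$spectra %*% stack_to_h(sim$truth)
  expect_equal(sim$map$data - mix, sim$baseline, tolerance = 1e-12,
               ignore_attr = TRUE)

  # noise AND baseline off: NNLS against the true components recovers truth
  sim0 <- simulate_map("WT", noise = no_noise(), seed = 5, level_cv = 0)
  H_hat <- nnls_cd(sim0$components$spectra, sim0$map$data)
  H_true <- stack_to_h(sim0$truth)
  expect_lt(max(abs(H_hat - H_true)) / max(H_true), 1e-6)
})

test_that("cohorts are deterministic with the documented geometry", {
  design <- cohort_design(list(list(name = "WT", n_maps = 6),
                               list(name = "Fbln5KO", n_maps = 6),
                               list(name = "Fbln4SMKO", n_maps = 6,
                                    disease_components = "cc6_like")),
                          seed = 2)
  sims <- simulate_cohort(design)
  expect_length(sims, 18)
  expect_equal(sims[[1]]$map$n_rows, 10L)    # high-res: 10 x 150 um at 1 um
  expect_equal(sims[[1]]$map$n_cols, 150L)
  expect_equal(sims[[1]]$map$pixel_size_um, c(1, 1))
  sims2 <- simulate_cohort(design)
  expect_identical(sims[[7]]$map$data, sims2[[7]]$map$data)
  # per-map seeds differ -> maps differ
  expect_false(identical(sims[[1]]$map$data, sims[[2]]$map$data))

  la <- ramanmark:::scan_geometry("large_area")  # 100 x 200 um at 2 um
  expect_equal(la$n_rows * la$pixel_size_um[1], 100)
  expect_equal(la$n_cols * la$pixel_size_um[2], 200)

  expect_error(cohort_design(list()), class = "ramanmark_error_empty_design")
})

test_that("tissue layout masks partition the grid", {
  lay <- tissue_layout(10, 150, n_lamellae = 5)
  total <- lay$intima + lay$media_lamellae + lay$interlamellar +
    lay$adventitia
  expect_true(all(total == 1))
  expect_gte(sum(apply(lay$media_lamellae, 2, any)), 5)
})
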