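test_that("SVD initialization honors the non-negative max-1 gauge", {
  set.seed(1)
  w <- runif(30); h <- runif(40)
  A <- outer(w, h)
  ini <- svd_initialize(A, 1)
  expect_gte(vcos(ini$W0[, 1], w), 1 - 1e-9)   # Perron-Frobenius
  expect_equal(max(ini$W0[, 1]), 1)
  expect_true(all(ini$W0 >= 0) && all(ini$H0 >= 0))

  Af <- matrix(runif(30 * 40), 30, 40)
  full <- svd_initialize(Af, 30)
  expect_true(all(is.finite(full$W0)) && all(is.finite(full$H0)))

  Af[1, 1] <- -1
  expect_error(svd_initialize(Af, 2),
               class = "ramanmark_error_negative_values")
  expect_error(svd_initialize(abs(Af), 31),
               class = "ramanmark_error_k_too_large")
})

test_that("lam = 0 rank-1 factorization is recovered exactly", {
  set.seed(2)
  w <- runif(50); h <- runif(120)
  A <- outer(w, h)
  fit <- fit_mcr_als(A, 1, lam = 0)
  expect_lt(tail(fit$objective_trace, 1), 1e-10 * sum(A^2))
  expect_gte(vcos(fit$W[, 1], w), 0.9999)
  expect_equal(max(fit$W[, 1]), 1)
})

test_that("3-source noiseless mixtures are recovered after matching", {
  ax <- default_axis()
  refs <- reference_library(ax, c("nuclei", "lipid", "versican"))
  set.seed(3)
  H <- matrix(runif(3 * 150), 3, 150)
  A <- refs$spectra %*% H
  fit <- fit_mcr_als(A, 3, lam = 0)
  mt <- match_components(fit$W, refs)
  expect_true(all(mt$matched_cosine >= 0.95))
})

test_that("the objective trace never increases, for any lam", {
  set.seed(4)
  for (rep in 1:10) {
    m <- sample(10:30, 1); n <- sample(10:50, 1); k <- sample(1:4, 1)
    lam <- sample(c(0, 1e-3, 1e-2, 0.1), 1)
    A <- matrix(runif(m * n), m, n)
    fit <- fit_mcr_als(A, k, lam = lam, max_iter = 80)
    tolr <- 1e-10 * (fit$objective_trace[1] + sum(A^2))
    expect_true(all(diff(fit$objective_trace) <= tolr),
                info = sprintf("rep %d lam %g", rep, lam))
    expect_true(all(fit$W >= 0) && all(fit$H >= 0))
    expect_true(all(abs(apply(fit$W, 2, max) - 1) < 1e-12))
  }
})

test_that("sparsity is monotone in lam on fixed data", {
  set.seed(5)
  ax <- default_axis()
  refs <- reference_library(ax, c("nuclei", "lipid", "versican"))
  H <- matrix(runif(3 * 80), 3, 80)
  H[3, sample(80, 80 * 0.7)] <- 0                      # a sparse source
  A <- refs$spectra %*% H + abs(matrix(rnorm(701 * 80, 0, 0.005), 701, 80))
  grid <- c(0, 1e-3, 2e-3, 1e-2)
  fits <- lapply(grid, function(l) fit_mcr_als(A, 3, lam = l,
                                               max_iter = 120))
  l1 <- vapply(fits, function(f) sum(f$H), numeric(1))
  expect_true(all(diff(l1) <= 1e-8 * l1[1]))
  zero_frac <- vapply(fits, function(f) mean(f$H == 0), numeric(1))
  expect_true(all(diff(zero_frac) >= -1e-12))
})

test_that("lam = 0 fits respect and approach the Eckart-Young bound", {
  set.seed(6)
  ax <- default_axis()
  refs <- reference_library(ax, c("nuclei", "lipid", "versican"))
  H <- matrix(runif(3 * 100), 3, 100)
  A <- refs$spectra %*% H + abs(matrix(rnorm(701 * 100, 0, 0.01), 701, 100))
  k <- 3
  fit <- fit_mcr_als(A, k, lam = 0, max_iter = 300)
  resid <- sum((A - fit$W %*% fit$H)^2)
  d <- svd(A, nu = 0, nv = 0)$d
  bound <- sum(d[-(1:k)]^2)
  expect_gte(resid, bound * (1 - 1e-9))
  expect_lt(resid, 1.05 * bound)     # well-separated case: within 5%
})

test_that("an all-zero matrix returns the zero factorization, converged", {
  fit <- fit_mcr_als(matrix(0, 10, 8), 2)
  expect_true(fit$converged)
  expect_true(all(fit$H == 0))
})

test_that("warm starts keep base components and pick up novel sources", {
  ax <- default_axis()
  base <- reference_library(ax, c("nuclei", "lipid"), fixed = FALSE)
  set.seed(7)
  Hb <- matrix(runif(2 * 90), 2, 90)
  A_same <- base$spectra %*% Hb
  fit0 <- warm_start_fit(A_same, base, k_extra = 0, lam = 0)
  expect_true(all(fit0$base_match$matched_cosine >= 0.99))

  novel <- reference_library(ax, "versican")
  Hx <- matrix(runif(90, 0, 0.8), 1, 90)
  A_extra <- A_same + novel$spectra %*% Hx
  fit1 <- warm_start_fit(A_extra, base, k_extra = 1, lam = 0)
  extra_name <- setdiff(fit1$component_names, base$names)
  expect_length(extra_name, 1)
  expect_gte(vcos(fit1$W[, extra_name], novel$spectra[, 1]), 0.95)

  # nested models: refusing the extra component leaves a larger residual
  fit_no <- warm_start_fit(A_extra, base, k_extra = 0, lam = 0)
  resid <- function(f) sum((A_extra - f$W %*% f$H)^2)
  expect_gt(resid(fit_no), resid(fit1))

  short <- component_set(ax[-1], base$spectra[-1, ], base$names)
  expect_error(warm_start_fit(A_extra, short, 0),
               class = "ramanmark_error_axis_mismatch")
})

test_that("element-holdout cross-validation is deterministic and prefers
          a positive penalty for sparse-source data with noise", {
  ax <- seq(400, 1000, 4)
  bands <- function(centers) data.frame(center_cm1 = centers, fwhm_cm1 = 12,
                                        amplitude = 1,
                                        lineshape = "gaussian")
  W <- cbind(render_reference(bands(c(500, 700)), ax)$intensity,
             render_reference(bands(c(600, 900)), ax)$intensity,
             render_reference(bands(800), ax)$intensity)
  set.seed(8)
  n <- 60
  H <- rbind(runif(n, 0.5, 1), runif(n, 0.5, 1), numeric(n))
  H[3, sample(n, 4)] <- 1                       # rare sparse source
  A <- pmax(W %*% H + matrix(rnorm(length(ax) * n, 0, 0.05),
                             length(ax), n), 0)

  one <- cross_validate_lambda(A, 3, lam_grid = 0.002, n_folds = 2, seed = 1)
  expect_equal(one$lambda, 0.002)
  expect_equal(nrow(one$cv_mean), 1)

  # a rank slightly above the dense signal lets lam = 0 overfit the noise,
  # so the held-out error should prefer a positive penalty
  cv_a <- cross_validate_lambda(A, 4, lam_grid = c(0, 2e-3, 1e-2, 5e-2),
                                n_folds = 3, seed = 9)
  cv_b <- cross_validate_lambda(A, 4, lam_grid = c(0, 2e-3, 1e-2, 5e-2),
                                n_folds = 3, seed = 9)
  expect_identical(cv_a$cv_table, cv_b$cv_table)
  expect_gt(cv_a$lambda, 0)
  mse0 <- cv_a$cv_mean$mse[cv_a$cv_mean$lambda == 0]
  expect_gt(mse0, min(cv_a$cv_mean$mse))

  expect_error(cross_validate_lambda(A, 3, numeric(0)),
               class = "ramanmark_error_bad_parameter")
})

test_that("the aneurysm-only collagen signature is recovered from mixed
          maps and stays at the noise floor in controls", {
  design <- cohort_design(list(
    list(name = "control", n_maps = 2),
    list(name = "aneurysm", n_maps = 2, disease_components = "cc6_like")),
    seed = 17, axis = seq(300, 2000, 2))
  sims <- simulate_cohort(design)
  pp <- lapply(sims, function(s) preprocess_map(s$map)$map)
  set.seed(1)
  A <- do.call(cbind, lapply(pp, function(m) {
    m$data[, sample(ncol(m$data), 200)]
  }))
  fit <- fit_mcr_als(A, 8, lam = 0.002, max_iter = 150,
                     names = paste0("C", 1:8))
  probe <- reference_library(pp[[1]]$wavenumber, "cc6_like")
  mt <- match_components(fit$W, probe)
  expect_gte(unname(mt$matched_cosine[1]), 0.9)
  means <- mean_abundance_per_map(fit, rep(c("c1", "c2", "a1", "a2"),
                                           each = 200))
  dm <- means[means$component == paste0("C", mt$assignment[1]), ]
  ctl <- dm$mean_intensity[dm$map_id %in% c("c1", "c2")]
  dis <- dm$mean_intensity[dm$map_id %in% c("a1", "a2")]
  expect_lt(max(ctl), 0.1 * min(dis))   # zero within noise on controls
})

test_that("per-map abundance means are simple, independent averages", {
  H <- rbind(a = c(2, 2, 2, 5, 5, 5), b = c(0, 0, 0, 1, 2, 3))
  res <- list(H = H)
  idx <- rep(c("m1", "m2"), each = 3)
  tab <- mean_abundance_per_map(res, idx)
  expect_equal(tab$mean_intensity[tab$component == "a" & tab$map_id == "m1"],
               2)
  expect_equal(tab$mean_intensity[tab$component == "b" & tab$map_id == "m2"],
               2)
  expect_equal(tab$mean_intensity[tab$component == "b" & tab$map_id == "m1"],
               0)
  # permutation invariance between disjoint maps
  perm <- c(4:6, 1:3)
  tab2 <- mean_abundance_per_map(list(H = H[, perm]), idx[perm])
  expect_equal(tab2[order(tab2$component, tab2$map_id), "mean_intensity"],
               tab[order(tab$component, tab$map_id), "mean_intensity"])
  expect_error(mean_abundance_per_map(res, idx[-1]),
               class = "ramanmark_error_unassigned_pixels")
})

test_that("component matching recovers permutations and ignores nuisance
          columns (vs brute force)", {
  set.seed(11)
  W <- matrix(runif(40 * 4), 40, 4)
  colnames(W) <- paste0("c", 1:4)
  self <- match_components(W, W)
  expect_equal(self$assignment, 1:4)
  expect_equal(unname(self$matched_cosine), rep(1, 4), tolerance = 1e-12)

  perm <- c(3, 1, 4, 2)
  mp <- match_components(W[, perm], W)
  expect_equal(mp$assignment, order(perm))
  expect_equal(unname(mp$matched_cosine), rep(1, 4), tolerance = 1e-12)

  # brute-force oracle over all assignments, k <= 5, with a nuisance column
  brute_best <- function(cosm) {
    perms <- combinat_perms(ncol(cosm))
    best <- -Inf; arg <- NULL
    for (p in perms) {
      v <- sum(cosm[cbind(p, seq_len(ncol(cosm)))])
      if (v > best) { best <- v; arg <- p }
    }
    list(total = best, assignment = arg)
  }
  combinat_perms <- function(k) {
    if (k == 1) return(list(1L))
    # permutations of 1..5 of length k drawn from the available est columns
    idx <- seq_len(5)
    out <- list()
    rec <- function(cur) {
      if (length(cur) == k) { out[[length(out) + 1]] <<- cur; return() }
      for (i in setdiff(idx, cur)) rec(c(cur, i))
    }
    rec(integer(0))
    out
  }
  W_est <- cbind(W, nuisance = runif(40))
  mn <- match_components(W_est, W)
  cosm <- ramanmark:::cosine_matrix(W_est, W)
  bb <- brute_best(cosm)
  expect_equal(sum(mn$matched_cosine), bb$total, tolerance = 1e-12)
  expect_equal(mn$assignment, bb$assignment)
})
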