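# Sparse MCR-ALS: A (m x n, non-negative) ~ W (m x k) H (k x n) minimizing
#   f(W, H) = ||A - W H||_F^2 + lam * sum(H)       (W, H >= 0)
# by alternating exact block coordinate descent. Because H >= 0 the l1 term
# is linear, so the H update has a closed-form soft-threshold-and-clip
# coordinate minimum. The W.H scale indeterminacy (which would let W grow to
# defeat the penalty) is fixed by constraining W to [0, 1] during the
# alternation — an exact coordinate minimization, so the objective trace is
# provably non-increasing — and rescaling columns to max exactly 1 once at
# the end (the rescale factor is <= 1, so it cannot increase the objective
# either).

mcr_objective <- function(A, W, H, lam) {
  sum((A - W %*% H)^2) + lam * sum(H)
}

#' SVD-based initialization for MCR-ALS
#'
#' Takes the top-k singular triplets of `A`, sign-flips each so that its
#' spectral component has positive sum, clips negative entries to zero, and
#' regauges so every W column has maximum 1 (scale pushed into H).
#'
#' @param A Non-negative m x n data matrix (preprocessed spectra in columns).
#' @param k Number of components, `k <= min(m, n)`.
#' @return List `W0` (m x k), `H0` (k x n), both non-negative.
#' @export
svd_initialize <- function(A, k) {
  A <- as.matrix(A)
  check_finite(A, "data matrix")
  if (any(A < 0)) {
    rm_abort("A must be non-negative (preprocess first)", "negative_values")
  }
  if (k < 1 || k > min(dim(A))) {
    rm_abort(sprintf("k must be in [1, %d]", min(dim(A))), "k_too_large")
  }
  sv <- svd(A, nu = k, nv = k)
  W0 <- matrix(0, nrow(A), k)
  H0 <- matrix(0, k, ncol(A))
  for (j in seq_len(k)) {
    u <- sv$u[, j]; v <- sv$v[, j]
    if (sum(u) < 0) { u <- -u; v <- -v }
    w <- pmax(u, 0)
    h <- pmax(sv$d[j] * v, 0)
    mx <- max(w)
    if (mx == 0) { w[] <- .Machine$double.eps; mx <- .Machine$double.eps }
    W0[, j] <- w / mx
    H0[j, ] <- h * mx
  }
  list(W0 = W0, H0 = H0)
}

reseed_dead_columns <- function(A, W, H, reseeded) {
  mx <- apply(W, 2, max)
  dead <- which(mx <= .Machine$double.eps & !reseeded)
  if (length(dead)) {
    R <- A - W %*% H
    sv <- svd(R, nu = 1, nv = 0)
    u <- sv$u[, 1]
    if (sum(u) < 0) u <- -u
    u <- pmax(u, 0)
    if (max(u) > 0) u <- u / max(u)
    for (j in dead) {
      # H row is (near) zero, so replacing the spectrum leaves W H and the
      # objective unchanged; the next sweep decides whether the column lives
      W[, j] <- u
      H[j, ] <- 0
      reseeded[j] <- TRUE
    }
  }
  list(W = W, H = H, reseeded = reseeded)
}

#' Fit sparse MCR-ALS
#'
#' Alternating non-negative updates: H by coordinate descent on the
#' l1-penalized quadratic (soft-threshold, clip at 0), W by box-constrained
#' ([0, 1]) coordinate descent with no penalty. Stops when the relative
#' objective change falls below `tol` or after `max_iter` sweeps. A
#' component whose spectrum dies (all-zero column) is reseeded once from the
#' leading residual SVD direction, then allowed to die.
#'
#' @param A Non-negative m x n matrix (channels x spectra/pixels).
#' @param k Number of components.
#' @param lam l1 penalty on H (the cohort default is 0.002, chosen by
#'   cross-validation; see [cross_validate_lambda()]).
#' @param tol Relative objective tolerance (default 1e-8).
#' @param max_iter Maximum alternating sweeps (default 500).
#' @param init `"svd"` for SVD initialization, or a `component_set` /
#'   m x k matrix of starting spectra (warm start).
#' @param names Optional component names for the result.
#' @return Object of class `mcr_result`: `W` (m x k, columns max-1), `H`
#'   (k x n), `lambda`, `objective_trace` (non-increasing), `converged`,
#'   `n_iter`.
#' @export
fit_mcr_als <- function(A, k, lam = 0.002, tol = 1e-8, max_iter = 500,
                        init = "svd", names = NULL) {
  A <- as.matrix(A)
  check_finite(A, "data matrix")
  if (any(A < 0)) {
    rm_abort("A must be non-negative (preprocess first)", "negative_values")
  }
  if (lam < 0) rm_abort("lam must be >= 0", "bad_parameter")
  m <- nrow(A); n <- ncol(A)
  if (all(A == 0)) {
    W <- matrix(.Machine$double.eps, m, k); H <- matrix(0, k, n)
    return(structure(list(W = W, H = H, lambda = lam,
                          objective_trace = 0, converged = TRUE, n_iter = 0L),
                     class = "mcr_result"))
  }
  if (is.character(init) && identical(init, "svd")) {
    ini <- svd_initialize(A, k)
    W <- ini$W0; H <- ini$H0
  } else {
    if (inherits(init, "component_set")) init <- init$spectra
    W <- as.matrix(init)
    if (nrow(W) != m || ncol(W) != k) {
      rm_abort("init spectra must be an m x k matrix", "bad_parameter")
    }
    mx <- pmax(apply(W, 2, max), .Machine$double.eps)
    W <- sweep(pmax(W, 0), 2, mx, "/")
    H <- nnls_cd(W, A, lam = lam)
  }
  reseeded <- rep(FALSE, k)
  obj <- mcr_objective(A, W, H, lam)
  trace <- obj
  converged <- FALSE
  n_iter <- 0L
  for (it in seq_len(max_iter)) {
    n_iter <- it
    H <- nnls_cd(W, A, lam = lam, H0 = H, max_iter = 50L)
    Wt <- nnls_cd(t(H), t(A), H0 = t(W), box_upper = 1, max_iter = 50L)
    W <- t(Wt)
    rs <- reseed_dead_columns(A, W, H, reseeded)
    W <- rs$W; H <- rs$H; reseeded <- rs$reseeded
    obj_new <- mcr_objective(A, W, H, lam)
    trace <- c(trace, obj_new)
    if (abs(obj - obj_new) <= tol * max(obj, .Machine$double.eps)) {
      converged <- TRUE
      obj <- obj_new
      break
    }
    obj <- obj_new
  }
  # final gauge: columns to max exactly 1 (scales <= 1 under the box
  # constraint, so the l1 term and hence the objective cannot increase)
  mx <- apply(W, 2, max)
  dead <- mx <= .Machine$double.eps
  if (any(dead)) { W[, dead] <- .Machine$double.eps; H[dead, ] <- 0 }
  mx[dead] <- 1
  W <- sweep(W, 2, mx, "/")
  H <- H * mx
  trace <- c(trace, mcr_objective(A, W, H, lam))
  if (!is.null(names)) { colnames(W) <- names; rownames(H) <- names }
  structure(list(W = W, H = H, lambda = lam, objective_trace = trace,
                 converged = converged, n_iter = n_iter),
            class = "mcr_result")
}

#' @export
print.mcr_result <- function(x, ...) {
  cat(sprintf(
    "<mcr_result> k = %d, lambda = %g, %d iterations (%sconverged)\n",
    ncol(x$W), x$lambda, x$n_iter, if (x$converged) "" else "not "))
  cat(sprintf("  objective %.6g -> %.6g, zero fraction of H: %.3f\n",
              x$objective_trace[1], utils::tail(x$objective_trace, 1),
              mean(x$H == 0)))
  invisible(x)
}

masked_mcr_fit <- function(A, mask_hidden, k, lam, n_em = 6, max_iter = 60,
                           tol = 1e-6) {
  # EM-style fit with hidden entries: impute, fit, re-impute
  A_imp <- A
  A_imp[mask_hidden] <- mean(A[!mask_hidden])
  fit <- NULL
  for (e in seq_len(n_em)) {
    fit <- fit_mcr_als(A_imp, k, lam = lam, tol = tol, max_iter = max_iter)
    A_imp[mask_hidden] <- pmax((fit$W %*% fit$H)[mask_hidden], 0)
  }
  fit
}

#' Cross-validate the l1 penalty by element holdout
#'
#' Wold-style cross-validation for factorization models: per fold, a random
#' fraction of matrix entries is hidden, the sparse factorization is fitted
#' on the observed entries (EM-imputed alternating least squares), and the
#' mean squared error on the hidden entries scores the penalty. The chosen
#' penalty is the grid argmin of the mean CV error; ties go to the smaller
#' penalty.
#'
#' @param A Non-negative data matrix.
#' @param k Number of components.
#' @param lam_grid Non-empty penalty grid.
#' @param holdout_fraction Fraction of entries hidden per fold, in (0, 0.5).
#' @param n_folds Number of folds.
#' @param seed Seed for the holdout masks (same seed, same table).
#' @return List: `lambda` (chosen), `cv_table` (data.frame lambda x fold
#'   MSEs), `cv_mean` (mean MSE per lambda).
#' @export
cross_validate_lambda <- function(A, k, lam_grid = c(0, 5e-4, 2e-3, 1e-2),
                                  holdout_fraction = 0.1, n_folds = 5,
                                  seed = 1) {
  if (!length(lam_grid)) rm_abort("lam_grid is empty", "bad_parameter")
  if (holdout_fraction <= 0 || holdout_fraction >= 0.5) {
    rm_abort("holdout_fraction must be in (0, 0.5)", "bad_parameter")
  }
  A <- as.matrix(A)
  n_entries <- length(A)
  rows <- with_seed(seed, {
    lapply(seq_len(n_folds), function(f) {
      hidden <- matrix(FALSE, nrow(A), ncol(A))
      hidden[sample.int(n_entries, round(holdout_fraction * n_entries))] <-
        TRUE
      vapply(lam_grid, function(lam) {
        fit <- masked_mcr_fit(A, hidden, k, lam)
        mean(((A - fit$W %*% fit$H)[hidden])^2)
      }, numeric(1))
    })
  })
  cv <- do.call(rbind, lapply(seq_len(n_folds), function(f) {
    data.frame(fold = f, lambda = lam_grid, mse = rows[[f]])
  }))
  cv_mean <- vapply(lam_grid, function(l) mean(cv$mse[cv$lambda == l]),
                    numeric(1))
  best <- lam_grid[which(cv_mean == min(cv_mean))]
  list(lambda = min(best), cv_table = cv,
       cv_mean = data.frame(lambda = lam_grid, mse = cv_mean))
}

#' Warm-started MCR-ALS from a base component set
#'
#' Transfers components fitted on one cohort to a new cohort: W is
#' initialized with the base spectra plus `k_extra` components taken from the
#' SVD of the initial residual, then all columns refine freely. Output
#' components are mapped back to base names by maximal cosine (Hungarian
#' matching); unmatched ones are the cohort-specific extras.
#'
#' @param A_new Non-negative data matrix of the new cohort.
#' @param base A `component_set` (axis must match) of base spectra.
#' @param k_extra Number of additional free components (>= 0).
#' @param lam,tol,max_iter As in [fit_mcr_als()].
#' @param axis Optional axis of `A_new` rows, checked against `base`.
#' @return `mcr_result` with extra fields `base_match` (result of
#'   [match_components()] vs the base) and `component_names` (base names for
#'   matched columns, `extra_*` otherwise).
#' @export
warm_start_fit <- function(A_new, base, k_extra = 0, lam = 0.002,
                           tol = 1e-8, max_iter = 500, axis = NULL) {
  stopifnot(inherits(base, "component_set"))
  A_new <- as.matrix(A_new)
  if (nrow(A_new) != length(base$wavenumber)) {
    rm_abort("A_new channel count does not match the base axis",
             "axis_mismatch")
  }
  if (!is.null(axis) && !axes_equal(axis, base$wavenumber)) {
    rm_abort("data axis does not match the base axis", "axis_mismatch")
  }
  W0 <- base$spectra
  k_base <- ncol(W0)
  if (k_extra > 0) {
    H0 <- nnls_cd(W0, A_new, lam = lam)
    R <- A_new - W0 %*% H0
    sv <- svd(R, nu = k_extra, nv = 0)
    extras <- vapply(seq_len(k_extra), function(j) {
      u <- sv$u[, j]
      if (sum(u) < 0) u <- -u
      u <- pmax(u, 0)
      if (max(u) > 0) u / max(u) else rep(.Machine$double.eps, length(u))
    }, numeric(nrow(A_new)))
    W0 <- cbind(W0, extras)
  }
  fit <- fit_mcr_als(A_new, k_base + k_extra, lam = lam, tol = tol,
                     max_iter = max_iter, init = W0)
  bm <- match_components(fit$W, base$spectra)
  nm <- rep(NA_character_, ncol(fit$W))
  nm[bm$assignment[!is.na(bm$assignment)]] <-
    base$names[!is.na(bm$assignment)]
  extra_idx <- which(is.na(nm))
  nm[extra_idx] <- paste0("extra_", seq_along(extra_idx))
  colnames(fit$W) <- nm
  rownames(fit$H) <- nm
  fit$base_match <- bm
  fit$component_names <- nm
  fit
}

#' Per-map mean abundance of each component
#'
#' The biomarker readout: the arithmetic mean of each H row over the pixels
#' of each map.
#'
#' @param result An `mcr_result` (or any list with an `H` matrix).
#' @param pixel_to_map_index Vector (length `ncol(H)`) assigning every pixel
#'   to a map id; no NA allowed.
#' @return data.frame with columns `map_id`, `component`, `mean_intensity`.
#' @export
mean_abundance_per_map <- function(result, pixel_to_map_index) {
  H <- result$H
  idx <- pixel_to_map_index
  if (length(idx) != ncol(H) || anyNA(idx)) {
    rm_abort("every pixel must be assigned to exactly one map",
             "unassigned_pixels")
  }
  idx <- as.character(idx)
  comp <- rownames(H) %||% paste0("component_", seq_len(nrow(H)))
  maps <- unique(idx)
  out <- expand.grid(map_id = maps, component = comp,
                     stringsAsFactors = FALSE)
  out$mean_intensity <- mapply(function(mid, cj) {
    mean(H[match(cj, comp), idx == mid])
  }, out$map_id, out$component)
  out[order(out$component, out$map_id), , drop = FALSE]
}
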