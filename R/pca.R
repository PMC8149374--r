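# NIPALS principal-component analysis. NIPALS extracts one PC at a time by
# power iteration with deflation, the standard chemometrics route for
# spectral datasets (it needs no full decomposition and tolerates n_s << m).

#' Fit PCA by the NIPALS algorithm
#'
#' Mean-centered (never variance-scaled: loadings are read as spectral
#' shapes, which unit-variance scaling would distort). Components are
#' extracted by power iteration with deflation; each loading is unit-norm
#' and sign-fixed so its largest-magnitude element is positive.
#'
#' @param dataset A `spectral_dataset` (rows = spectra, normalized upstream).
#' @param k Number of components, `k <= min(n_s - 1, m)`.
#' @param tol Convergence: relative change of the score vector.
#' @param max_iter Power-iteration cap per component.
#' @return Object of class `pca_result`: `scores` (n_s x k), `loadings`
#'   (k x m, unit-norm rows), `explained_variance_fraction`, `mean_spectrum`,
#'   `labels`, `wavenumber`.
#' @export
fit_pca_nipals <- function(dataset, k, tol = 1e-9, max_iter = 500) {
  stopifnot(inherits(dataset, "spectral_dataset"))
  X <- dataset$spectra
  n_s <- nrow(X); m <- ncol(X)
  if (n_s < 2) rm_abort("PCA needs at least 2 spectra", "too_few_spectra")
  if (k > min(n_s - 1, m)) {
    rm_abort(sprintf("k = %d exceeds min(n_s - 1, m) = %d", k,
                     min(n_s - 1, m)), "k_too_large")
  }
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  ss_total <- sum(Xc^2)
  if (ss_total <= .Machine$double.eps * n_s * m) {
    rm_abort("dataset has zero variance", "zero_variance")
  }
  scores <- matrix(0, n_s, k)
  loadings <- matrix(0, k, m)
  ev <- numeric(k)
  E <- Xc
  for (h in seq_len(k)) {
    t_vec <- E[, which.max(colSums(E^2))]
    if (all(t_vec == 0)) {
      rm_abort(sprintf("residual rank exhausted at component %d", h),
               "k_too_large")
    }
    for (it in seq_len(max_iter)) {
      p_vec <- as.vector(crossprod(E, t_vec)) / sum(t_vec^2)
      p_vec <- p_vec / sqrt(sum(p_vec^2))
      t_new <- as.vector(E %*% p_vec)
      if (sqrt(sum((t_new - t_vec)^2)) <= tol * sqrt(sum(t_new^2))) {
        t_vec <- t_new
        break
      }
      t_vec <- t_new
    }
    # sign convention: largest-magnitude loading element positive
    sgn <- sign(p_vec[which.max(abs(p_vec))])
    if (sgn < 0) { p_vec <- -p_vec; t_vec <- -t_vec }
    scores[, h] <- t_vec
    loadings[h, ] <- p_vec
    ev[h] <- sum(t_vec^2) / ss_total
    E <- E - tcrossprod(t_vec, p_vec)
  }
  structure(list(n_components = k, scores = scores, loadings = loadings,
                 explained_variance_fraction = ev, mean_spectrum = mu,
                 labels = dataset$labels, wavenumber = dataset$wavenumber),
            class = "pca_result")
}

#' Per-animal mean scores for one PC
#'
#' Spectra are pseudo-replicates within an animal; the unit of inference is
#' the animal, so scores are averaged per animal before statistics.
#'
#' @param pca A `pca_result` whose labels carry `animal_id` (and `group`).
#' @param pc_index Which PC (1-based).
#' @return data.frame with columns `animal_id`, `group`, `mean_score`, one
#'   row per animal.
#' @export
animal_mean_scores <- function(pca, pc_index) {
  stopifnot(inherits(pca, "pca_result"))
  if (pc_index < 1 || pc_index > pca$n_components) {
    rm_abort("pc_index out of range", "bad_parameter")
  }
  lb <- pca$labels
  if (is.null(lb$animal_id) || any(lb$animal_id == "n/a")) {
    rm_abort("labels must carry animal_id for per-animal aggregation",
             "bad_labels")
  }
  sc <- pca$scores[, pc_index]
  agg <- stats::aggregate(sc, by = list(animal_id = lb$animal_id,
                                        group = lb$group), FUN = mean)
  names(agg)[3] <- "mean_score"
  agg[order(agg$group, agg$animal_id), , drop = FALSE]
}

#' Project new spectra onto a fitted PCA
#'
#' Centers by the training mean and projects on the loadings.
#'
#' @param pca A `pca_result`.
#' @param dataset A `spectral_dataset` on the training axis.
#' @return n_s x k score matrix.
#' @export
pca_project <- function(pca, dataset) {
  stopifnot(inherits(pca, "pca_result"), inherits(dataset, "spectral_dataset"))
  if (!axes_equal(pca$wavenumber, dataset$wavenumber)) {
    rm_abort("dataset axis does not match the PCA training axis",
             "axis_mismatch")
  }
  sweep(dataset$spectra, 2, pca$mean_spectrum) %*% t(pca$loadings)
}
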