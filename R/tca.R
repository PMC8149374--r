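# Reference-seeded non-negative unmixing ("true component analysis" style):
# abundances solve a per-pixel non-negative least squares against a library
# of reference spectra; optional free components are refined by alternating
# non-negative updates. Produces abundance heatmaps and ROI spectral
# datasets for downstream PCA/MCR.

#' Fit reference-seeded non-negative unmixing
#'
#' With all components fixed the fit is pixel-separable NNLS of every pixel
#' spectrum against the reference spectra. `n_free > 0` adds free components
#' (random non-negative initialization) refined by alternating non-negative
#' least squares while the fixed references stay bit-frozen.
#'
#' @param map A `raman_map` (preprocessed).
#' @param references A `component_set` on the same axis.
#' @param n_free Number of additional free components (>= 0).
#' @param tol Relative tolerance on the residual norm between sweeps.
#' @param max_iter Maximum alternating sweeps (only used when `n_free > 0`).
#' @param seed Seed for the free-component initialization.
#' @return Object of class `tca_result`: `components` (`component_set`,
#'   fixed ones unchanged), `abundances` (`abundance_stack`),
#'   `residual_norm` (`||A - WH||_F`), `residual_trace`.
#' @export
fit_tca <- function(map, references, n_free = 0, tol = 1e-6,
                    max_iter = 200, seed = 1) {
  stopifnot(inherits(map, "raman_map"), inherits(references, "component_set"))
  if (!axes_equal(map$wavenumber, references$wavenumber)) {
    rm_abort("map and reference axes differ", "axis_mismatch")
  }
  A <- map$data
  m <- nrow(A); n <- ncol(A)
  k_fixed <- length(references$names)
  n_free <- as.integer(n_free)
  k <- k_fixed + n_free
  if (k > min(m, n)) {
    rm_abort(sprintf("k = %d exceeds min(channels, pixels) = %d", k,
                     min(m, n)), "k_too_large")
  }

  names_all <- references$names
  fixed <- references$fixed
  W <- references$spectra
  if (n_free > 0) {
    Wf <- with_seed(seed, matrix(stats::runif(m * n_free), m, n_free))
    Wf <- sweep(Wf, 2, apply(Wf, 2, max), "/")
    W <- cbind(W, Wf)
    names_all <- c(names_all, paste0("free_", seq_len(n_free)))
    fixed <- c(fixed, rep(FALSE, n_free))
  }
  free_cols <- !fixed

  H <- nnls_cd(W, A)
  res <- norm(A - W %*% H, "F")
  trace <- res
  if (any(free_cols)) {
    for (it in seq_len(max_iter)) {
      # refine free spectra given H (transposed NNLS), references frozen
      Wt <- nnls_cd(t(H), t(A), H0 = t(W), free = free_cols)
      W <- t(Wt)
      # regauge free columns to max 1 (leaves W %*% H unchanged in effect
      # after the H refit below; residual trace is measured after both)
      mx <- apply(W[, free_cols, drop = FALSE], 2, max)
      mx[mx == 0] <- 1
      W[, free_cols] <- sweep(W[, free_cols, drop = FALSE], 2, mx, "/")
      H[free_cols, ] <- H[free_cols, , drop = FALSE] * mx
      H <- nnls_cd(W, A, H0 = H)
      res_new <- norm(A - W %*% H, "F")
      trace <- c(trace, res_new)
      if (abs(res - res_new) <= tol * max(res, .Machine$double.eps)) {
        res <- res_new
        break
      }
      res <- res_new
    }
  }
  # regauge to the max-1 convention; dead (all-zero) free components get a
  # flat placeholder spectrum and zero abundance
  mx <- apply(W, 2, max)
  dead <- mx == 0
  if (any(dead)) {
    W[, dead] <- .Machine$double.eps
    H[dead, ] <- 0
    mx[dead] <- 1
  }
  comps <- component_set(map$wavenumber, W, names_all, fixed)
  H <- H * mx
  rownames(H) <- names_all
  structure(list(components = comps,
                 abundances = stack_from_h(H, map$n_rows, map$n_cols),
                 residual_norm = res, residual_trace = trace),
            class = "tca_result")
}

#' Extract ROI spectra selected by a component heatmap
#'
#' Returns the pixel spectra whose abundance for `component_name` is at or
#' above the `q` quantile of that heatmap's positive values (ties at the
#' boundary included). Labels are inherited from the map metadata.
#'
#' @param map The `raman_map` the unmixing was fitted on.
#' @param tca A `tca_result` from [fit_tca()].
#' @param component_name Component to threshold on.
#' @param q Quantile in (0, 1); default 0.9 keeps the top decile.
#' @return A `spectral_dataset` with one row per selected pixel and a
#'   `pixel` column in the labels giving the linear pixel index.
#' @export
extract_roi_spectra <- function(map, tca, component_name, q = 0.9) {
  stopifnot(inherits(tca, "tca_result"))
  if (q <= 0 || q >= 1) rm_abort("q must be in (0, 1)", "bad_parameter")
  if (!component_name %in% tca$abundances$names) {
    rm_abort(sprintf("component '%s' not in the fit", component_name),
             "unknown_component")
  }
  H <- stack_to_h(tca$abundances)
  h <- H[component_name, ]
  pos <- h[h > 0]
  if (!length(pos)) {
    rm_abort(sprintf("heatmap for '%s' is all zero: empty ROI",
                     component_name), "empty_roi")
  }
  thr <- stats::quantile(pos, q, names = FALSE)
  sel <- which(h >= thr)
  labels <- data.frame(group = map$meta$group, region = map$meta$region,
                       species = map$meta$species,
                       animal_id = map$meta$animal_id,
                       component = component_name, pixel = sel,
                       stringsAsFactors = FALSE)
  spectral_dataset(map$wavenumber, t(map$data[, sel, drop = FALSE]), labels)
}
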