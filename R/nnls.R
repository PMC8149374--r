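# Shared non-negative least squares machinery. All abundance and spectral
# updates in TCA and MCR-ALS reduce to the box-constrained, optionally
# l1-penalized quadratic
#   min_{L <= H <= U}  ||A - W H||_F^2 + lam * sum(H)
# solved by cyclic coordinate descent. Each coordinate update is an exact
# scalar minimization (soft-threshold then clip), so the objective never
# increases; updates for one component are vectorized over all columns.

#' Penalized non-negative least squares by coordinate descent
#'
#' Solves `min ||A - W H||_F^2 + lam * sum(H)` subject to
#' `0 <= H <= box_upper`, jointly for all columns of `A`.
#'
#' @param W m x k design (component spectra).
#' @param A m x n right-hand sides.
#' @param lam l1 penalty on H (>= 0; H >= 0 makes |H| linear).
#' @param H0 Optional k x n warm start.
#' @param box_upper Upper bound on entries of H (default `Inf`).
#' @param tol Relative convergence tolerance on coordinate updates.
#' @param max_iter Maximum coordinate sweeps.
#' @param free Optional logical length k; only these rows of H are updated
#'   (the rest are held at their `H0` values).
#' @return k x n solution matrix.
#' @export
nnls_cd <- function(W, A, lam = 0, H0 = NULL, box_upper = Inf,
                    tol = 1e-10, max_iter = 1000L, free = NULL) {
  W <- as.matrix(W); A <- as.matrix(A)
  k <- ncol(W); n <- ncol(A)
  if (nrow(W) != nrow(A)) rm_abort("W and A channel counts differ",
                                   "channel_mismatch")
  G <- crossprod(W)              # k x k Gram
  WtA <- crossprod(W, A)         # k x n
  H <- if (is.null(H0)) matrix(0, k, n) else as.matrix(H0)
  if (is.null(free)) free <- rep(TRUE, k)
  scale_ref <- max(abs(WtA), 1)
  for (it in seq_len(max_iter)) {
    delta <- 0
    for (j in which(free)) {
      gjj <- G[j, j]
      if (gjj <= 0) { H[j, ] <- 0; next }
      # gradient of the quadratic wrt H[j,] is -2(WtA - G H); exact
      # coordinate minimum after soft-thresholding by lam/2
      hj <- H[j, ] + (WtA[j, ] - as.vector(G[j, ] %*% H) - lam / 2) / gjj
      hj <- pmin(pmax(hj, 0), box_upper)
      delta <- max(delta, max(abs(hj - H[j, ])))
      H[j, ] <- hj
    }
    if (delta <= tol * scale_ref) break
  }
  H
}

cosine_sim <- function(a, b) {
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) return(0)
  sum(a * b) / (na * nb)
}

cosine_matrix <- function(A, B) {
  # columns of A vs columns of B
  An <- sweep(A, 2, pmax(sqrt(colSums(A^2)), .Machine$double.eps), "/")
  Bn <- sweep(B, 2, pmax(sqrt(colSums(B^2)), .Machine$double.eps), "/")
  crossprod(An, Bn)
}
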