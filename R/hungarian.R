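# Optimal one-to-one assignment (Hungarian algorithm, potentials + shortest
# augmenting path, O(n^3)). Used to name fitted components after reference
# spectra by maximal total cosine similarity.

hungarian_min <- function(cost) {
  n <- nrow(cost); m <- ncol(cost)
  stopifnot(n <= m, all(is.finite(cost)))
  u <- numeric(n)            # row potentials
  v <- numeric(m + 1)        # column potentials (m+1 = virtual column)
  p <- integer(m + 1)        # p[j] = row assigned to column j, 0 = none
  way <- integer(m + 1)
  for (i in seq_len(n)) {
    p[m + 1] <- i
    j0 <- m + 1L
    minv <- rep(Inf, m)
    used <- rep(FALSE, m + 1)
    repeat {
      used[j0] <- TRUE
      i0 <- p[j0]
      delta <- Inf; j1 <- 0L
      for (j in seq_len(m)) {
        if (!used[j]) {
          cur <- cost[i0, j] - u[i0] - v[j]
          if (cur < minv[j]) { minv[j] <- cur; way[j] <- j0 }
          if (minv[j] < delta) { delta <- minv[j]; j1 <- j }
        }
      }
      for (j in seq_len(m + 1)) {
        if (used[j]) {
          if (p[j] > 0) u[p[j]] <- u[p[j]] + delta
          v[j] <- v[j] - delta
        } else if (j <= m) {
          minv[j] <- minv[j] - delta
        }
      }
      j0 <- j1
      if (p[j0] == 0L) break
    }
    repeat {
      j1 <- way[j0]
      p[j0] <- p[j1]
      j0 <- j1
      if (j0 == m + 1L) break
    }
  }
  assignment <- integer(n)
  for (j in seq_len(m)) if (p[j] > 0) assignment[p[j]] <- j
  assignment
}

#' Match estimated components to reference components
#'
#' Finds the one-to-one assignment between columns of `W_est` and columns of
#' `W_ref` that maximizes total cosine similarity (Hungarian algorithm). When
#' the two sets differ in size, the smaller side is fully matched.
#'
#' @param W_est m x k_est matrix (or `component_set`) of fitted spectra.
#' @param W_ref m x k_ref matrix (or `component_set`) of reference spectra.
#' @return List: `assignment` — integer vector over reference columns giving
#'   the matched estimated column (NA if unmatched); `cosine` — full
#'   k_est x k_ref cosine table; `matched_cosine` — cosine of each matched
#'   pair, named by reference component where names exist.
#' @export
match_components <- function(W_est, W_ref) {
  if (inherits(W_est, "component_set")) W_est <- W_est$spectra
  if (inherits(W_ref, "component_set")) W_ref <- W_ref$spectra
  W_est <- as.matrix(W_est); W_ref <- as.matrix(W_ref)
  if (nrow(W_est) != nrow(W_ref)) {
    rm_abort("component matrices have different channel counts",
             "channel_mismatch")
  }
  cosm <- cosine_matrix(W_est, W_ref)      # k_est x k_ref
  ke <- ncol(W_est); kr <- ncol(W_ref)
  assignment <- rep(NA_integer_, kr)
  if (ke >= kr) {
    # assign each reference (rows of cost) an estimated column
    a <- hungarian_min(t(-cosm))           # kr x ke cost
    assignment <- a
  } else {
    # fewer estimates than references: assign each estimate a reference
    a <- hungarian_min(-cosm)              # ke x kr cost
    assignment[a] <- seq_len(ke)
  }
  matched <- ifelse(is.na(assignment), NA_real_,
                    cosm[cbind(assignment, seq_len(kr))])
  names(matched) <- colnames(W_ref)
  list(assignment = assignment, cosine = cosm, matched_cosine = matched)
}
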