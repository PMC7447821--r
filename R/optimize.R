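#' Constrained rank-1 factorization of a cluster's B matrix
#'
#' Solves \deqn{\min \|\phi \otimes \delta - B\|_F,\quad 0 \le \phi_s \le 1,
#' \ 0 \le \delta_m \le CN} for a cluster of mutations assumed to share one
#' per-biopsy frequency vector \eqn{\phi} while each mutation keeps its own
#' biopsy-constant mutant-allele copy number \eqn{\delta_m}. The solver is
#' projected (box-clamped) alternating least squares -- each block update is
#' the exact constrained minimizer, so the objective is non-increasing --
#' with multiple restarts to escape local optima. The first restart starts
#' from unit copy numbers and `anchor_phi`; later restarts draw
#' \eqn{\phi} uniformly. The factorization is scale-ambiguous
#' (\eqn{(c\phi, \delta/c)} ties); among restarts tied on residual the
#' solution whose \eqn{\phi} is closest to `anchor_phi` is kept.
#'
#' @param B Numeric matrix, biopsies x mutations, non-negative and finite.
#' @param cn_max Copy-number upper bound (default 15).
#' @param n_restarts Number of random restarts (default 10).
#' @param tol Convergence tolerance on the objective (default 1e-8); also the
#'   residual-tie tolerance between restarts.
#' @param max_iter Maximum alternating iterations per restart (default 500).
#' @param anchor_phi Per-biopsy anchor for initialization and tie-breaking;
#'   defaults to the row-wise medians of `B` clamped to `[0, 1]` (the
#'   first-approximation scale, since copy numbers start at 1).
#' @param seed Optional seed for the random restarts.
#' @return List with `phi` (length = biopsies), `delta` (length = mutations),
#'   `residual` (Frobenius norm at the optimum) and `restarts` (per-restart
#'   residuals).
#' @examples
#' B <- outer(c(0.5, 0.25), c(1, 2))
#' optimize_rank1(B, seed = 1)$residual # ~0
#' @export
optimize_rank1 <- function(B, cn_max = 15, n_restarts = 10, tol = 1e-8,
                           max_iter = 500, anchor_phi = NULL, seed = NULL) {
  B <- as.matrix(B)
  check_that(length(B) > 0 && all(is.finite(B)) && all(B >= 0),
             "B must be non-empty, finite and non-negative")
  nS <- nrow(B); nM <- ncol(B)
  if (is.null(anchor_phi)) {
    anchor_phi <- clamp(apply(B, 1, median), 0, 1)
  }
  check_that(length(anchor_phi) == nS, "anchor_phi length must match nrow(B)")

  als <- function(phi0) {
    phi <- phi0
    delta <- rep(1, nM)
    obj <- function(phi, delta) sqrt(sum((outer(phi, delta) - B)^2))
    prev <- obj(phi, delta)
    for (it in seq_len(max_iter)) {
      ss <- sum(phi^2)
      delta <- if (ss > 0) clamp(colSums(B * phi) / ss, 0, cn_max) else
        rep(0, nM)
      sd2 <- sum(delta^2)
      phi <- if (sd2 > 0) clamp(as.vector(B %*% delta) / sd2, 0, 1) else phi
      cur <- obj(phi, delta)
      if (prev - cur < tol) { prev <- cur; break }
      prev <- cur
    }
    list(phi = phi, delta = delta, residual = prev)
  }

  with_seed_if(seed, {
    inits <- c(list(anchor_phi),
               lapply(seq_len(max(0, n_restarts - 1)),
                      function(i) runif(nS)))
    fits <- lapply(inits, als)
    res <- vapply(fits, `[[`, numeric(1), "residual")
    tied <- which(res <= min(res) + tol)
    anchor_dist <- vapply(fits[tied],
                          function(f) sqrt(sum((f$phi - anchor_phi)^2)),
                          numeric(1))
    best <- fits[[tied[which.min(anchor_dist)]]]
    best$restarts <- res
    best
  })
}

#' Build the B matrix for a set of mutations
#'
#' `B[s, m] = f * c_obs / purity` ([b_entry()]) over the given mutations and
#' all biopsies of the dataset; on noiseless data this equals
#' \eqn{\phi_m^s \delta_m} entrywise.
#'
#' @param dataset A [tumor_dataset()].
#' @param mutation_ids Mutations to include (columns), default all.
#' @return Matrix, biopsies x mutations, with dimnames.
#' @export
build_b_matrix <- function(dataset, mutation_ids = dataset$mutations) {
  obs <- obs_with_purity(dataset) %>%
    filter(.data$mutation_id %in% mutation_ids)
  f <- read_fraction(obs$alt_reads, obs$ref_reads,
                     id = paste0(obs$mutation_id, "@", obs$biopsy_id))
  b <- b_entry(f, obs$c_obs, obs$purity)
  m <- matrix(NA_real_, length(dataset$biopsies), length(mutation_ids),
              dimnames = list(dataset$biopsies, mutation_ids))
  m[cbind(obs$biopsy_id, obs$mutation_id)] <- b
  m
}
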