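# Shared fixtures and independent oracles, built in code at test time.

# A tiny hand-built dataset: `rows` is a data frame with mutation_id,
# biopsy_id, alt_reads, ref_reads, c_obs; purity defaults to 1 everywhere.
make_dataset <- function(rows, purity = NULL, tumor_id = "toy") {
  if (is.null(purity)) {
    purity <- tibble::tibble(biopsy_id = unique(rows$biopsy_id), purity = 1)
  }
  tumor_dataset(rows, purity, tumor_id = tumor_id)
}

# Independent oracle for the box-constrained rank-1 problem: dense grid over
# phi in [0,1]^S at `step`, with the optimal delta profiled out in closed
# form per column (for fixed phi the unconstrained minimizer is
# sum(phi*B)/sum(phi^2), clamped to the box, and the objective is separable
# in delta). Vectorized over the whole phi grid; returns the minimal
# Frobenius residual.
grid_rank1_residual <- function(B, cn_max = 15, step = 0.01) {
  S <- nrow(B)
  g <- seq(0, 1, by = step)
  P <- as.matrix(expand.grid(rep(list(g), S)))  # N x S
  ss <- rowSums(P^2)
  numer <- P %*% B                              # N x M  (phi' B)
  D <- pmin(pmax(numer / ifelse(ss > 0, ss, 1), 0), cn_max)
  D[ss == 0, ] <- 0
  # ||phi delta' - B||^2 = ||phi||^2 ||delta||^2 - 2 delta'(B'phi) + ||B||^2
  res2 <- ss * rowSums(D^2) - 2 * rowSums(D * numer) + sum(B^2)
  sqrt(max(0, min(res2)))
}

# Closed-form moments of the truncated normal on [lo, hi] (oracle for the
# simulator's copy-number draws).
trunc_norm_var <- function(mu, sigma, lo, hi) {
  a <- (lo - mu) / sigma; b <- (hi - mu) / sigma
  Z <- pnorm(b) - pnorm(a)
  sigma^2 * (1 + (a * dnorm(a) - b * dnorm(b)) / Z -
               ((dnorm(a) - dnorm(b)) / Z)^2)
}

# Truth subclone-frequency matrix of a simulated tumor (one row per
# subclone: the mass of its subtree in each biopsy).
truth_subclone_phi <- function(sim) {
  t(sapply(sim$phylogeny$subclones, function(s) {
    sub <- clonefreq:::subtree_of(sim$phylogeny, s)
    colSums(sim$composition[sub, , drop = FALSE])
  }))
}

pair_key <- function(p) paste(p$ancestor, p$descendant)
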