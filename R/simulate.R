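#' Sample a random subclone phylogeny
#'
#' Draws a rooted tree over `n_subclones` subclones (node 1 is the tumor-
#' initiating clone) by assigning each subclone `k > 1` a parent uniformly
#' among subclones `1..k-1`, and gives every subclone a disjoint set of
#' novel mutations. A subclone's mutation burden is the union of the novel
#' mutations along its root path (infinite-sites inheritance).
#'
#' @param n_subclones Number of subclones, between 3 and 12.
#' @param mutations_per_subclone Integer range `c(lo, hi)` from which each
#'   subclone's novel-mutation count is drawn uniformly (default 20--50).
#' @param seed Optional integer seed.
#' @return A `phylogeny`: list with `subclones` (ids), `parent` (named
#'   vector, `NA` for the root), and `mutations` tibble
#'   (`mutation_id`, `subclone`) giving each mutation's originating subclone.
#' @examples
#' ph <- sim_phylogeny(4, c(20, 20), seed = 1)
#' nrow(ph$mutations) # 80
#' @export
sim_phylogeny <- function(n_subclones, mutations_per_subclone = c(20L, 50L),
                          seed = NULL) {
  check_that(length(n_subclones) == 1 && n_subclones >= 3 && n_subclones <= 12,
             "n_subclones must be between 3 and 12",
             class = "clonefreq_range_error")
  rng <- range(mutations_per_subclone)
  check_that(rng[1] >= 20 && rng[2] <= 50,
             "mutations_per_subclone must lie within [20, 50]",
             class = "clonefreq_range_error")
  with_seed_if(seed, {
    n <- as.integer(n_subclones)
    parent <- c(NA_integer_,
                vapply(2:n, function(k) sample.int(k - 1L, 1L), integer(1)))
    ids <- paste0("S", seq_len(n))
    n_mut <- if (rng[1] == rng[2]) rep(rng[1], n) else
      sample(seq(rng[1], rng[2]), n, replace = TRUE)
    muts <- tibble(
      mutation_id = sprintf("M%04d", seq_len(sum(n_mut))),
      subclone = rep(ids, n_mut)
    )
    structure(list(subclones = ids,
                   parent = setNames(ifelse(is.na(parent), NA, ids[parent]), ids),
                   mutations = muts),
              class = "phylogeny")
  })
}

# subclone ids in the subtree rooted at `node` (descendants incl. itself)
subtree_of <- function(phylo, node) {
  kids <- names(phylo$parent)[!is.na(phylo$parent) & phylo$parent == node]
  c(node, unlist(lapply(kids, subtree_of, phylo = phylo), use.names = FALSE))
}

# ordered (ancestor, descendant) subclone pairs of a phylogeny
phylo_ancestor_pairs <- function(phylo) {
  out <- list()
  for (s in phylo$subclones) {
    desc <- setdiff(subtree_of(phylo, s), s)
    if (length(desc)) out[[s]] <- tibble(ancestor = s, descendant = desc)
  }
  if (length(out) == 0) return(tibble(ancestor = character(), descendant = character()))
  bind_rows(out)
}

#' Sample a cellular composition matrix for a simulated tumor
#'
#' Each biopsy (column) is a mixture of the tumor subclones plus a wild-type
#' (non-tumor) compartment. The wild-type proportion is uniform on
#' `[0, wt_max]`; the remaining mass is split over subclones by a symmetric
#' Dirichlet(1). Columns sum to 1 exactly and are pairwise distinct.
#'
#' @param phylogeny A [sim_phylogeny()] result.
#' @param n_biopsies Number of biopsies (>= 2).
#' @param wt_max Maximum wild-type contamination (default 0.10).
#' @param seed Optional integer seed.
#' @return Matrix of cell fractions, rows = subclones plus `"WT"`, columns =
#'   biopsy ids `B1..Bn`.
#' @export
sim_composition <- function(phylogeny, n_biopsies, wt_max = 0.10, seed = NULL) {
  check_that(n_biopsies >= 2, "at least two biopsies are required",
             class = "clonefreq_range_error")
  check_that(wt_max >= 0 && wt_max <= 1, "wt_max must lie in [0, 1]")
  with_seed_if(seed, {
    k <- length(phylogeny$subclones)
    draw_col <- function() {
      wt <- runif(1, 0, wt_max)
      w <- stats::rexp(k)        # Dirichlet(1) via normalized exponentials
      c((1 - wt) * w / sum(w), wt)
    }
    repeat {
      rho <- vapply(seq_len(n_biopsies), function(i) draw_col(),
                    numeric(k + 1))
      if (!anyDuplicated(t(round(rho, 12)))) break
    }
    dimnames(rho) <- list(c(phylogeny$subclones, "WT"),
                          paste0("B", seq_len(n_biopsies)))
    rho
  })
}

#' Draw from a truncated normal distribution
#'
#' Inverse-CDF sampler on `[lo, hi]`; `sigma = 0` returns the (in-range)
#' mean exactly. Used for per-allele copy numbers.
#'
#' @param n Number of draws.
#' @param mu,sigma Mean and sd of the parent normal.
#' @param lo,hi Truncation bounds.
#' @return Numeric vector of length `n` in `[lo, hi]`.
#' @export
rtrunc_norm <- function(n, mu, sigma, lo = 0, hi = 15) {
  if (sigma == 0) {
    check_that(mu >= lo && mu <= hi, "degenerate mean outside bounds")
    return(rep(mu, n))
  }
  plo <- pnorm((lo - mu) / sigma)
  phi <- pnorm((hi - mu) / sigma)
  mu + sigma * qnorm(runif(n, plo, phi))
}

# closed-form mean of the truncated normal on [lo, hi] (test oracle lives in
# the test suite; this is exported for users sizing simulations)
#' Mean of a truncated normal distribution
#' @inheritParams rtrunc_norm
#' @return The mean of the truncated distribution.
#' @export
trunc_norm_mean <- function(mu, sigma, lo = 0, hi = 15) {
  if (sigma == 0) return(mu)
  a <- (lo - mu) / sigma
  b <- (hi - mu) / sigma
  mu + sigma * (dnorm(a) - dnorm(b)) / (pnorm(b) - pnorm(a))
}

#' Sample per-(mutation, biopsy) copy-number trios
#'
#' Each mutation in each biopsy gets an independent trio
#' (`delta`, `delta_w`, `delta_m`): per-allele copy numbers of the reference
#' allele in unmutated cells and of the wild-type and mutant alleles in
#' mutated cells. All three are i.i.d. truncated-normal(`mu`, `sigma`) on
#' `[0, cn_max]`; no linkage across mutations or biopsies. `mu = 1` is the
#' no-change regime; `sigma = 0` is only valid with `mu = 1` (a perfectly
#' stable diploid genome).
#'
#' @param mutation_ids,biopsy_ids Character vectors of ids.
#' @param mu Trio mean, one of 1, 2, 3.
#' @param sigma Trio sd, one of 0, 1, 2, 3 (`0` only with `mu = 1`).
#' @param cn_max Upper copy-number bound (default 15).
#' @param seed Optional integer seed.
#' @return Tibble (`mutation_id`, `biopsy_id`, `delta`, `delta_w`, `delta_m`).
#' @export
sim_trios <- function(mutation_ids, biopsy_ids, mu = 1, sigma = 0,
                      cn_max = 15, seed = NULL) {
  check_that(mu %in% c(1, 2, 3) && sigma %in% c(0, 1, 2, 3),
             "mu must be in {1,2,3} and sigma in {0,1,2,3}",
             class = "clonefreq_range_error")
  check_that(!(sigma == 0 && mu != 1),
             "sigma = 0 is only valid with mu = 1",
             class = "clonefreq_range_error")
  with_seed_if(seed, {
    grid <- tidyr::expand_grid(mutation_id = mutation_ids,
                               biopsy_id = biopsy_ids)
    n <- nrow(grid)
    grid %>% mutate(
      delta   = rtrunc_norm(n, mu, sigma, 0, cn_max),
      delta_w = rtrunc_norm(n, mu, sigma, 0, cn_max),
      delta_m = rtrunc_norm(n, mu, sigma, 0, cn_max)
    )
  })
}

# true mutation frequencies: phi[m, s] = sum of rho over subclones whose
# burden contains m = mass of the subtree rooted at the originating subclone
true_phi_matrix <- function(phylogeny, composition) {
  rho <- composition[phylogeny$subclones, , drop = FALSE]
  subtree_mass <- t(vapply(
    phylogeny$subclones,
    function(s) colSums(rho[subtree_of(phylogeny, s), , drop = FALSE]),
    numeric(ncol(rho))
  ))
  phi <- subtree_mass[phylogeny$mutations$subclone, , drop = FALSE]
  rownames(phi) <- phylogeny$mutations$mutation_id
  phi
}

#' Simulate sequencing read counts for a ground-truthed tumor
#'
#' For each (mutation, biopsy): total coverage `N` is drawn from the coverage
#' model; the idealized mutated-read count is `round(N * f)` with `f` from
#' [expected_read_fraction()] at the true frequency, the locus trio, and the
#' biopsy's tumor fraction; both counts are then independently perturbed by
#' a multiplicative factor uniform on `[1-u, 1+u]` with
#' `u ~ Uniform(0, dup_loss_max)`, emulating mild duplication/loss of
#' observations.
#'
#' @param phi True frequency matrix (mutations x biopsies).
#' @param trios Trio tibble from [sim_trios()].
#' @param purity Named per-biopsy purity vector (tumor fraction, `1 - WT`).
#' @param coverage_fn Function `n -> integer vector` of total coverages;
#'   default negative binomial (mean 120, dispersion 5) floored at 20,
#'   heavy-tailed like real exome coverage.
#' @param dup_loss_max Maximum relative duplication/loss of counts
#'   (default 0.05).
#' @param tumor_id Dataset label.
#' @param seed Optional integer seed.
#' @return A [tumor_dataset()].
#' @export
sim_reads <- function(phi, trios, purity,
                      coverage_fn = coverage_negbin(),
                      dup_loss_max = 0.05, tumor_id = "sim", seed = NULL) {
  check_that(dup_loss_max >= 0 && dup_loss_max <= 1,
             "dup_loss_max must lie in [0, 1]")
  with_seed_if(seed, {
    long <- trios %>%
      mutate(phi = phi[cbind(.data$mutation_id, .data$biopsy_id)],
             p = purity[.data$biopsy_id])
    n <- nrow(long)
    f_star <- expected_read_fraction(long$phi, long$delta, long$delta_w,
                                     long$delta_m, long$p)
    N <- coverage_fn(n)
    alt <- round(N * f_star)
    ref <- N - alt
    if (dup_loss_max > 0) {
      u_a <- runif(n, 0, dup_loss_max)
      u_r <- runif(n, 0, dup_loss_max)
      alt <- pmax(0, round(alt * runif(n, 1 - u_a, 1 + u_a)))
      ref <- pmax(0, round(ref * runif(n, 1 - u_r, 1 + u_r)))
    }
    C_tumor <- expected_total_copy_number(long$phi, long$delta, long$delta_w,
                                          long$delta_m)
    obs <- tibble(
      mutation_id = long$mutation_id,
      biopsy_id = long$biopsy_id,
      alt_reads = as.integer(alt),
      ref_reads = as.integer(ref),
      c_obs = unname(observed_copy_number(C_tumor, long$p))
    )
    pur <- tibble(biopsy_id = names(purity), purity = unname(purity))
    tumor_dataset(obs, pur, tumor_id = tumor_id)
  })
}

#' Negative-binomial coverage model
#'
#' @param mean_cov Mean total coverage (default 120).
#' @param dispersion Negative-binomial size parameter (default 5).
#' @param floor Minimum coverage (default 20).
#' @return A function `n -> integer coverages`.
#' @export
coverage_negbin <- function(mean_cov = 120, dispersion = 5, floor = 20) {
  function(n) pmax(floor, rnbinom(n, mu = mean_cov, size = dispersion))
}

#' Simulate one ground-truthed multi-biopsy tumor
#'
#' Full generative pipeline: random phylogeny, cellular composition with
#' wild-type contamination, independent copy-number trios, and read counts,
#' bundled with every piece of ground truth needed for evaluation.
#'
#' @inheritParams sim_phylogeny
#' @inheritParams sim_composition
#' @inheritParams sim_trios
#' @inheritParams sim_reads
#' @param n_biopsies Number of biopsies (default 6).
#' @param coverage_fn Coverage model, see [sim_reads()].
#' @return A `sim_tumor`: list with `phylogeny`, `composition`, `trios`,
#'   `phi` (true frequencies), `dataset` (the emitted [tumor_dataset()]) and
#'   the generating parameters in `$params`.
#' @examples
#' st <- sim_tumor(n_subclones = 4, n_biopsies = 4, seed = 11)
#' st$dataset
#' @export
sim_tumor <- function(n_subclones = 6, n_biopsies = 6,
                      mutations_per_subclone = c(20L, 50L),
                      mu = 1, sigma = 0, cn_max = 15, wt_max = 0.10,
                      coverage_fn = coverage_negbin(), dup_loss_max = 0.05,
                      tumor_id = "sim", seed = NULL) {
  with_seed_if(seed, {
    phylo <- sim_phylogeny(n_subclones, mutations_per_subclone)
    rho <- sim_composition(phylo, n_biopsies, wt_max)
    phi <- true_phi_matrix(phylo, rho)
    trios <- sim_trios(rownames(phi), colnames(rho), mu, sigma, cn_max)
    purity <- 1 - rho["WT", ]
    ds <- sim_reads(phi, trios, purity, coverage_fn, dup_loss_max,
                    tumor_id = tumor_id)
    structure(
      list(phylogeny = phylo, composition = rho, trios = trios, phi = phi,
           dataset = ds,
           params = list(n_subclones = n_subclones, n_biopsies = n_biopsies,
                         mu = mu, sigma = sigma, cn_max = cn_max,
                         wt_max = wt_max, dup_loss_max = dup_loss_max,
                         seed = seed, tumor_id = tumor_id)),
      class = "sim_tumor"
    )
  })
}

#' @export
print.sim_tumor <- function(x, ...) {
  p <- x$params
  cat("<sim_tumor> ", p$tumor_id, ": ", p$n_subclones, " subclones, ",
      nrow(x$phi), " mutations, ", p$n_biopsies, " biopsies",
      " (mu=", p$mu, ", sigma=", p$sigma, ")\n", sep = "")
  invisible(x)
}

#' Simulate a cohort of ground-truthed tumors
#'
#' Expands a configuration grid into per-tumor simulations with seeds derived
#' from one master seed, so the cohort is reproducible element-wise.
#'
#' @param config Data frame with one row per condition; recognized columns
#'   (all optional, defaults as in [sim_tumor()]): `n_subclones`,
#'   `n_biopsies`, `mu`, `sigma`, `wt_max`, `dup_loss_max`, `replicates`.
#' @param seed Master integer seed.
#' @param ... Passed on to [sim_tumor()] (e.g. `coverage_fn`).
#' @return List of `sim_tumor` objects, one per replicate per condition.
#' @export
sim_cohort <- function(config, seed = NULL, ...) {
  cfg <- as_tibble(config)
  if (!"replicates" %in% names(cfg)) cfg$replicates <- 1L
  rows <- cfg[rep(seq_len(nrow(cfg)), cfg$replicates), , drop = FALSE]
  rows$replicate <- unlist(lapply(cfg$replicates, seq_len))
  seeds <- derive_seeds(seed, nrow(rows))
  lapply(seq_len(nrow(rows)), function(i) {
    r <- rows[i, ]
    args <- list(seed = seeds[i],
                 tumor_id = sprintf("sim%03d", i), ...)
    for (nm in c("n_subclones", "n_biopsies", "mu", "sigma", "wt_max",
                 "dup_loss_max")) {
      if (nm %in% names(r)) args[[nm]] <- r[[nm]]
    }
    do.call(sim_tumor, args)
  })
}
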