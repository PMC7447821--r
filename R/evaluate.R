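#' Mean L1 frequency error, normalized by biopsy count
#'
#' The mean over assigned mutations of the L1 distance between true and
#' estimated frequency vectors divided by the number of biopsies, so an
#' error of `e` in every biopsy yields `e` regardless of how many regions
#' were profiled.
#'
#' @param true_phi,est_phi Numeric matrices (mutations x biopsies) with
#'   mutation ids as rownames; columns must correspond.
#' @param assigned_ids Mutations to average over (default: rows of
#'   `est_phi`). An empty set yields `NA` (undefined, not zero).
#' @return Single non-negative number, or `NA_real_`.
#' @examples
#' t <- rbind(m1 = c(0.5, 0.5)); e <- rbind(m1 = c(0.6, 0.4))
#' mean_l1_error(t, e) # 0.1
#' @export
mean_l1_error <- function(true_phi, est_phi, assigned_ids = rownames(est_phi)) {
  check_that(ncol(true_phi) == ncol(est_phi),
             "true and estimated matrices must share the biopsy dimension")
  ids <- intersect(assigned_ids, rownames(true_phi))
  if (length(ids) == 0) return(NA_real_)
  diffs <- abs(true_phi[ids, , drop = FALSE] - est_phi[ids, , drop = FALSE])
  mean(rowSums(diffs) / ncol(true_phi))
}

#' Fraction of mutations that received a frequency estimate
#'
#' Clustered mutations over total detected mutations; unassigned (noise or
#' invalid) mutations count in the denominator only.
#'
#' @param fit A `subclone_fit`.
#' @return Number in `[0, 1]`.
#' @export
assigned_fraction <- function(fit) {
  a <- fit$assignments
  check_that(nrow(a) > 0, "empty fit")
  mean(!is.na(a$cluster))
}

#' Ancestral-pair error
#'
#' Combined frequency of false-positive and false-negative ordered
#' (ancestor, descendant) mutation pairs:
#' \eqn{(|I \setminus T| + |T \setminus I|) / |U|} over a stated universe of
#' evaluable ordered pairs.
#'
#' @param true_pairs,inferred_pairs Tibbles with columns `ancestor`,
#'   `descendant` (ordered pairs).
#' @param universe Either the universe size (count of evaluable ordered
#'   pairs) or a character vector of mutation ids, in which case the
#'   universe is all ordered pairs of distinct ids and both pair sets are
#'   restricted to it.
#' @return Number in `[0, 1]`, or `NA_real_` when the universe is empty.
#' @export
ancestry_error <- function(true_pairs, inferred_pairs, universe) {
  key <- function(p) paste(p$ancestor, p$descendant, sep = "\r")
  tp <- key(true_pairs); ip <- key(inferred_pairs)
  if (is.character(universe)) {
    n_u <- length(universe) * (length(universe) - 1)
    in_u <- function(p) p$ancestor %in% universe & p$descendant %in% universe
    tp <- tp[in_u(true_pairs)]
    ip <- ip[in_u(inferred_pairs)]
  } else {
    n_u <- universe
  }
  if (n_u == 0) return(NA_real_)
  (length(setdiff(ip, tp)) + length(setdiff(tp, ip))) / n_u
}

#' Per-mutation coefficient of variation of copy numbers across biopsies
#'
#' The instability surrogate: sd/mean (population sd, dividing by n) of a
#' mutation's copy numbers across biopsies. Scale-invariant; zero for a
#' perfectly stable locus; undefined (`NA`) at zero mean.
#'
#' @param x Long tibble with columns `mutation_id`, `value` (one row per
#'   biopsy), or a numeric matrix mutations x biopsies.
#' @return Tibble (`mutation_id`, `cv`).
#' @examples
#' instability_cv(rbind(m1 = c(1, 3)))$cv # 0.5
#' @export
instability_cv <- function(x) {
  if (is.matrix(x)) {
    check_that(ncol(x) >= 2, "at least two biopsies are required")
    x <- tibble(mutation_id = rep(rownames(x), ncol(x)),
                value = as.vector(x))
  }
  sd_pop <- function(v) sqrt(mean((v - mean(v))^2))
  x %>%
    group_by(.data$mutation_id) %>%
    summarise(cv = if (mean(.data$value) > 0)
      sd_pop(.data$value) / mean(.data$value) else NA_real_,
      .groups = "drop")
}

#' Evaluate a fit against simulator ground truth
#'
#' One-row summary combining the accuracy metrics: mean L1 frequency error
#' over assigned mutations, assigned fraction, ancestral-pair error (over
#' ordered pairs of assigned mutations), cluster count, and the median
#' instability CV of the simulated mutant-allele copy numbers.
#'
#' @param fit A `subclone_fit`.
#' @param sim The matching `sim_tumor`.
#' @param epsilon Dominance tolerance for the inferred tree (default 0).
#' @return One-row tibble.
#' @export
evaluate_fit <- function(fit, sim, epsilon = 0) {
  check_that(fit$config$tumor_id == sim$params$tumor_id,
             "fit and simulation refer to different tumors",
             class = "clonefreq_id_mismatch")
  est_long <- mutation_phi(fit)
  est <- matrix(NA_real_, 0, ncol(sim$phi))
  if (nrow(est_long)) {
    wide <- est_long %>%
      tidyr::pivot_wider(names_from = "biopsy_id", values_from = "phi_est")
    est <- as.matrix(wide[, -1, drop = FALSE])
    rownames(est) <- wide$mutation_id
    est <- est[, colnames(sim$phi), drop = FALSE]
  }
  merr <- mean_l1_error(sim$phi, est)

  assigned <- fit$assignments$mutation_id[!is.na(fit$assignments$cluster)]
  true_pairs <- ancestral_pairs_truth(sim)
  inf_pairs <- if (nrow(fit$frequencies)) {
    tr <- suppressWarnings(clone_tree(fit, epsilon = epsilon))
    ancestral_pairs(tr, fit$assignments)
  } else {
    tibble(ancestor = character(), descendant = character())
  }
  aerr <- ancestry_error(true_pairs, inf_pairs, universe = assigned)

  cv <- instability_cv(
    sim$trios %>% select("mutation_id", value = "delta_m"))

  tibble(
    tumor_id = sim$params$tumor_id,
    mean_error = merr,
    assigned_fraction = assigned_fraction(fit),
    ancestry_error = aerr,
    n_clusters = length(unique(fit$assignments$cluster[
      !is.na(fit$assignments$cluster)])),
    n_subclones_true = sim$params$n_subclones,
    median_cv = median(cv$cv, na.rm = TRUE),
    mu = sim$params$mu,
    sigma = sim$params$sigma
  )
}

#' True ancestral mutation pairs of a simulated tumor
#'
#' Ordered (ancestor, descendant) mutation pairs implied by the simulated
#' phylogeny: a pair exists when the originating subclone of the first is a
#' proper ancestor of the originating subclone of the second.
#'
#' @param sim A `sim_tumor`.
#' @return Tibble (`ancestor`, `descendant`).
#' @export
ancestral_pairs_truth <- function(sim) {
  sub_pairs <- phylo_ancestor_pairs(sim$phylogeny)
  by_sub <- split(sim$phylogeny$mutations$mutation_id,
                  sim$phylogeny$mutations$subclone)
  rows <- lapply(seq_len(nrow(sub_pairs)), function(i)
    tidyr::expand_grid(ancestor = by_sub[[sub_pairs$ancestor[i]]],
                       descendant = by_sub[[sub_pairs$descendant[i]]]))
  out <- bind_rows(rows)
  if (nrow(out) == 0) tibble(ancestor = character(), descendant = character())
  else out
}

#' Subclone-count convergence across region subsets
#'
#' Re-runs the inference on biopsy subsets of increasing size and records
#' the number of detected subclones, probing how many regions are needed
#' before predictions stabilize. Subsets are enumerated exhaustively up to
#' `max_subsets` per size and sampled (seeded) beyond that.
#'
#' @param dataset A [tumor_dataset()] with at least 3 biopsies.
#' @param k_range Subset sizes to evaluate (default `2:|S|`).
#' @param max_subsets Cap on subsets per size (default 200).
#' @param seed Seed for subset sampling and inference.
#' @param ... Passed to [infer_subclones()].
#' @return Tibble (`k`, `subset_id`, `biopsies`, `n_clusters`,
#'   `assigned_fraction`).
#' @export
region_convergence <- function(dataset, k_range = NULL, max_subsets = 200,
                               seed = NULL, ...) {
  S <- dataset$biopsies
  if (is.null(k_range)) k_range <- 2:length(S)
  check_that(all(k_range >= 2 & k_range <= length(S)),
             "k_range must lie within [2, number of biopsies]",
             class = "clonefreq_range_error")
  seeds <- derive_seeds(seed, length(k_range) + 1L)
  rows <- list()
  for (ki in seq_along(k_range)) {
    k <- k_range[ki]
    subsets <- combn(S, k, simplify = FALSE)
    if (length(subsets) > max_subsets) {
      idx <- with_seed_if(seeds[ki],
                          sample.int(length(subsets), max_subsets))
      subsets <- subsets[idx]
    }
    for (si in seq_along(subsets)) {
      sub <- subsets[[si]]
      obs <- dataset$observations %>% filter(.data$biopsy_id %in% sub)
      pur <- dataset$purity %>% filter(.data$biopsy_id %in% sub)
      ds <- tumor_dataset(obs, pur, tumor_id = dataset$tumor_id)
      fit <- infer_subclones(ds, seed = seeds[length(k_range) + 1L], ...)
      rows[[length(rows) + 1L]] <- tibble(
        k = k, subset_id = si, biopsies = paste(sub, collapse = ","),
        n_clusters = length(unique(
          fit$assignments$cluster[!is.na(fit$assignments$cluster)])),
        assigned_fraction = assigned_fraction(fit))
    }
  }
  bind_rows(rows)
}
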