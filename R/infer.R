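#' First-approximation mutation frequencies
#'
#' Corrects each mutated-read fraction for the observed copy number and
#' biopsy purity under the simplifying assumption that the mutant allele
#' carries half the tumor copy number (\eqn{\delta_m = C/2}):
#' \deqn{\tilde\phi = \min\!\left(\frac{2 f\, C_{obs}}{C_{obs} - 2(1-p)},\, 1\right).}
#' In a pure diploid biopsy this reduces to \eqn{\min(2f, 1)}. Entries whose
#' denominator is non-positive (observed copy number at or below the normal-
#' contamination baseline, e.g. homozygous-deletion-like loci) are flagged
#' invalid; such mutations cannot be clustered and are later reported
#' unassigned.
#'
#' @param dataset A [tumor_dataset()].
#' @return Tibble (`mutation_id`, `biopsy_id`, `f`, `phi_tilde`, `valid`).
#'   `phi_tilde` is `NA` where invalid.
#' @examples
#' # pure diploid: phi_tilde = 2f
#' @export
first_approximation <- function(dataset) {
  obs <- obs_with_purity(dataset)
  f <- read_fraction(obs$alt_reads, obs$ref_reads,
                     id = paste0(obs$mutation_id, "@", obs$biopsy_id))
  denom <- obs$c_obs - 2 * (1 - obs$purity)
  valid <- denom > 0
  phi_tilde <- ifelse(valid, pmin(2 * f * obs$c_obs / denom, 1), NA_real_)
  tibble(mutation_id = obs$mutation_id, biopsy_id = obs$biopsy_id,
         f = f, phi_tilde = phi_tilde, valid = valid)
}

#' Infer tumor subclones from a multi-biopsy dataset
#'
#' The full three-step pipeline: (1) first-approximation frequencies per
#' mutation and biopsy ([first_approximation()]); (2) density clustering of
#' frequency vectors into candidate subclones ([cluster_frequencies()]);
#' (3) per-cluster refinement of the shared frequency vector and per-mutation
#' mutant-allele copy numbers by constrained rank-1 factorization of the B
#' matrix ([optimize_rank1()]). Mutations labeled noise by the clustering, or
#' with an undefined first approximation in any biopsy, receive no frequency
#' estimate and are reported unassigned.
#'
#' @param dataset A [tumor_dataset()], or a data frame of observations (then
#'   `purity` must be supplied and a dataset is assembled on the fly).
#' @param purity Optional purity data frame when `dataset` is raw
#'   observations.
#' @param min_cluster_size Minimum mutations per cluster (default 5).
#' @param method Clustering backend, see [cluster_frequencies()].
#' @param cn_max Copy-number upper bound for the optimization (default 15).
#' @param n_restarts Restarts for the rank-1 optimization (default 10).
#' @param tol Optimization tolerance (default 1e-8).
#' @param seed Integer seed covering clustering and restarts.
#' @return A `subclone_fit`: list with
#'   \describe{
#'     \item{frequencies}{tibble (`cluster`, `biopsy_id`, `phi`): refined
#'       per-subclone frequency vectors,}
#'     \item{assignments}{tibble (`mutation_id`, `cluster`, `delta`,
#'       `reason`): cluster membership (cluster `NA` = unassigned) with the
#'       refined mutant-allele copy number,}
#'     \item{phi_tilde}{the first-approximation table,}
#'     \item{residuals}{per-cluster optimization residuals,}
#'     \item{config}{effective parameters, including the seed.}
#'   }
#' @examples
#' st <- sim_tumor(n_subclones = 3, n_biopsies = 4, mu = 1, sigma = 0,
#'                 dup_loss_max = 0, seed = 5)
#' fit <- infer_subclones(st$dataset, seed = 1)
#' glance(fit)
#' @export
infer_subclones <- function(dataset, purity = NULL, min_cluster_size = 5,
                            method = c("density", "trimmed_kmeans"),
                            cn_max = 15, n_restarts = 10, tol = 1e-8,
                            seed = NULL) {
  method <- match.arg(method)
  if (!inherits(dataset, "tumor_dataset")) {
    check_that(!is.null(purity),
               "supply a tumor_dataset or observations plus a purity table")
    dataset <- tumor_dataset(dataset, purity)
  }
  check_that(length(dataset$biopsies) >= 2,
             "at least two profiled regions per tumor are required",
             class = "clonefreq_few_biopsies")

  fa <- first_approximation(dataset)
  bad <- fa %>% group_by(.data$mutation_id) %>%
    summarise(ok = all(.data$valid), .groups = "drop")
  invalid_ids <- bad$mutation_id[!bad$ok]
  usable <- fa %>% filter(!.data$mutation_id %in% invalid_ids)

  seeds <- derive_seeds(seed, 2L)
  clusters <- if (nrow(usable) > 0) {
    cluster_frequencies(usable, min_cluster_size = min_cluster_size,
                        method = method, seed = seeds[1])
  } else {
    tibble(mutation_id = character(), cluster = integer())
  }

  cluster_ids <- sort(unique(clusters$cluster[clusters$cluster > 0]))
  phi_wide <- if (nrow(usable)) phi_long_to_matrix(usable) else NULL
  opt_seeds <- derive_seeds(seeds[2], max(1L, length(cluster_ids)))

  freq_rows <- list(); assign_rows <- list(); residuals <- numeric(0)
  for (i in seq_along(cluster_ids)) {
    cl <- cluster_ids[i]
    members <- clusters$mutation_id[clusters$cluster == cl]
    B <- build_b_matrix(dataset, members)
    anchor <- apply(phi_wide[members, dataset$biopsies, drop = FALSE], 2,
                    median)
    opt <- optimize_rank1(B, cn_max = cn_max, n_restarts = n_restarts,
                          tol = tol, anchor_phi = anchor,
                          seed = opt_seeds[i])
    freq_rows[[i]] <- tibble(cluster = cl, biopsy_id = dataset$biopsies,
                             phi = opt$phi)
    assign_rows[[i]] <- tibble(mutation_id = members, cluster = cl,
                               delta = opt$delta, reason = NA_character_)
    residuals[as.character(cl)] <- opt$residual
  }

  noise_ids <- clusters$mutation_id[clusters$cluster == 0]
  unassigned <- bind_rows(
    if (length(noise_ids))
      tibble(mutation_id = noise_ids, cluster = NA_integer_,
             delta = NA_real_, reason = "noise"),
    if (length(invalid_ids))
      tibble(mutation_id = invalid_ids, cluster = NA_integer_,
             delta = NA_real_,
             reason = "undefined first approximation (c_obs <= 2(1-p))")
  )
  assignments <- bind_rows(assign_rows, unassigned) %>%
    arrange(match(.data$mutation_id, dataset$mutations))

  structure(
    list(frequencies = bind_rows(freq_rows),
         assignments = assignments,
         phi_tilde = fa,
         residuals = residuals,
         dataset = dataset,
         config = list(min_cluster_size = min_cluster_size, method = method,
                       cn_max = cn_max, n_restarts = n_restarts, tol = tol,
                       seed = seed, tumor_id = dataset$tumor_id,
                       n_biopsies = length(dataset$biopsies),
                       n_mutations = length(dataset$mutations))),
    class = "subclone_fit"
  )
}

#' @export
print.subclone_fit <- function(x, ...) {
  g <- glance(x)
  cat("<subclone_fit> ", x$config$tumor_id, ": ", g$n_clusters,
      " subclone(s), ", round(100 * g$assigned_fraction, 1),
      "% of ", g$n_mutations, " mutations assigned\n", sep = "")
  invisible(x)
}

#' Per-subclone frequency matrix of a fit
#'
#' @param fit A `subclone_fit`.
#' @return Matrix clusters x biopsies of refined frequencies (possibly
#'   0-row when no subclones were detected).
#' @export
subclone_phi <- function(fit) {
  if (nrow(fit$frequencies) == 0) {
    return(matrix(numeric(0), 0, fit$config$n_biopsies,
                  dimnames = list(NULL, fit$dataset$biopsies)))
  }
  wide <- fit$frequencies %>%
    tidyr::pivot_wider(names_from = "biopsy_id", values_from = "phi")
  m <- as.matrix(wide[, -1, drop = FALSE])
  rownames(m) <- paste0("C", wide$cluster)
  m[, fit$dataset$biopsies, drop = FALSE]
}

#' Per-mutation refined frequency estimates
#'
#' Every assigned mutation inherits its cluster's refined frequency vector.
#'
#' @param fit A `subclone_fit`.
#' @return Tibble (`mutation_id`, `biopsy_id`, `phi_est`), assigned
#'   mutations only.
#' @export
mutation_phi <- function(fit) {
  fit$assignments %>%
    filter(!is.na(.data$cluster)) %>%
    select("mutation_id", "cluster") %>%
    inner_join(fit$frequencies, by = "cluster",
               relationship = "many-to-many") %>%
    select("mutation_id", "biopsy_id", phi_est = "phi")
}
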