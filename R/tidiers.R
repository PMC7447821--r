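#' Tidy a subclone fit
#'
#' One row per mutation: cluster membership, refined mutant-allele copy
#' number, and the unassignment reason where applicable.
#'
#' @param x A `subclone_fit`.
#' @param ... Unused.
#' @return Tibble (`mutation_id`, `cluster`, `delta`, `reason`).
#' @exportS3Method generics::tidy
tidy.subclone_fit <- function(x, ...) {
  as_tibble(x$assignments)
}

#' One-row summary of a subclone fit
#'
#' @param x A `subclone_fit`.
#' @param ... Unused.
#' @return Tibble with `n_mutations`, `n_clusters`, `assigned_fraction`,
#'   `total_residual`, `n_biopsies`.
#' @exportS3Method generics::glance
glance.subclone_fit <- function(x, ...) {
  tibble(
    n_mutations = x$config$n_mutations,
    n_clusters = nrow(subclone_phi(x)),
    assigned_fraction = assigned_fraction(x),
    total_residual = sum(x$residuals),
    n_biopsies = x$config$n_biopsies
  )
}

#' Tidy a clone tree
#'
#' @param x A `clone_tree`.
#' @param ... Unused.
#' @return Edge tibble (`parent`, `child`).
#' @exportS3Method generics::tidy
tidy.clone_tree <- function(x, ...) {
  as_tibble(x$edges)
}

#' Tidy a simulated tumor
#'
#' The ground-truth frequency matrix in long form.
#'
#' @param x A `sim_tumor`.
#' @param ... Unused.
#' @return Tibble (`mutation_id`, `biopsy_id`, `phi`, `subclone`).
#' @exportS3Method generics::tidy
tidy.sim_tumor <- function(x, ...) {
  tibble(
    mutation_id = rep(rownames(x$phi), ncol(x$phi)),
    biopsy_id = rep(colnames(x$phi), each = nrow(x$phi)),
    phi = as.vector(x$phi)
  ) %>%
    left_join(x$phylogeny$mutations, by = "mutation_id") %>%
    arrange(.data$mutation_id, .data$biopsy_id)
}
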