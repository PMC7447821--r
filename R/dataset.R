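#' Assemble and validate a multi-biopsy tumor dataset
#'
#' Bundles per-(mutation, biopsy) read counts and observed copy numbers with
#' per-biopsy purities into the container all inference functions consume.
#' Mutations absent from some biopsy are completed with `alt_reads = 0` and
#' that biopsy's median total coverage as `ref_reads` (a mutation undetected
#' in a region still needs a complete frequency vector for clustering);
#' loci on sex chromosomes are dropped with a warning.
#'
#' @param observations Data frame with columns `mutation_id`, `biopsy_id`,
#'   `alt_reads`, `ref_reads`, `c_obs` (observed total copy number,
#'   diploid-normalized so 2 = no change). Optional metadata columns
#'   `chrom`, `pos`, `ref_allele`, `alt_allele` are carried through
#'   untouched and never used in computation.
#' @param purity Data frame with columns `biopsy_id`, `purity` (in `(0, 1]`),
#'   one row per biopsy.
#' @param tumor_id Single string identifying the tumor.
#' @return A `tumor_dataset`: list with tibbles `observations` (complete over
#'   the mutation x biopsy grid, ordered), `purity`, plus `biopsies`,
#'   `mutations` and `tumor_id`.
#' @export
tumor_dataset <- function(observations, purity, tumor_id = "tumor") {
  obs <- as_tibble(observations)
  pur <- as_tibble(purity)
  need <- c("mutation_id", "biopsy_id", "alt_reads", "ref_reads", "c_obs")
  missing_cols <- setdiff(need, names(obs))
  check_that(length(missing_cols) == 0,
             paste0("observations is missing column(s): ",
                    paste(missing_cols, collapse = ", ")),
             class = "clonefreq_schema_error")
  check_that(all(c("biopsy_id", "purity") %in% names(pur)),
             "purity table needs columns biopsy_id, purity",
             class = "clonefreq_schema_error")
  check_that(is_count(obs$alt_reads) && is_count(obs$ref_reads),
             "read counts must be non-negative integers",
             class = "clonefreq_schema_error")
  check_that(all(obs$c_obs >= 0), "c_obs must be non-negative",
             class = "clonefreq_schema_error")
  check_that(all(pur$purity > 0 & pur$purity <= 1),
             "purity must lie in (0, 1]", class = "clonefreq_schema_error")

  dup <- obs %>% dplyr::count(.data$mutation_id, .data$biopsy_id) %>%
    filter(.data$n > 1)
  if (nrow(dup) > 0) {
    abort(paste0("duplicate (mutation_id, biopsy_id) key: ",
                 dup$mutation_id[1], " / ", dup$biopsy_id[1]),
          class = "clonefreq_duplicate_key")
  }

  if ("chrom" %in% names(obs)) {
    sex <- grepl("^(chr)?[XY]$", obs$chrom)
    if (any(sex)) {
      warn(paste0("dropping ", sum(sex),
                  " observation(s) on sex chromosomes (chrX/chrY)"))
      obs <- obs[!sex, , drop = FALSE]
    }
  }

  biopsies <- unique(pur$biopsy_id)
  check_that(all(obs$biopsy_id %in% biopsies),
             "observations reference biopsies absent from the purity table",
             class = "clonefreq_schema_error")
  mutations <- unique(obs$mutation_id)
  check_that(length(mutations) > 0, "no observations left after filtering")

  # complete the grid: undetected (mutation, biopsy) pairs get alt = 0 and
  # the biopsy's typical coverage as ref, so f = 0 there
  grid <- tidyr::expand_grid(mutation_id = mutations, biopsy_id = biopsies)
  filled <- grid %>% left_join(obs, by = c("mutation_id", "biopsy_id"))
  if (anyNA(filled$alt_reads)) {
    med_cov <- obs %>%
      group_by(.data$biopsy_id) %>%
      summarise(cov = max(1, round(median(.data$alt_reads + .data$ref_reads))),
                .groups = "drop")
    filled <- filled %>%
      left_join(med_cov, by = "biopsy_id") %>%
      mutate(
        ref_reads = ifelse(is.na(.data$ref_reads), .data$cov, .data$ref_reads),
        alt_reads = ifelse(is.na(.data$alt_reads), 0L, .data$alt_reads),
        c_obs     = ifelse(is.na(.data$c_obs), 2, .data$c_obs)
      ) %>%
      select(-"cov")
  }
  filled <- filled %>%
    mutate(mutation_id = factor(.data$mutation_id, levels = mutations),
           biopsy_id = factor(.data$biopsy_id, levels = biopsies)) %>%
    arrange(.data$mutation_id, .data$biopsy_id) %>%
    mutate(mutation_id = as.character(.data$mutation_id),
           biopsy_id = as.character(.data$biopsy_id))

  structure(
    list(observations = filled,
         purity = pur %>% select("biopsy_id", "purity"),
         biopsies = biopsies,
         mutations = mutations,
         tumor_id = tumor_id),
    class = "tumor_dataset"
  )
}

#' @export
print.tumor_dataset <- function(x, ...) {
  cat("<tumor_dataset> ", x$tumor_id, ": ",
      length(x$mutations), " mutations x ",
      length(x$biopsies), " biopsies\n", sep = "")
  cat("  purity: ",
      paste(sprintf("%s=%.2f", x$purity$biopsy_id, x$purity$purity),
            collapse = ", "), "\n", sep = "")
  invisible(x)
}

# named purity vector in biopsy order
purity_vector <- function(ds) {
  setNames(ds$purity$purity, ds$purity$biopsy_id)[ds$biopsies]
}

# long observations joined with purity
obs_with_purity <- function(ds) {
  ds$observations %>% left_join(ds$purity, by = "biopsy_id")
}
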