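# TSV is the canonical exchange format; floats are written with 6
# significant digits; genomic coordinates are 1-based (VCF convention) and
# carried as metadata only.

mutation_table_cols <- c("tumor_id", "biopsy_id", "mutation_id", "chrom",
                         "pos", "ref_allele", "alt_allele", "ref_reads",
                         "alt_reads", "c_obs")

#' Read a mutation table and purity table into tumor datasets
#'
#' The mutation table is a TSV with header columns `tumor_id`, `biopsy_id`,
#' `mutation_id`, `chrom`, `pos` (1-based), `ref_allele`, `alt_allele`,
#' `ref_reads`, `alt_reads`, `c_obs`; the purity table has `tumor_id`,
#' `biopsy_id`, `purity`. One [tumor_dataset()] is built per `tumor_id`;
#' mutations missing in some biopsy are completed (zero alt reads), and
#' sex-chromosome loci are dropped with a warning.
#'
#' @param path Mutation table TSV path.
#' @param purity_path Purity table TSV path.
#' @return Named list of [tumor_dataset()] objects.
#' @export
read_mutation_table <- function(path, purity_path) {
  mt <- read_tsv_checked(path, mutation_table_cols)
  pt <- read_tsv_checked(purity_path, c("tumor_id", "biopsy_id", "purity"))
  check_that(is_count(mt$ref_reads) && is_count(mt$alt_reads),
             "negative or non-integer read counts in mutation table",
             class = "clonefreq_schema_error")
  dup <- duplicated(mt[, c("tumor_id", "mutation_id", "biopsy_id")])
  if (any(dup)) {
    abort(paste0("duplicate (mutation_id, biopsy_id) at data row ",
                 which(dup)[1]),
          class = "clonefreq_duplicate_key")
  }
  tumors <- unique(mt$tumor_id)
  out <- lapply(tumors, function(tid) {
    tumor_dataset(mt %>% filter(.data$tumor_id == tid) %>%
                    select(-"tumor_id"),
                  pt %>% filter(.data$tumor_id == tid) %>%
                    select("biopsy_id", "purity"),
                  tumor_id = tid)
  })
  setNames(out, tumors)
}

read_tsv_checked <- function(path, cols) {
  check_that(file.exists(path), paste0("file not found: ", path),
             class = "clonefreq_io_error")
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE)
  missing <- setdiff(cols, names(df))
  check_that(length(missing) == 0,
             paste0(path, " is missing column(s): ",
                    paste(missing, collapse = ", ")),
             class = "clonefreq_schema_error")
  as_tibble(df[, cols, drop = FALSE])
}

#' Write a tumor dataset (plus purity) as TSVs
#'
#' Inverse of [read_mutation_table()]; a write-then-read round trip
#' reproduces the dataset exactly.
#'
#' @param dataset A [tumor_dataset()].
#' @param path,purity_path Output TSV paths.
#' @return Invisibly, the written observation tibble.
#' @export
write_mutation_table <- function(dataset, path, purity_path) {
  obs <- dataset$observations
  if (!"chrom" %in% names(obs)) obs$chrom <- "chr1"
  if (!"pos" %in% names(obs)) {
    obs$pos <- match(obs$mutation_id, dataset$mutations)
  }
  if (!"ref_allele" %in% names(obs)) obs$ref_allele <- "A"
  if (!"alt_allele" %in% names(obs)) obs$alt_allele <- "T"
  obs$tumor_id <- dataset$tumor_id
  obs <- obs[, mutation_table_cols]
  obs$c_obs <- fmt_num(obs$c_obs)
  utils::write.table(obs, path, sep = "\t", quote = FALSE, row.names = FALSE)
  pur <- dataset$purity
  pur$tumor_id <- dataset$tumor_id
  pur <- pur[, c("tumor_id", "biopsy_id", "purity")]
  pur$purity <- fmt_num(pur$purity)
  utils::write.table(pur, purity_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(obs)
}

#' Write simulator ground truth as TSVs
#'
#' Emits the composition matrix, per-(mutation, biopsy) trios, and the true
#' frequency matrix alongside the dataset, so downstream evaluation never
#' needs the in-memory object.
#'
#' @param sim A `sim_tumor`.
#' @param dir Output directory (created if absent).
#' @return Invisibly, the vector of written paths.
#' @export
write_truth <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tid <- sim$params$tumor_id
  p1 <- file.path(dir, paste0(tid, "_composition.tsv"))
  comp <- as_tibble(sim$composition, rownames = "subclone")
  comp[-1] <- lapply(comp[-1], fmt_num)
  utils::write.table(comp, p1, sep = "\t", quote = FALSE, row.names = FALSE)
  p2 <- file.path(dir, paste0(tid, "_trios.tsv"))
  tr <- sim$trios
  tr[c("delta", "delta_w", "delta_m")] <-
    lapply(tr[c("delta", "delta_w", "delta_m")], fmt_num)
  utils::write.table(tr, p2, sep = "\t", quote = FALSE, row.names = FALSE)
  p3 <- file.path(dir, paste0(tid, "_true_phi.tsv"))
  phi <- as_tibble(sim$phi, rownames = "mutation_id")
  phi[-1] <- lapply(phi[-1], fmt_num)
  utils::write.table(phi, p3, sep = "\t", quote = FALSE, row.names = FALSE)
  p4 <- file.path(dir, paste0(tid, "_phylogeny.tsv"))
  edges <- tibble(parent = unname(sim$phylogeny$parent),
                  child = names(sim$phylogeny$parent)) %>%
    filter(!is.na(.data$parent))
  utils::write.table(edges, p4, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(p1, p2, p3, p4))
}

#' Write an inference result as TSVs plus a JSON run manifest
#'
#' Emits a clusters table (`mutation_id`, `cluster_id`, `delta_m`, `reason`),
#' a frequencies table (`cluster_id`, `biopsy_id`, `phi`), and a manifest
#' JSON holding the full effective configuration, seed, and per-cluster
#' residuals; two runs with equal manifests produce equal outputs.
#'
#' @param fit A `subclone_fit`.
#' @param dir Output directory.
#' @return Invisibly, the written paths.
#' @export
write_inference <- function(fit, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tid <- fit$config$tumor_id
  p1 <- file.path(dir, paste0(tid, "_clusters.tsv"))
  cl <- tidy(fit) %>%
    dplyr::rename(cluster_id = "cluster", delta_m = "delta")
  cl$delta_m <- fmt_num(cl$delta_m)
  utils::write.table(cl, p1, sep = "\t", quote = FALSE, row.names = FALSE)
  p2 <- file.path(dir, paste0(tid, "_frequencies.tsv"))
  fr <- fit$frequencies %>% dplyr::rename(cluster_id = "cluster")
  fr$phi <- fmt_num(fr$phi)
  utils::write.table(fr, p2, sep = "\t", quote = FALSE, row.names = FALSE)
  p3 <- file.path(dir, paste0(tid, "_manifest.json"))
  jsonlite::write_json(
    list(config = fit$config,
         residuals = as.list(fit$residuals)),
    p3, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(p1, p2, p3))
}

#' Write a clone tree as Newick, edge list and ancestral pairs
#'
#' @param tree A [clone_tree()].
#' @param dir Output directory.
#' @param prefix File-name prefix (default "tree").
#' @param assignments Optional assignments tibble to expand ancestral pairs
#'   to mutations (see [ancestral_pairs()]).
#' @return Invisibly, the written paths.
#' @export
write_tree <- function(tree, dir, prefix = "tree", assignments = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p1 <- file.path(dir, paste0(prefix, ".nwk"))
  writeLines(to_newick(tree), p1)
  p2 <- file.path(dir, paste0(prefix, "_edges.tsv"))
  utils::write.table(tree$edges, p2, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  p3 <- file.path(dir, paste0(prefix, "_pairs.tsv"))
  utils::write.table(ancestral_pairs(tree, assignments), p3, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(c(p1, p2, p3))
}

#' Ingest per-sample allelic depths from a VCF
#'
#' Convenience converter: reads a VCF whose genotype field carries allelic
#' depth (`AD`), maps samples to biopsies, and returns mutation-table rows
#' with `ref_reads`/`alt_reads` taken from AD. Multi-allelic records are
#' skipped with a warning. Observed copy numbers are not in VCFs and must be
#' joined from a separate table before building a [tumor_dataset()].
#'
#' @param path VCF path (plain text or bgzipped).
#' @param sample_map Named character vector mapping VCF sample names to
#'   biopsy ids; defaults to the samples themselves.
#' @return Tibble (`mutation_id`, `biopsy_id`, `chrom`, `pos`, `ref_allele`,
#'   `alt_allele`, `ref_reads`, `alt_reads`).
#' @export
read_vcf_counts <- function(path, sample_map = NULL) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  if (nrow(vcf@fix) == 0) {
    return(tibble(mutation_id = character(), biopsy_id = character(),
                  chrom = character(), pos = integer(),
                  ref_allele = character(), alt_allele = character(),
                  ref_reads = integer(), alt_reads = integer()))
  }
  fix <- as_tibble(as.data.frame(vcf@fix, stringsAsFactors = FALSE))
  multi <- grepl(",", fix$ALT)
  if (any(multi)) {
    warn(paste0("skipping ", sum(multi), " multi-allelic VCF record(s)"))
  }
  fmt <- vcfR::extract.gt(vcf, element = "AD")
  if (is.null(fmt) || all(is.na(fmt))) {
    abort("VCF has no allelic-depth (AD) genotype field",
          class = "clonefreq_schema_error")
  }
  samples <- colnames(fmt)
  if (is.null(sample_map)) sample_map <- setNames(samples, samples)
  keep <- which(!multi)
  rows <- lapply(keep, function(i) {
    ad <- strsplit(fmt[i, ], ",", fixed = TRUE)
    no_ad <- vapply(ad, function(a) length(a) < 2 || anyNA(a), logical(1))
    if (any(no_ad)) {
      abort(paste0("missing AD for record ", fix$CHROM[i], ":", fix$POS[i],
                   " sample(s) ", paste(samples[no_ad], collapse = ",")),
            class = "clonefreq_schema_error")
    }
    tibble(
      mutation_id = paste0(fix$CHROM[i], ":", fix$POS[i], "_",
                           fix$REF[i], ">", fix$ALT[i]),
      biopsy_id = unname(sample_map[samples]),
      chrom = fix$CHROM[i],
      pos = as.integer(fix$POS[i]),
      ref_allele = fix$REF[i],
      alt_allele = fix$ALT[i],
      ref_reads = as.integer(vapply(ad, `[[`, character(1), 1)),
      alt_reads = as.integer(vapply(ad, `[[`, character(1), 2))
    )
  })
  bind_rows(rows)
}
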