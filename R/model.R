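#' Mutated-read fraction from allele counts
#'
#' The fraction of sequencing reads at a locus that carry the mutant allele
#' (the VAF), `alt / (alt + ref)`.
#'
#' @param alt_reads,ref_reads Non-negative integer read counts (vectorized).
#' @param id Optional label (e.g. "mutation@biopsy") used in the error raised
#'   when total coverage is zero.
#' @return Numeric vector in `[0, 1]`.
#' @examples
#' read_fraction(30, 70) # 0.3
#' @export
read_fraction <- function(alt_reads, ref_reads, id = NULL) {
  check_that(is_count(alt_reads) && is_count(ref_reads),
             "read counts must be non-negative integers")
  total <- alt_reads + ref_reads
  if (any(total == 0)) {
    where <- if (is.null(id)) which(total == 0)[1] else id[total == 0][1]
    abort(paste0("undefined read fraction: zero total coverage at ", where),
          class = "clonefreq_zero_coverage")
  }
  alt_reads / total
}

#' Expected total copy number at a mutated locus in tumor cells
#'
#' Weighted sum of per-allele copy numbers over the two cell populations:
#' cells without the mutation carry two reference alleles at `delta` copies
#' each, mutated cells carry `delta_w` wild-type plus `delta_m` mutant copies:
#' \deqn{C = 2\delta(1-\phi) + (\delta_w + \delta_m)\phi.}
#' All copy numbers are per-allele with 1 = no change (so a fully diploid
#' locus gives C = 2).
#'
#' @param phi Mutation frequency in `[0, 1]` (fraction of profiled cells
#'   carrying the mutation).
#' @param delta Per-allele copy number of the reference allele in cells
#'   without the mutation (1 = no change).
#' @param delta_w,delta_m Copy numbers of the wild-type and mutated allele in
#'   mutated cells (1 = no change).
#' @return Expected total copy number (non-negative real; 2 = diploid).
#' @examples
#' expected_total_copy_number(0.5, 1, 1, 3) # 3
#' @export
expected_total_copy_number <- function(phi, delta, delta_w, delta_m) {
  check_that(all(phi >= 0 & phi <= 1), "phi must lie in [0, 1]")
  check_that(all(delta >= 0) && all(delta_w >= 0) && all(delta_m >= 0),
             "copy numbers must be non-negative")
  2 * delta * (1 - phi) + (delta_w + delta_m) * phi
}

#' Expected mutated-read fraction given frequency, copy numbers and purity
#'
#' The model linking the (unobserved) mutation frequency to the observable
#' read fraction in an impure biopsy:
#' \deqn{f = \frac{\phi\,\delta_m\,p}{2(1-p) + C\,p}}
#' with \eqn{C} from [expected_total_copy_number()]. At purity 1 this reduces
#' to \eqn{f = \phi\delta_m / C}.
#'
#' @inheritParams expected_total_copy_number
#' @param purity Tumor purity in `(0, 1]`.
#' @return Expected read fraction in `[0, 1]`.
#' @examples
#' expected_read_fraction(0.5, 1, 1, 1, purity = 1) # 0.25
#' @export
expected_read_fraction <- function(phi, delta, delta_w, delta_m, purity) {
  check_that(all(purity > 0 & purity <= 1), "purity must lie in (0, 1]")
  C <- expected_total_copy_number(phi, delta, delta_w, delta_m)
  denom <- 2 * (1 - purity) + C * purity
  if (any(denom <= 0)) {
    abort("no DNA at locus: total copy number 0 at purity 1",
          class = "clonefreq_no_dna")
  }
  phi * delta_m * purity / denom
}

#' Observed (bulk) copy number from tumor copy number and purity
#'
#' A bulk biopsy mixes tumor cells at copy number `C` with diploid normal
#' cells: \eqn{C_{obs} = 2(1-p) + C\,p}. A diploid tumor locus is therefore
#' indistinguishable from normal tissue at any purity.
#'
#' @param C Tumor-cell total copy number (non-negative real, 2 = diploid).
#' @param purity Tumor purity in `[0, 1]`.
#' @return Observed copy number.
#' @examples
#' observed_copy_number(4, 0.5) # 3
#' @export
observed_copy_number <- function(C, purity) {
  check_that(all(C >= 0), "copy number must be non-negative")
  check_that(all(purity >= 0 & purity <= 1), "purity must lie in [0, 1]")
  2 * (1 - purity) + C * purity
}

#' Purity- and copy-number-corrected read-count summary (B-matrix entry)
#'
#' \eqn{B = f \cdot C_{obs} / p}. When `f` and `C_obs` derive noiselessly
#' from the model equations, this equals \eqn{\phi \cdot \delta_m} exactly
#' -- the product the rank-1 factorization step decouples.
#'
#' @param f Mutated-read fraction in `[0, 1]`.
#' @param c_obs Observed copy number (non-negative).
#' @param purity Tumor purity in `(0, 1]`.
#' @return Numeric vector of products \eqn{\phi\delta_m}.
#' @examples
#' b_entry(0.25, 4, 0.5) # 2
#' @export
b_entry <- function(f, c_obs, purity) {
  check_that(all(purity > 0), "purity must be positive")
  f * c_obs / purity
}
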