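Package: clonefreq
Title: Copy-Number-Aware Subclone Frequency Inference from Multi-Biopsy
    Tumor Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Joint inference of tumor-subclone mutation frequencies and
    mutated-allele copy numbers from DNA profiles of multiple same-tumor
    biopsies. Corrects mutated-read fractions for observed copy number and
    tumor purity, clusters per-mutation frequency vectors across biopsies
    with a density-based method that labels outliers as noise, and refines
    each candidate subclone by box-constrained rank-1 matrix factorization.
    Includes a ground-truthed whole-exome-like simulator of multi-region
    tumor profiles under varying genetic instability, clone-tree
    reconstruction by frequency-vector dominance, accuracy metrics, TSV/VCF
    ingestion, and a small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    optparse,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR,
    withr
Suggests:
    ape,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
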