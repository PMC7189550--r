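Package: panetsig
Title: Copy-Number Signature, Molecular Timing and Pericentromeric
    Expression Analysis for Pancreatic Neuroendocrine Tumors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to characterize the recurrent loss-of-heterozygosity (LOH)
    and copy-number signature of MEN1/ATRX/DAXX-mutant (MAD+) pancreatic
    neuroendocrine tumors. Calls per-chromosome copy and zygosity states from
    binned shallow whole-genome counts, times somatic mutations relative to
    LOH and genome doubling under pathologist-purity constraints, tests
    monoallelic expression with a depth-weighted bootstrap statistic, tests
    parental skewing of LOH chromosomes from trio genotypes, quantifies
    pericentromeric expression repression against fractional centromere
    distance, summarizes CENP-A ChIP peaks per cytoband, and pools
    chromosomal-instability versus metastasis association across comparative
    genomic hybridization studies with a Mantel-Haenszel odds ratio and
    Cochran's Q. Ships a synthetic-cohort generator that emulates the
    statistical structure of all inputs so the whole pipeline is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    knitr,
    mclust,
    metafor,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
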