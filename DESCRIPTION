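Package: pleiogene
Title: Gene-Level Pleiotropy and Allelic Heterogeneity from GWAS Summary Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Dissects cross-trait genetic overlap at the gene level from GWAS
    summary statistics and an LD reference panel. Implements quality control and
    allele harmonization of summary statistics, approximate conditional-and-joint
    (COJO-style) stepwise selection of independent association signals, gene
    binning with flanking windows and merging of fully overlapping genes into
    gene blocks, classification of multi-signal regions into gene-level
    pleiotropy, allelic heterogeneity, SNP-level pleiotropy and mixed cases,
    LD-corrected Brown combined gene scores with within-trait FDR adjustment,
    and haplotype analysis (four-gamete blocks, EM haplotype frequencies,
    placement of trait-associated alleles on haplotypes). A synthetic-data
    module generates reference panels, gene annotations and multi-trait summary
    statistics with planted causal structure so the whole pipeline is testable
    end to end.
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
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
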