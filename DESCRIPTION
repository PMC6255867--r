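Package: boarmix
Title: Genome-Wide Screening for Recent Pig Introgression in European Wild Boar
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for detecting recent domestic pig ancestry in wild boar
    from SNP-array genotypes. Reads and merges PLINK text PED/MAP datasets,
    applies call-rate, relatedness (identity-by-descent) and sample-size
    equalization filters, computes diversity statistics and Weir-Cockerham
    pairwise F_ST after LD pruning, performs dosage PCA with
    loading-based selection of ancestry-informative marker panels, fits a
    maximum-likelihood admixture model (binomial genotype likelihood,
    EM updates, cross-validated choice of K), and combines multiple
    analyses into a weighted consensus hybrid classification with
    per-country tallies and an east/west regional split. A synthetic-data
    module generates Balding-Nichols structured genotypes with known
    ancestry truth so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
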