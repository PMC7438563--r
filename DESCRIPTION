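Package: gocsim
Title: Simulation and Management of Genetic Diversity in Genomic Optimal
    Contribution Selection Schemes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forward-in-time simulator and analysis library for sib-testing
    breeding schemes under genomic optimal contribution (GOC) selection.
    Generates base-population genomes in mutation-drift-linkage equilibrium,
    runs SNP-BLUP selection with group-coancestry constraints under seven
    alternative relationship matrices (pedigree A, VanRaden G matrices, a
    homozygosity matrix, an angular-transform intensity matrix, a
    runs-of-homozygosity matrix, and a linkage-analysis IBD matrix), and
    computes drift-, homozygosity- and IBD-based inbreeding metrics that
    expose systematic discrepancies between heterozygosity loss and genetic
    drift induced by IBS-based diversity management.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    yaml,
    optparse,
    vcfR,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
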