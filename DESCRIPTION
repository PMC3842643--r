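Package: snptrio
Title: Parent-Offspring Tests and Quality Control for Fixed-Panel SNP Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Verifies the parentage of individuals genotyped on a fixed SNP
    panel against a pair of inbred parents. Markers are classified as
    monomorphic or polymorphic between the parents; progeny calls at
    monomorphic loci are scored 0/1/2 by the number of parental alleles
    carried, and a per-offspring similarity statistic S = (2a+b)/(2a+2b+2c)
    summarises agreement with the parents. Individuals falling below a
    similarity threshold are flagged as putative variants (outcrosses, seed
    mixtures, or handling errors) and the marker data are partitioned into
    monomorphic and polymorphic sets for downstream analyses. A built-in
    simulator of bi-parental recombinant inbred line populations under
    single-seed descent, with injectable contamination and genotyping error,
    supports end-to-end testing, and a single-marker regression scan
    demonstrates the effect of variant removal on QTL variance explained.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    vcfR,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
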