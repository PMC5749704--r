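Package: polyarray
Title: Polyploid SNP-Array Genotype Calling, Probeset QC and Diversity Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for high-density SNP genotyping arrays in polyploid crops,
    modelled on hexaploid bread wheat. Transforms two-channel allele signals
    to contrast/size space, calls genotypes per probeset with a Gaussian
    mixture model supporting an inbred penalty, two-step recalling and
    off-target-variant (null allele) detection; computes probeset quality
    metrics (call rate, HomRO, HomFLD) and the six-way Axiom-style category
    classification with a diploidization criterion; estimates marker
    diversity (polymorphism information content, simple-matching distances,
    Ward and neighbour-joining trees, presence/absence analysis of null
    alleles); prepares recombinant-inbred mapping data (segregation
    distortion filtering, cosegregation bins, genetic-map summaries); and
    applies resequencing-based SNP discovery filters, locus classification
    and array candidate selection. A synthetic-data module generates signal
    tables, diversity panels, RIL populations and variant records with known
    truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    ape,
    igraph,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    optparse,
    withr
Config/testthat/edition: 3
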