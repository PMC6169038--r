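Package: metalineage
Title: Quantifying Uncultivated Microbial Lineages Across Metagenomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A tested, reusable implementation of the computational chain used
    to quantify and characterize uncultivated pelagic bacterial lineages in
    shotgun metagenomes: screening of unassembled reads against a reduced 16S
    rRNA reference set, hierarchical taxonomic classification with identity and
    alignment-length thresholds, majority-vote contig taxonomy, rRNA-masked
    fragment recruitment with RPKG normalization, fragment-based average
    nucleotide identity (ANI) with species-level clustering, and CARD-FISH
    cell morphometrics with biomass partitioning. A synthetic-community
    generator produces reference databases, read sets with known composition,
    genome pairs at controlled divergence, and cell-size populations with
    ground-truth tables, so every stage can be validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    methods,
    Rcpp,
    stats,
    tools,
    utils,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    igraph,
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
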