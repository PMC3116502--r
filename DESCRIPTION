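Package: regshadow
Title: Phylogenetic Footprinting and Shadowing of Candidate Cis-Regulatory Regions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparative analysis of candidate cis-regulatory
    sequence around tandem gene arrays, modelled on the opsin arrays of
    African cichlid fishes. Implements region-wise Jukes-Cantor divergence
    with intron-edge masking, sliding-window detection of conserved
    non-coding elements, position-weight-matrix scanning with exact
    score-distribution p-values, shared/divergent binding-site
    classification with exact binomial tests of the divergence proportion
    against a neutral null, microRNA seed-target profiling with
    cross-species conservation filtering, haplotype-panel polymorphism
    summaries (segregating sites, nucleotide diversity, Tajima's D),
    sliding-window diversity profiles, additive-model SNP-expression
    association, and seeded synthetic-data generators that give every
    pipeline stage inputs with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    rtracklayer,
    stats,
    utils
Suggests:
    ape,
    vegan,
    vcfR,
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
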