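Package: csindel
Title: Conserved Signature Indel Detection and Phylogenetic Profiling for
    Protein Families
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Detects and classifies conserved signature indels (CSIs) in
    protein multiple sequence alignments: indel loci are found as clusters of
    overlapping gap runs, filtered by a flanking-conservation rule, and
    classified by their group specificity (group-specific, shared, or
    paired-length signatures).  Companion tools build the catalytic-domain
    phylogeny the signatures are interpreted against (pairwise maximum
    likelihood distances under the Jones-Taylor-Thornton model, neighbour
    joining, column bootstrap, midpoint rooting, monophyly reports), assign
    query proteins to their closest isozyme by local alignment against a
    labelled reference panel, and simulate protein families with planted
    clade-specific indels so that every stage is testable against exact
    ground truth.  Developed around the diacylglycerol kinase (DGK) family
    (ten vertebrate isozymes in five classes) but applicable to any labelled
    protein family alignment.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    phangorn,
    Biostrings,
    stats,
    utils
Suggests:
    withr,
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
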