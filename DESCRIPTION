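Package: genetreeviz
Title: Gene-Family Structure Comparison and Static Gene-Tree Visualization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Projects gene-family protein alignments, encoded as
    Ensembl-Compara-style CIGAR strings, onto genomic exon/intron
    structures relative to a user-chosen guide gene; classifies
    ortholog/paralog relationships from event-labelled gene trees
    (Newick/NHX); computes bidirectional identity, positivity and
    coverage statistics for homologous pairs; and renders deterministic
    static SVG gene-tree, pairwise-alignment and gene-order (synteny)
    views. Ships a seeded gene-family simulator so the whole pipeline is
    testable without external downloads, and a command-line front end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    Biostrings,
    jsonlite,
    optparse,
    rtracklayer,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    xml2
Config/testthat/edition: 3
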