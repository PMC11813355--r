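Package: symbiovar
Title: Comparative Variation Analysis of Circular Endosymbiont Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparative genomics of small circular endosymbiont
    genomes such as Buchnera aphidicola: normalization of circular start
    positions, sliding-window Nei-Li nucleotide diversity with region
    segmentation and peak detection, SNP and INDEL-region calling from
    pairwise alignments, detection and three-class classification of simple
    sequence repeats (SSRs), cross-genome SSR grouping by flanking-sequence
    similarity, neighbor-joining phylogenies from Tamura-Nei distances with
    bootstrap support, host-symbiont congruence reports, and a synthetic
    genome-set simulator with known ground truth for validating every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    ape,
    phangorn,
    igraph,
    yaml,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    rtracklayer,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
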