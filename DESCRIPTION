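Package: circmir
Title: Prediction and Annotation of miRNA Binding Sites on Circular RNAs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts microRNA binding sites on circular RNAs (circRNAs) by
    combining three independent in-package engines: an exact seed-match scanner
    (8mer/7mer-m8/7mer-A1/6mer site types), an intermolecular RNA:RNA duplex
    minimum-free-energy dynamic program over a nearest-neighbor stacking model,
    and a position-weighted gapped local aligner with G:U wobble scoring.
    Resolves circRNA exon structure from a BED/GTF pair, assembles strand-correct
    transcript sequences, maps predicted sites back to genomic coordinates,
    merges identical sites across engines into consensus interactions, and
    annotates each interaction with experimentally validated miRNA:RNA
    interactions, Argonaute CLIP peak overlap, and circBase identity. Includes a
    deterministic synthetic-fixture generator (toy genome with planted sites)
    and a command-line entry point producing the 12-column result table.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    parallel,
    jsonlite,
    Rcpp,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    rtracklayer
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
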