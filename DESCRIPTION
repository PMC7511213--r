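Package: cbei
Title: Design and Evaluation of sgRNAs for Cytosine Base Editor-Mediated
    Gene Inactivation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Designs single-guide RNA spacers whose in-window C-to-T (or
    antisense G-to-A) base edits convert codons of a coding sequence into
    premature stop codons, inactivating the gene without a double-strand
    break. Detects open reading frames on all six frames under any of 25
    NCBI genetic codes, ships 13 cytosine base editor presets with fully
    customisable PAM, spacer and editing-window parameters, verifies
    candidate spacers with a mismatch-tolerant anchor (pigeonhole)
    off-target search against arbitrary genome FASTA files with large-file
    segmentation, and evaluates the inactivation ability of editors and
    genomes across restricted search regions. Includes a synthetic
    CDS/genome generator with planted ground truth and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    optparse,
    stats,
    tools,
    utils,
    yaml
Suggests:
    ggplot2,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
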