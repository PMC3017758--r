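Package: blocktrim
Title: Entropy and Stationarity Based Trimming of Multiple Sequence Alignments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Selects phylogenetically informative columns of DNA, codon or amino
    acid multiple sequence alignments. Columns are scored with a von
    Neumann-type entropy weighted by a similarity matrix (BLOSUM target
    frequencies, DNA PAM matrices or the identity), smoothed along the
    alignment, and gathered into conserved blocks by an iterative region-merging
    rule. A second, stationarity-based trimmer removes compositionally
    heterogeneous columns using Stuart's matched-pairs test of marginal
    symmetry with an iterative add-and-remove refinement. Also provides
    RY-coding, codon translation and degenerated-codon recoding, FASTA /
    PHYLIP-sequential / NEXUS input-output with an HTML trimming report, and
    seeded simulators of informative/noise and GC-heterogeneous alignments for
    testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    ape,
    stats,
    tools,
    utils
Suggests:
    optparse,
    jsonlite,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
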