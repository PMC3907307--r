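Package: foldback
Title: Simulation and Breakpoint-Junction Analysis of Fold-Back Inverted Duplications
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Mechanistic simulation of fold-back inverted duplications
    adjacent to terminal deletions (double-strand break, 5'-3' resection,
    intrastrand annealing at short inverted homology, dicentric formation and
    breakage-fusion-bridge resolution), together with the analysis used to
    characterize such rearrangements from breakpoint junction sequences:
    split alignment and junction classification (disomy-inversion,
    inversion-telomere, inversion-translocation), microhomology and insertion
    calling, disomic-spacer measurement, array-CGH segmentation,
    discordant read-pair clustering, microsatellite parent-of-origin
    inference, and an inverted-microhomology null model with a combinatorial
    empirical p-value. All analyses run on synthetic genomes produced by the
    package's own generator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    ggplot2
Config/testthat/edition: 3
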