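Package: cpdscreen
Title: Evolutionary Screening of Compensated Pathogenic Deviations in
    Mitochondrial rRNA and Ribosomal Proteins
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Detects mammalian species that have fixed a human pathogenic
    mitochondrial rRNA allele (compensated pathogenic deviations), scores
    candidate compensatory protein positions by a conservation index
    (percentage of aligned sequences carrying the human wild-type state)
    and by structural proximity in a ribosome crystal structure, and dates
    the fixation of pathogenic and compensatory alleles on a dated species
    phylogeny under a single-gain parsimony model with loss tolerance.
    Includes generators for synthetic alignments, dated trees with tip
    states and toy coordinate files with exactly specified composition, so
    the whole screen is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    bio3d,
    Biostrings,
    jsonlite,
    phangorn,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
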