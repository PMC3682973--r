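Package: epiclades
Title: Functional Clade Classification and Annotation Rules for
    N-Acetylhexosamine 4-Epimerases
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Classifies bacterial N-acetylhexosamine 4-epimerase proteins
    into functional clades (gne/galE, gnaB, gnu, unknown) from protein
    alignments via neighbour-joining trees with bootstrap support and
    reference-anchored clade assignment. Encodes rule systems for
    recommending gene names from clade plus genomic context, for deriving
    expected gnu/gne gene presence from O-antigen repeat-unit structure,
    and for predicting the first sugar of the repeat unit; provides the
    genotype-structure concordance accounting that validates those rules,
    together with seeded simulators for protein alignments evolved along
    known trees and serogroup tables with controlled discordances.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    phangorn,
    seqinr,
    jsonlite,
    withr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr
Config/testthat/edition: 3
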