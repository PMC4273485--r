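Package: pletools
Title: Structural Annotation and Population Analysis of piggyBac-Like
    Transposable Elements
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for characterizing piggyBac-like DNA transposons and using
    their insertion sites as population-genetic markers. Locates element
    copies in genomic sequence by their terminal inverted repeats and TTAA
    target-site duplications and annotates subterminal repeats, the
    transposase open reading frame with its catalytic DDD aspartates, and
    promoter/polyadenylation signals. Builds presence/absence matrices of
    insertion sites across populations from in-silico transposon-display
    tags, computes Dice genetic similarities and UPGMA dendrograms,
    quantifies per-region sequence-variation rates among aligned element
    copies (including indel "special variation positions" and variability
    hotspots), and estimates insertion frequencies with replicate-group
    standard errors from flanking-PCR amplicon calls. Includes a synthetic
    data generator that plants element copies with known ground truth into
    simulated diploid host populations so the whole pipeline is testable
    end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
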