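Package: transfree
Title: Transgene-Freedom Verification for Genome-Edited Plant Lines
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Verifies that genome-edited plant lines are free of vector-derived
    DNA. Builds a per-position k-mer index of a transformation vector, counts
    reads from an edited line and a wild-type control that carry each position's
    k-mer, tests each position with a 2x2 G-statistic (log-likelihood ratio)
    against the chi-square 1-df threshold, and calls candidate integration
    segments that must replicate across independent sequencing runs before they
    count as evidence of integration. Orthogonal in-silico checks are included:
    tiled-PCR presence/absence over a primer panel, restriction-digest and probe
    fragment prediction, and target-site allele classification (indels, reading
    frame, complete-disruptant status) with off-target screening. A synthetic
    data generator (host genomes, annotated circular vectors, integration
    events, error-bearing shotgun reads with ground truth) makes every stage
    testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    BiocGenerics,
    jsonlite,
    yaml,
    graphics,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
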