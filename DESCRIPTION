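Package: raacdip
Title: Reduced-Alphabet Gapped-Dipeptide Features for Immunoglobulin
    Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Protein-sequence toolkit for classifying immunoglobulins from
    primary sequence alone. Maps sequences onto a five-letter reduced amino
    acid cluster (RAAC) alphabet, extracts lambda-gap dipeptide compositions
    and auto-cross covariance (ACC) physicochemical descriptors, ranks
    features by max-relevance-max-distance (MRMD), reduces greedily to a
    minimal two-feature model, and evaluates gain-ratio decision trees and
    random-forest analogues under stratified cross-validation. Includes an
    axis-aligned two-feature threshold rule for interpretation, exact and
    Hamming-tolerant motif scanning, and a seeded generator of motif-bearing
    synthetic datasets so the whole pipeline is testable without downloads.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
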