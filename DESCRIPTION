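Package: foldswitchr
Title: Fragment-Based Prediction of Fold-Switching Proteins
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scores every residue of a query protein for secondary-structure
    diversity using exact 7-mer matches against a structure-annotated sequence
    database, reduces the per-residue tracks to a four-dimensional feature
    vector (rolled diversity index, Shannon entropy, substitution score, and a
    sample-size uncertainty penalty), classifies fold-switching versus
    monomorphic proteins with a quadratic-kernel support vector machine, and
    applies proteome-scale disorder-overlap and domain-annotation filters to
    positive predictions. Includes a synthetic-data generator with planted
    ground truth so the whole pipeline is testable without external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    IRanges,
    e1071,
    zoo,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
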