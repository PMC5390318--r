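Package: oculoconcord
Title: Concordance Analysis of Matched Blood and Ocular Tissue DNA Methylation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for asking how well peripheral blood DNA methylation acts as
    a surrogate for inaccessible ocular tissues (neurosensory retina,
    RPE/choroid, optic nerve) on HM450K-like beta-value matrices from matched
    donors. Implements probe-level quality filtering, three-class methylation
    categorisation with UpSet-style disjoint overlap counts, sample-level
    Spearman concordance and hierarchical clustering, blood-variable probe
    selection with per-probe matched blood-eye correlation against a
    permutation null of unmatched pairings, paired-t similarity screening,
    PCA-based separation of tissue- versus individual-driven variation with a
    moderated-F test for tissue-specific probes, and genomic-context
    enrichment. Ships a synthetic-data generator that emulates matched
    multi-tissue methylation studies with known ground truth so every stage is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    ape,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    limma,
    optparse,
    withr
Config/testthat/edition: 3
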