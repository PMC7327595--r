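Package: p3c
Title: Entitymetric Indices for Drug-Repurposing Trend Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes windowed entitymetric indicators (Popularity, Promising,
    Prestige and Collaboration indices) for biomedical entities mentioned in a
    publication corpus, to trace how diseases, drugs and genes move in and out
    of focus around a drug of interest across its repurposing history. Includes
    a MEDLINE/PubMed XML reader, dictionary-based entity tagging over titles and
    abstracts, deterministic author keying, phase assignment by index maxima,
    maxima-interval reports, and a seeded synthetic-corpus generator with known
    ground-truth trends for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    graphics,
    grDevices,
    xml2
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
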