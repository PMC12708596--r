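Package: hsescan
Title: Detection, Classification and Ranking of Heat Shock Elements in
    Plant Promoters
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Scans promoter sequences for heat shock elements (HSEs) built
    from tandemly alternating nGAAn pentamer units, allowing a bounded
    number of substitutions in the GAA/TTC cores and bounded insertions
    between adjacent units. Detected elements are classified as canonical,
    perfect minimal, or imperfect, annotated with their distance to the
    transcription start site, and ranked by predicted functionality.
    Includes a seeded planted-motif promoter simulator and an independent
    brute-force template-expansion oracle so the scanner can be validated
    end to end without external data, plus a command-line interface for
    scan, summarize, rank and simulate workflows.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
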