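Package: fflsurv
Title: Feed-Forward Loop Analysis of Cancer Survival Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds cancer-specific survival networks from RNAi screening,
    copy-number and expression evidence; converts per-tumor missense
    mutation catalogs into network heat profiles by propagation; enumerates
    and filters feed-forward loop motifs; identifies loops enriched in
    mutation-defined patient cohorts; and tests loop status against
    survival outcome and a PAM50-derived proliferation index. A
    synthetic-data generator with planted ground truth allows the whole
    pipeline to be exercised and validated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    survival,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
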