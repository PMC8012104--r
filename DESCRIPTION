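Package: readgaze
Title: Viewing-Time Decomposition and Text-Predictability Analysis for Reading Eye Movements
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing eye-movement records from text reading.
    Decomposes per-word viewing time into first-fixation duration (FFD),
    refixation duration (RFD) and re-reading duration (RRD) from raw fixation
    logs, with the standard pre-processing filters (blinks, line edges, trial
    edges, line switches, duration bounds, word-boundary landings). Computes
    word-level predictors from n-gram count tables (log relative frequency,
    backoff surprisal) and multi-scale embedding cosine similarities
    (word-sentence, sentence-sentence, sentence-paragraph,
    paragraph-paragraph). Fits linear mixed-effects models with crossed
    participant and word random intercepts, and recursive path models with
    direct/indirect effect decomposition. Includes a fully seeded synthetic
    data generator (texts, n-gram counts, embeddings, participants, fixation
    scanpaths with injected effect structure) so the whole pipeline is
    testable by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    lme4,
    lmerTest,
    jsonlite,
    yaml,
    ggplot2,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
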