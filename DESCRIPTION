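Package: chunklab
Title: Detection and Analysis of Motor Chunks in Timestamped Action Streams
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying motor chunking in timestamped categorical
    action logs such as real-time-strategy game telemetry. Detects
    over-represented action n-grams ("chunks") with a base-rate-corrected
    binomial test and train/test data splitting, quantifies the time saved
    by chunked actions relative to same-type non-chunked baselines,
    measures behavioural sequence diversity against a permutation null,
    and provides the skill-level inferential statistics (additive two-way
    ANOVA with partial eta squared, t-tests, correlations, family-wise
    corrected planned comparisons). A synthetic event-stream simulator
    with planted chunks and ground-truth labels supports parameter
    recovery testing of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    car,
    dplyr,
    readr,
    stats,
    tibble,
    utils,
    withr
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
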