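Package: payn
Title: Positive-Unlabeled Learning for Reaction Yield Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Spy-based positive-unlabeled (PU) learning for chemical
    reaction yield data affected by reporting bias. Simulates the
    positives-only label regime found in the synthetic-chemistry
    literature from fully labeled high-throughput experimentation (HTE)
    tables, extracts reliable negatives from the unlabeled pool via the
    spy technique, estimates the SCAR label frequency, and benchmarks
    yield-regression models trained on positives-only, reliable-negative
    augmented, and fully labeled data under identical cross-validation
    splits. Includes a synthetic combinatorial HTE generator with a known
    reactivity oracle, extended-connectivity fingerprint featurization of
    reaction components, a YAML-configured pipeline, and a command-line
    entry point.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    xgboost,
    jsonlite,
    yaml
Suggests:
    ChemmineOB,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
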