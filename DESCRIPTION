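Package: faceverify
Title: Simulation and Threshold Evaluation for 1:1 Facial-Recognition
    Patient Verification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for evaluating 1:1 biometric face verification in
    clinical settings without access to patient images or a proprietary
    recognition engine.  Generates a synthetic cohort of unit-norm face
    embeddings whose genuine and impostor authentication-score
    distributions are calibrated to published per-condition score
    summaries (mask wearing, eye closure, posture, illumination),
    computes cosine-similarity authentication scores over all
    genuine/impostor pairs, derives false-acceptance / false-rejection
    curves and zero-FAR decision thresholds, and reports per-condition
    and aggregate certification rates with Welch t-tests and analytic
    rate predictions.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    parallel,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
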