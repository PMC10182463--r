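Package: semscale
Title: Semantic Scales for Language-Based Severity Assessment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Builds latent semantic analysis (LSA) word embedding spaces
    from n-gram co-occurrence counts, trains cross-validated semantic
    scales that map keyword responses to 0-10 severity ratings, and
    quantifies calibration and accuracy biases between people who
    experience violent events and people (or a computational model) who
    rate them from text. Includes a synthetic two-phase study generator
    with planted calibration shifts and severity-graded vocabularies so
    the full pipeline is reproducible without access to restricted study
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
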