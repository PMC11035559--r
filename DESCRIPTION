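Package: comorbnet
Title: Statistically Validated Comorbidity Networks from Diagnosis Registries
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds age- and gender-stratified comorbidity networks from raw
    patient diagnosis records coded in ICD-10. Patient histories are reduced to
    first-diagnosis ages, stratified into ten-year age-gender cohorts, and each
    cohort's bipartite disease-patient network is projected onto disease codes.
    Links are retained only when the observed co-occurrence count rejects an
    exact hypergeometric null that preserves code prevalences and per-patient
    diagnosis counts, with false-discovery-rate control across all tested
    pairs. Tools are included to extract and summarize the ego network of a
    focal code (by default I67.1, unruptured intracranial aneurysm), and to
    simulate synthetic diagnosis registries with known ground truth for
    calibration and power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    igraph,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
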