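Package: catmgm
Title: Moderated Mixed Graphical Network Models for Categorical Cohort Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for network analysis of categorical mental-health cohort
    data: derivation of binary and ordinal analysis variables from raw
    questionnaire items, contingency-table association statistics,
    pairwise and moderated mixed graphical models estimated by nodewise
    L1-penalised multinomial regression with extended-BIC model selection,
    nodewise predictability, expected-influence centrality, and
    nonparametric bootstrap edge stability. Includes a Gibbs sampler for
    categorical Markov random fields with known three-way interaction
    structure and a deterministic synthetic cohort generator, so the full
    pipeline can be exercised and validated without access to restricted
    participant-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    glmnet,
    Matrix,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
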