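Package: gesturemorphs
Title: Splitting Gesture Actions into Morphs by Constrained Latent Class
    Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for discovering 'morphs' -- sub-types of categorical
    gesture actions defined by non-random combinations of modifier levels
    (body part, contact point, rhythmic repetition, laterality) -- in
    ethological gesture corpora. Implements the full workflow: reading and
    validating gesture-token tables, lumping and rare-level preprocessing,
    per-action latent class analysis over one-hot coded modifiers with
    deterministic-cluster and minimum-support constraints, extraction of
    sparse assignment rules, entropy-based permutation tests of whether
    morphs reduce uncertainty about signal goal and community, and a naive
    Bayes comparison of gesture action versus morph as predictors of goal.
    Ships a synthetic-corpus generator with planted morph structure so
    every stage can be validated against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mclust,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
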