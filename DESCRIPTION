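Package: bratrelex
Title: Rule-Featured Maximum-Entropy Relation Extraction over Brat Standoff Corpora
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for extracting binary biomedical relations (variant,
    gene, disease, patient-cohort) from corpora annotated in the brat
    standoff format. Implements a dependency- and constituency-based
    feature rule set, maximum-entropy (multinomial logistic) classifiers
    fitted by L-BFGS, a non-overlapping argument-labelling dynamic
    program with top-k joint semantic typing, a semantically constrained
    sentential co-occurrence baseline, a cross-validated F-beta
    evaluation harness, and a seeded synthetic-corpus generator so the
    whole pipeline can be exercised without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
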