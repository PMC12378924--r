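Package: kganomaly
Title: Knowledge-Guided Anomaly Detection in Longitudinal Clinical Event Records
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Ontology-aware representation learning and anomaly scoring for
    patient trajectories of coded clinical events (diagnoses, medications,
    labs, procedures). Provides a knowledge base layer (is-a hierarchy
    closure, relation/type/causal matrices, graph Laplacians and Laplacian
    eigenmaps), knowledge-guided masking of implausible event co-occurrences,
    a temporal graph encoder with disentangled latent factors, constraint
    based refinement of latent states against hierarchy and causal
    precedence knowledge, Laplacian-regularized factorization of the
    patient-event occurrence matrix, and a composite anomaly-scoring
    pipeline exercised on synthetic cohorts with planted anomalies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
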