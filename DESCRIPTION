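Package: ddigauss
Title: Drug-Drug Interaction Relation Extraction with Gaussian-Noise
    Augmented Neural Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for extracting and classifying drug-drug interactions
    (DDIs) from sentence-level biomedical text in the SemEval-2013 Task 9
    corpus dialect. Implements the full pipeline: corpus reading/writing and
    validation, candidate-pair generation with entity anonymization and
    negative-instance filtering, multichannel word and relative-position
    embeddings, a multichannel piecewise convolutional network with an
    attention mechanism and a Gaussian-noise data-augmentation layer, an
    entity-marker relation head over a pluggable bidirectional encoder,
    training with validation-based early stopping, micro-averaged DDI
    evaluation with confusion-matrix reporting, and a synthetic-corpus
    generator with controlled class triggers for fully offline experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    xml2,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
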