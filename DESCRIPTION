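Package: neuralign
Title: One-to-One Alignment Between Single Neurons and Latent Model Units
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies how well individual units of a learned or constructed
    latent representation align one-to-one with single neurons recorded from a
    neural population responding to the same stimuli. Implements an
    entropy-based alignment (completeness) score computed from sparse
    encoding-model weights, the Spearman variant of the Unsupervised
    Disentanglement Ranking (UDR) over families of representations,
    correlation-ratio and unit-proportion statistics, held-out variance
    explained for encoding and decoding models, and decoding of held-out
    stimuli from one-to-one matched single neurons via minimum-cost
    assignment. Ships a synthetic-data generator that plants axis-coded
    neural populations with known ground-truth factors so the whole pipeline
    is testable without access to restricted recordings.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    glmnet,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
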