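Package: KnowShot
Title: Knowledge-Fused Few-Shot Wildlife Species Recognition with
    Open-Set Incremental Learning
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Few-shot and zero-shot recognition of wildlife species from
    camera-trap image embeddings by fusing specialist-knowledge texts
    (per-species features, names and short descriptions) with a frozen
    dual-encoder. Image embeddings are linked to an encoded knowledge
    bank through cosine similarity, and a lightweight self-attention
    multilayer-perceptron head is trained on the resulting fusion
    weights. A softmax-confidence trigger flags probable unseen or
    unknown species and drives class-incremental registration and
    retraining. Ships a deterministic mock encoder and a synthetic
    embedding-world generator so the full learn / infer / increment
    workflow is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'hash.R'
    'knowledge.R'
    'encoders.R'
    'fusion.R'
    'adapter.R'
    'train.R'
    'monitor.R'
    'synthetic.R'
    'io.R'
    'pipeline.R'
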