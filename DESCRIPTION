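Package: gpnre
Title: Sentence-Graph Pointer Networks for Biomedical Relation Extraction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Sentence-level biomedical relation extraction with dependency-parse
    sentence graphs and a graph pointer neural network (GPNN). Builds undirected
    word-piece graphs from CoNLL-U dependency parses, samples multi-hop
    breadth-first neighbor sequences per node, scores and selects the most
    relevant neighbors with LSTM pointer attention over GCN-encoded node
    features, and fuses local, convolved and contextual token features into a
    sentence representation for softmax relation classification (e.g. the
    CHEMPROT chemical-protein interaction scheme). Includes the micro-averaged
    evaluation protocol with confusion-matrix input, a trainable toy token
    encoder so the full pipeline runs without downloads or GPUs, and a
    synthetic-corpus generator that plants a graph-topological label signal for
    end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    nnet
Config/testthat/edition: 3
RoxygenNote: 7.3.3
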