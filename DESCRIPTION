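Package: seednet
Title: Seed-Term Co-Occurrence Networks for Discourse Corpora
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds seed-term semantic co-occurrence networks from document
    corpora, as used in infodemiology and health-communication research.
    Provides keyword-based corpus filtering, sentence segmentation and
    dictionary lemmatization with pluggable backends, conditional
    sentence-level co-occurrence frequencies for a set of seed lemmas,
    weighted semantic-network construction, modularity clustering via a
    resolution-parameterized Louvain optimizer, GEXF export for network
    visualization tools, and a planted-topic synthetic corpus generator with
    ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    mclust,
    stats,
    stringi,
    utils,
    xml2
Suggests:
    igraph,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
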