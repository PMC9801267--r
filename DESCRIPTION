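Package: evirank
Title: Evidence-Quality Retrieval and Reranking for Precision-Medicine Literature
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A two-stage literature retriever for precision-medicine queries
    (disease, gene variant, treatment). A fielded Okapi BM25 index with
    boolean and dis_max query scoring and weighted synonym expansion produces
    candidate articles; an evidence-quality reranker combines a least-squares
    feature model (retrieval score, text-pair score, publication type,
    citation quantile) with a trainable text-pair scorer fitted by a top-1
    expert-in-the-loop active learning strategy. Includes TREC-style
    evaluation (P@10, R-precision, NDCG and inferred NDCG under standard and
    exponential gains), readers and writers for topic, qrels and run files,
    and a synthetic benchmark generator with a simulated expert annotator so
    the whole pipeline is testable without external corpora.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    jsonlite,
    xml2,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
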