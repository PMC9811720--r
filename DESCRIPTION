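Package: pmretrieve
Title: Two-Stage Hybrid Retrieval for Precision-Medicine Literature
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A two-stage retrieval pipeline for biomedical literature tailored
    to precision-medicine patient cases (disease, gene variant, demographic).
    Stage one scores documents with an extended BM25 composite made of an
    abstract score, a controlled-vocabulary wordlist score, and a disease-gene
    co-word score, fused by max-min normalization. Stage two compresses
    abstracts to a fixed token budget by k-means clustering of sentence
    embeddings, scores query-document pairs with a pluggable similarity
    backend, and re-ranks by the sum of normalized scores. Includes readers
    and writers for MEDLINE-flavoured XML, a JSONL collection dialect, TREC
    topics, qrels and run files; demographic (age and gender) extraction with
    MeSH fallback; query expansion from a user-supplied synonym table;
    trec_eval-compatible evaluation (P@k, R-Prec, MAP, NDCG, PR curves); and a
    synthetic fixture generator with planted relevance structure for
    self-contained testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    xml2
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
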