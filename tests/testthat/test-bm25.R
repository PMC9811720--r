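four_doc_index <- function() {
  # df("q") = 1 among 4 docs; doc 1 has f = 2 and dl = avgdl = 8
  build_index(list(
    document("1", abstract = paste(c("q", "q", rep("x", 6)), collapse = " ")),
    document("2", abstract = paste(rep("y", 8), collapse = " ")),
    document("3", abstract = paste(rep("z", 8), collapse = " ")),
    document("4", abstract = paste(rep("w", 8), collapse = " "))))
}

test_that("idf is ln(n/df) with zero for absent and ubiquitous tokens", {
  idx <- four_doc_index()
  expect_equal(idf("q", "abstract", idx), log(4), tolerance = 1e-12)
  expect_identical(idf("nosuchtoken", "abstract", idx), 0)
  # token in every document
  idx2 <- build_index(list(document("1", abstract = "a b"),
                           document("2", abstract = "a c")))
  expect_identical(idf("a", "abstract", idx2), 0)
})

test_that("abstract score matches the hand-evaluated closed form", {
  idx <- four_doc_index()
  tp <- topic("t", "q", genes = "absentgene")
  # IDF = ln 4; f = 2, dl = avgdl: ln4 * (2 * 2.2) / (2 + 1.2) = 1.906155
  expect_equal(abstract_score(tp, "1", idx), log(4) * 4.4 / 3.2,
               tolerance = 1e-9)
  expect_equal(abstract_score(tp, "1", idx), 1.906155, tolerance = 1e-6)
  # no query token in the abstract
  expect_identical(abstract_score(tp, "2", idx), 0)
  # saturation: contribution approaches IDF * (k1 + 1) for large f
  big <- build_index(list(
    document("1", abstract = paste(rep("q", 5000), collapse = " ")),
    document("2", abstract = paste(rep("y", 5000), collapse = " ")),
    document("3", abstract = paste(rep("z", 5000), collapse = " ")),
    document("4", abstract = paste(rep("w", 5000), collapse = " "))))
  expect_equal(abstract_score(tp, "1", big), log(4) * 2.2, tolerance = 1e-3)
  expect_lt(abstract_score(tp, "1", big), log(4) * 2.2)
})

test_that("wordlist score saturates the summed IDF mass", {
  # df_wordlist("q") = 1 of 4; dwl = avgdwl
  idx <- build_index(list(
    document("1", abstract = "x", keywords = c("q", "a")),
    document("2", abstract = "x", keywords = c("b", "c")),
    document("3", abstract = "x", keywords = c("d", "e")),
    document("4", abstract = "x", keywords = c("f", "g"))))
  tp <- topic("t", "q", genes = "absentgene")
  tfw <- log(4)
  expect_equal(wordlist_score(tp, "1", idx), tfw * 2.2 / (tfw + 1.2),
               tolerance = 1e-9)
  expect_equal(wordlist_score(tp, "1", idx), 1.179235, tolerance = 1e-6)
  expect_identical(wordlist_score(tp, "2", idx), 0)
  # empty wordlist
  idx0 <- build_index(list(document("1", abstract = "q x")))
  expect_identical(wordlist_score(tp, "1", idx0), 0)
  # monotonicity in tfw: doubling the IDF mass strictly increases WS
  f <- function(tfw) tfw * 2.2 / (tfw + 1.2)
  expect_gt(f(2 * log(4)), f(log(4)))
})

test_that("co-word score requires disease-gene co-occurrence and sums genes", {
  mk <- function(abstracts, keywords = NULL) {
    build_index(lapply(seq_along(abstracts), function(i) {
      document(as.character(i), abstract = abstracts[[i]],
               keywords = if (is.null(keywords)) character(0)
                          else keywords[[i]])
    }))
  }
  # disease absent from the document -> 0
  idx <- mk(c("g1 x", "y", "z", "w"))
  expect_identical(coword_score(topic("t", "dis", "g1"), "1", idx), 0)
  # disease + one gene with df = 1 of 4 -> ln 4
  idx <- mk(c("dis g1 x", "y", "z", "w"))
  expect_equal(coword_score(topic("t", "dis", "g1"), "1", idx), log(4),
               tolerance = 1e-9)
  # two qualifying genes with IDFs ln4 and ln2 -> ln4 + ln2
  idx <- mk(c("dis g1 g2", "g2 y", "z", "w"))
  expect_equal(coword_score(topic("t", "dis", c("g1", "g2")), "1", idx),
               log(4) + log(2), tolerance = 1e-9)
  # union reading: disease in abstract, gene only in the wordlist qualifies
  idx <- mk(c("dis x", "y", "z", "w"),
            keywords = list("g1", character(0), character(0), character(0)))
  expect_equal(coword_score(topic("t", "dis", "g1"), "1", idx), log(4),
               tolerance = 1e-9)
})

test_that("max-min normalization hits endpoints and handles degeneracy", {
  expect_equal(minmax_normalize(c(2, 4, 6)), c(0, 0.5, 1))
  expect_identical(minmax_normalize(c(3, 3, 3)), c(0, 0, 0))
  expect_error(minmax_normalize(numeric(0)), "empty")
  for (i in 1:20) {
    x <- rnorm(sample(2:30, 1))
    nx <- minmax_normalize(x)
    expect_true(all(nx >= 0 & nx <= 1))
    expect_identical(nx[which.min(x)], 0)
    expect_identical(nx[which.max(x)], 1)
  }
})

test_that("stage-1 ranking is complete, tie-broken by pmid, and truncated", {
  docs <- lapply(1:5, function(i) {
    document(as.character(i), abstract = paste("filler text", i))
  })
  idx <- build_index(docs)
  tp <- topic("t", "filler", "nogene")
  out <- stage1_retrieve(tp, idx, k = 1000)
  expect_identical(nrow(out), 5L)
  expect_identical(out$rank, 1:5)
  # all raw sums equal (identical docs up to a unique token) -> pmid order
  expect_true(all(diff(as.integer(out$pmid[out$raw_sum == max(out$raw_sum)]))
                  > 0))
  out2 <- stage1_retrieve(tp, idx, k = 3)
  expect_identical(nrow(out2), 3L)
  expect_true(all(out$norm_score >= 0 & out$norm_score <= 1))
})

test_that("3-doc ranking matches independent hand scoring", {
  docs <- list(document("a", abstract = "q q q x y"),
               document("b", abstract = "q x y z w"),
               document("c", abstract = "x y z w v"))
  idx <- build_index(docs)
  tp <- topic("t", "q", "nogene")
  out <- stage1_retrieve(tp, idx)
  ab <- list(c("q", "q", "q", "x", "y"), c("q", "x", "y", "z", "w"),
             c("x", "y", "z", "w", "v"))
  manual <- vapply(1:3, function(i) oracle_as("q", i, ab), 0)
  expect_identical(out$pmid, c("a", "b", "c")[order(-manual)])
  expect_equal(out$raw_sum, sort(manual, decreasing = TRUE),
               tolerance = 1e-9)
})

test_that("b1 = 0 removes document-length dependence", {
  docs <- list(document("1", abstract = "q x"),
               document("2", abstract = paste(c("q", rep("pad", 60)),
                                              collapse = " ")),
               document("3", abstract = "y y"))
  idx <- build_index(docs)
  tp <- topic("t", "q", "nogene")
  p <- scoring_params(b1 = 0)
  expect_equal(abstract_score(tp, "1", idx, p), abstract_score(tp, "2", idx, p),
               tolerance = 1e-12)
  expect_false(isTRUE(all.equal(abstract_score(tp, "1", idx),
                                abstract_score(tp, "2", idx))))
})

test_that("ranking is invariant under positive affine transform of raw_sum", {
  set.seed(11)
  corp <- random_oracle_corpus(12)
  idx <- build_index(corp$collection)
  out <- stage1_retrieve(corp$topic, idx)
  shifted <- 3.7 * out$raw_sum + 2.5
  expect_identical(order(-shifted, out$pmid), order(-out$raw_sum, out$pmid))
  expect_equal(minmax_normalize(shifted), out$norm_score, tolerance = 1e-12)
})

test_that("avgdl/avgdwl overrides shift the length normalization", {
  idx <- four_doc_index()
  tp <- topic("t", "q", "nogene")
  base <- abstract_score(tp, "1", idx)
  longer <- abstract_score(tp, "1", idx,
                           scoring_params(avgdl_override = 85))
  # dl/avgdl shrinks -> denominator shrinks -> score grows
  expect_gt(longer, base)
})
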