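small_fixture <- function(seed = 5) {
  generate_fixture(fixture_spec(n_docs = 60, n_topics = 2,
                                n_relevant_per_topic = 5, vocab_size = 120,
                                seed = seed))
}

test_that("pair scorers stay in [0,1] and respect the token cap", {
  cs <- constant_scorer(0.5)
  expect_identical(cs$score("any query", "any text"), 0.5)
  ov <- overlap_scorer()
  expect_identical(ov$score("a b", "c d"), 0)
  expect_identical(ov$score("a b", "a b"), 1)
  expect_equal(ov$score("a b c", "a x y"), 1 / 5)
  expect_identical(ov$score("", "a"), 0)
  # cap: tokens beyond max_len are invisible to the scorer
  capped <- overlap_scorer(max_len = 2)
  expect_identical(capped$score("a b", "x y a"), 0)
})

test_that("query text assembles disease, genes, demographic in order", {
  tp <- topic("2017-1", "Liposarcoma", "CDK4 (Amplification)",
              "38-year-old male")
  expect_identical(query_text(tp),
                   "liposarcoma cdk4 amplification middle age male")
})

test_that("score_pairs produces one bounded similarity per candidate", {
  fx <- small_fixture()
  idx <- build_index(fx$collection)
  tp <- expand_topic(fx$topics[[1]], fx$expansion_table)
  cand <- stage1_retrieve(tp, idx, k = 15)
  sims <- score_pairs(tp, cand, idx, constant_scorer(0.5))
  expect_identical(unname(sims), rep(0.5, 15))
  expect_identical(names(sims), cand$pmid)
  sims2 <- score_pairs(tp, cand, idx, overlap_scorer())
  expect_true(all(sims2 >= 0 & sims2 <= 1))
  # empty candidate list
  empty <- score_pairs(tp, cand[0, ], idx, overlap_scorer())
  expect_length(empty, 0)
  # a scorer failure names the pmid
  bad <- pmretrieve:::pair_scorer(function(q, t) NaN, 512L)
  expect_error(score_pairs(tp, cand[1, ], idx, bad), cand$pmid[1])
})

test_that("hand-set overlaps on a 2-doc fixture match direct computation", {
  docs <- list(document("1", title = "t", abstract = "melanoma braf response."),
               document("2", title = "t", abstract = "unrelated words here."))
  idx <- build_index(docs)
  tp <- topic("t1", "melanoma", "BRAF")
  cand <- stage1_retrieve(tp, idx, k = 2)
  sims <- score_pairs(tp, cand, idx, overlap_scorer())
  # query tokens {melanoma, braf}; doc1 {melanoma, braf, response} -> 2/3
  expect_equal(unname(sims["1"]), 2 / 3, tolerance = 1e-12)
  expect_identical(unname(sims["2"]), 0)
})

test_that("constant-scorer fusion reproduces the stage-1 order", {
  fx <- small_fixture()
  idx <- build_index(fx$collection)
  tp <- expand_topic(fx$topics[[1]], fx$expansion_table)
  cand <- stage1_retrieve(tp, idx, k = 30)
  sims <- score_pairs(tp, cand, idx, constant_scorer(0.7))
  fused <- fuse_and_rank(cand, sim_abstract = sims)
  expect_identical(fused$pmid, cand$pmid)
  expect_identical(fused$rank, cand$rank)
  expect_equal(fused$fused_score, cand$norm_score, tolerance = 1e-12)
})

test_that("exact cancellation yields all-equal fused scores in pmid order", {
  fx <- small_fixture()
  idx <- build_index(fx$collection)
  tp <- expand_topic(fx$topics[[1]], fx$expansion_table)
  cand <- stage1_retrieve(tp, idx, k = 20)
  sims <- stats::setNames(1 - cand$norm_score, cand$pmid)
  fused <- fuse_and_rank(cand, sim_abstract = sims)
  expect_equal(fused$fused_score, rep(1, 20), tolerance = 1e-12)
  expect_identical(fused$pmid, sort(cand$pmid))
})

test_that("abstract+title fusion sums the normalized fields, hand-checked", {
  cand <- data.frame(pmid = c("1", "2", "3", "4"),
                     raw_sum = c(4, 3, 2, 1),
                     norm_score = c(1, 2 / 3, 1 / 3, 0),
                     rank = 1:4, stringsAsFactors = FALSE)
  sa <- c(`1` = 0.1, `2` = 0.9, `3` = 0.5, `4` = 0.1)
  st <- c(`1` = 0.2, `2` = 0.2, `3` = 0.8, `4` = 0.4)
  fused <- fuse_and_rank(cand, sim_abstract = sa, sim_title = st)
  # minmax(sa) = 0, 1, .5, 0 ; minmax(st) = 0, 0, 1, 1/3
  want <- c(`1` = 1 + 0 + 0, `2` = 2 / 3 + 1 + 0,
            `3` = 1 / 3 + 0.5 + 1, `4` = 0 + 0 + 1 / 3)
  want_order <- names(sort(want, decreasing = TRUE))
  expect_identical(fused$pmid, want_order)
  expect_equal(fused$fused_score, unname(sort(want, decreasing = TRUE)),
               tolerance = 1e-12)
  expect_identical(fused$rank, 1:4)
  expect_error(fuse_and_rank(cand), "at least one")
  # fused score bounded by 1 + number of enabled fields
  expect_true(all(fused$fused_score <= 3))
})

pm_case_topics <- function() {
  list(topic("2017-1", "Liposarcoma", "CDK4 (Amplification)",
             "38-year-old male"),
       topic("2017-2", "Liposarcoma", "MDM2 (Amplification)",
             "29-year-old male"),
       topic("2018-1", "Melanoma", "BRAF (V600E)", "64-year-old male"),
       topic("2017-12", "Colon cancer", "BRAF (V600E)", "50-year-old female"),
       topic("2019-9", "Gastric cancer", "ERBB2 (Amplification)",
             "64-year-old female"))
}

test_that("training pairs mirror the structured head + summary layout", {
  tps <- pm_case_topics()
  doc <- document("10101594",
                  title = "CDK4 amplification in liposarcoma",
                  abstract = paste("A 38-year-old male with liposarcoma and",
                                   "cdk4 amplification. Treatment response",
                                   "was assessed over twelve months."))
  idx <- build_index(list(doc))
  qrels <- data.frame(topic_id = "2017-1", pmid = "10101594", grade = 2L,
                      stringsAsFactors = FALSE)
  pairs <- make_training_pairs(tps, qrels, idx)
  expect_identical(names(pairs),
                   c("pmid", "doc_text", "query_text", "topic_id", "label"))
  pos <- pairs[pairs$label == 1L, ]
  neg <- pairs[pairs$label == 0L, ]
  expect_identical(nrow(pos), 1L)
  # structured head: genes, human element, demographic category, gender
  expect_match(pos$doc_text, "^cdk4 amplification human middle age male \\+ ")
  expect_identical(pos$query_text,
                   "liposarcoma cdk4 amplification middle age male")
  expect_identical(pos$topic_id, "2017-1")
  # the only sibling shares the disease with a different gene
  expect_identical(nrow(neg), 1L)
  expect_identical(neg$topic_id, "2017-2")
  expect_identical(neg$doc_text, pos$doc_text)
  expect_identical(neg$query_text,
                   "liposarcoma mdm2 amplification young male")
})

test_that("negatives differ from positives in exactly one slot", {
  tps <- pm_case_topics()
  by_id <- stats::setNames(tps, vapply(tps, `[[`, "", "topic_id"))
  docs <- lapply(seq_along(tps), function(i) {
    document(sprintf("9%07d", i),
             abstract = sprintf("A %s with %s and %s. More text follows here.",
                                tps[[i]]$demographic, tps[[i]]$disease,
                                paste(tokenize(tps[[i]]$genes), collapse = " ")))
  })
  idx <- build_index(docs)
  qrels <- data.frame(topic_id = vapply(tps, `[[`, "", "topic_id"),
                      pmid = vapply(docs, `[[`, "", "pmid"),
                      grade = 2L, stringsAsFactors = FALSE)
  pairs <- make_training_pairs(tps, qrels, idx)
  neg <- pairs[pairs$label == 0L, ]
  expect_gt(nrow(neg), 0)
  for (r in seq_len(nrow(neg))) {
    own <- pairs[pairs$label == 1L & pairs$pmid == neg$pmid[r], ]
    own_tp <- by_id[[own$topic_id]]
    sib_tp <- by_id[[neg$topic_id[r]]]
    same_disease <- identical(tokenize(own_tp$disease),
                              tokenize(sib_tp$disease))
    same_genes <- identical(sort(tokenize(own_tp$genes)),
                            sort(tokenize(sib_tp$genes)))
    expect_true(xor(same_disease, same_genes))
  }
  # a topic with no sibling yields positives only
  expect_false(any(neg$topic_id == "2019-9"))
  expect_true(any(pairs$label == 1L & pairs$topic_id == "2019-9"))
})

test_that("training pairs round-trip through TSV", {
  tps <- pm_case_topics()[1:2]
  doc <- document("777", abstract = "A 38-year-old male case. Full details.")
  idx <- build_index(list(doc))
  qrels <- data.frame(topic_id = "2017-1", pmid = "777", grade = 2L,
                      stringsAsFactors = FALSE)
  pairs <- make_training_pairs(tps, qrels, idx)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_training_pairs(pairs, path)
  back <- read_training_pairs(path)
  expect_equal(back, pairs, ignore_attr = TRUE)
})
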