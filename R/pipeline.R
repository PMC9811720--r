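#' Run the full two-stage retrieval pipeline
#'
#' For each topic: expand the query morphemes from the synonym table (always
#' appending the "human" element), rank the whole collection with the BM25
#' composite and keep the top `k` candidates (stage 1), compress each
#' candidate abstract to the token budget by cluster-based extraction, score
#' (query, abstract) — and optionally (query, title) — pairs with the
#' similarity backend, max-min normalize each similarity field over the
#' candidate pool, add it to the normalized stage-1 score, and re-sort
#' (stage 2).
#'
#' @param collection a `pm_collection` (or a prebuilt index via `index`).
#' @param topics list of [topic()]s.
#' @param expansion_table a [read_expansion_table()] result.
#' @param params [scoring_params()].
#' @param k candidate depth for stage 1 (default 1000).
#' @param scorer pair scorer for stage 2; `NULL` skips reranking.
#' @param fields character subset of c("abstract", "title") to rerank with.
#' @param embedder sentence embedder for abstract extraction.
#' @param n_clusters,budget,seed extraction configuration.
#' @param title_max_len token cap for title pair scoring (default 128).
#' @param run_tag tag written into the run entries.
#' @param index optional prebuilt [build_index()] (skips indexing).
#' @return list with `stage1` and `final` run data.frames (topic_id, pmid,
#'   rank, score, run_tag), plus `candidates` (per-topic scored frames).
#' @export
run_pipeline <- function(collection, topics,
                         expansion_table = empty_expansion_table(),
                         params = scoring_params(), k = 1000L,
                         scorer = overlap_scorer(),
                         fields = "abstract",
                         embedder = hashing_embedder(), n_clusters = 4L,
                         budget = 512L, seed = 1L, title_max_len = 128L,
                         run_tag = "pmretrieve", index = NULL) {
  stopifnot(all(fields %in% c("abstract", "title")))
  if (is.null(index)) index <- build_index(collection)
  extract_cache <- new.env(parent = emptyenv())
  stage1_rows <- list()
  final_rows <- list()
  cand_list <- list()

  title_scorer <- if (!is.null(scorer)) {
    pair_scorer(scorer$score, title_max_len, scorer$deterministic)
  }

  for (tp in topics) {
    tp <- expand_topic(tp, expansion_table)
    cand <- stage1_retrieve(tp, index, params, k = k)
    stage1_rows[[tp$topic_id]] <-
      data.frame(topic_id = tp$topic_id, pmid = cand$pmid, rank = cand$rank,
                 score = cand$norm_score, run_tag = paste0(run_tag, "_stage1"),
                 stringsAsFactors = FALSE)
    if (!is.null(scorer) && length(fields) > 0L) {
      sim_ab <- NULL
      sim_ti <- NULL
      if ("abstract" %in% fields) {
        for (p in cand$pmid) {
          if (is.null(extract_cache[[p]])) {
            extract_cache[[p]] <- extract_abstract(
              index$docs[[p]]$abstract, embedder = embedder,
              n_clusters = n_clusters, budget = budget, seed = seed)
          }
        }
        sim_ab <- score_pairs(tp, cand, index, scorer, field = "abstract",
                              extracts = as.list(extract_cache))
      }
      if ("title" %in% fields) {
        sim_ti <- score_pairs(tp, cand, index, title_scorer, field = "title")
      }
      cand <- fuse_and_rank(cand, sim_abstract = sim_ab, sim_title = sim_ti)
      score_col <- cand$fused_score
    } else {
      score_col <- cand$norm_score
    }
    cand_list[[tp$topic_id]] <- cand
    final_rows[[tp$topic_id]] <-
      data.frame(topic_id = tp$topic_id, pmid = cand$pmid, rank = cand$rank,
                 score = score_col, run_tag = run_tag,
                 stringsAsFactors = FALSE)
  }
  list(stage1 = do.call(rbind, c(stage1_rows, make.row.names = FALSE)),
       final = do.call(rbind, c(final_rows, make.row.names = FALSE)),
       candidates = cand_list)
}
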