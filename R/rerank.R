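#' Pair scorers for query-document similarity
#'
#' A pair scorer maps a (query text, document text) pair to a similarity in
#' `[0, 1]`, truncating each input to `max_len` whitespace tokens first
#' (512 for abstracts, 128 for titles in the shipped configs). Two reference
#' backends are provided: [constant_scorer()] returns a fixed value (useful
#' for neutrality checks — reranking with it must reproduce the stage-1
#' order), and [overlap_scorer()] returns the Jaccard overlap of the
#' normalized token sets. A fine-tuned transformer pair classifier with a
#' sigmoid head plugs in through the same contract.
#'
#' @param value the constant similarity returned.
#' @param max_len token cap applied to each input before scoring.
#' @return an object of class `pm_pair_scorer` with elements
#'   `score(query, text)`, `max_len`, `deterministic`.
#' @export
constant_scorer <- function(value = 0.5, max_len = 512L) {
  stopifnot(value >= 0, value <= 1)
  pair_scorer(function(query, text) value, max_len)
}

#' @rdname constant_scorer
#' @export
overlap_scorer <- function(max_len = 512L) {
  pair_scorer(function(query, text) {
    q <- unique(truncate_tokens(query, max_len))
    d <- unique(truncate_tokens(text, max_len))
    if (length(q) == 0L || length(d) == 0L) return(0)
    length(intersect(q, d)) / length(union(q, d))
  }, max_len)
}

pair_scorer <- function(fun, max_len, deterministic = TRUE) {
  structure(list(score = fun, max_len = as.integer(max_len),
                 deterministic = deterministic),
            class = "pm_pair_scorer")
}

truncate_tokens <- function(text, max_len) {
  toks <- tokenize(text)
  toks[seq_len(min(length(toks), max_len))]
}

#' Query text for similarity matching
#'
#' Space-joined lowercase assembly in the order disease, genes, demographic
#' category tokens, gender — mirroring the query strings the training pairs
#' use ("liposarcoma cdk4 amplification middle age male").
#'
#' @param tp a [topic()].
#' @return character scalar.
#' @export
query_text <- function(tp) {
  parts <- c(tokenize(tp$disease), unlist(lapply(tp$genes, tokenize)))
  if (nzchar(tp$demographic)) {
    prof <- parse_demographic(tp$demographic)
    if (prof$age_category != "Unknown") {
      parts <- c(parts, tokenize(prof$age_category))
    }
    if (prof$gender != "Unknown") parts <- c(parts, tolower(prof$gender))
  }
  paste(parts, collapse = " ")
}

#' Score query-document pairs over a candidate list
#'
#' Computes one similarity per stage-1 candidate for the named field. For
#' `field = "abstract"` the document text is the cluster-extracted abstract
#' (computed on the fly with `embedder` when `extracts` is not supplied);
#' for `field = "title"` it is the title.
#'
#' @param tp a [topic()].
#' @param candidates a [stage1_retrieve()] data.frame.
#' @param index the [build_index()] result the candidates came from.
#' @param scorer a pair scorer.
#' @param field `"abstract"` or `"title"`.
#' @param extracts optional named list pmid -> `pm_extracted`, precomputed.
#' @param embedder embedder used when extracting on the fly.
#' @param n_clusters,budget,seed extraction configuration.
#' @return named numeric vector pmid -> similarity in `[0, 1]`.
#' @export
score_pairs <- function(tp, candidates, index, scorer,
                        field = c("abstract", "title"), extracts = NULL,
                        embedder = hashing_embedder(), n_clusters = 4L,
                        budget = 512L, seed = 1L) {
  field <- match.arg(field)
  qtext <- query_text(tp)
  sims <- vapply(candidates$pmid, function(p) {
    doc <- index$docs[[p]]
    text <- if (field == "title") {
      doc$title
    } else if (!is.null(extracts) && !is.null(extracts[[p]])) {
      extracted_text(extracts[[p]])
    } else {
      extracted_text(extract_abstract(doc$abstract, embedder = embedder,
                                      n_clusters = n_clusters,
                                      budget = budget, seed = seed))
    }
    s <- scorer$score(qtext, text)
    if (!is.finite(s) || s < 0 || s > 1) {
      stop("pair scorer returned an invalid similarity for pmid ", p)
    }
    s
  }, 0)
  stats::setNames(sims, candidates$pmid)
}

#' Fuse stage-1 and similarity scores into the final ranking
#'
#' Each enabled similarity field is max-min normalized over the candidate
#' pool and added to the stage-1 `norm_score`; the list is re-sorted in
#' descending fused order with ties broken by ascending pmid, and ranks are
#' reassigned 1..k. All addends carry equal weight.
#'
#' @param candidates a [stage1_retrieve()] data.frame.
#' @param sim_abstract,sim_title optional named vectors pmid -> similarity;
#'   at least one must be supplied.
#' @return the candidates data.frame with `sim_abstract`/`sim_title`,
#'   `fused_score`, and updated `rank`.
#' @export
fuse_and_rank <- function(candidates, sim_abstract = NULL, sim_title = NULL) {
  if (is.null(sim_abstract) && is.null(sim_title)) {
    stop("at least one similarity field must be supplied")
  }
  fused <- candidates$norm_score
  if (!is.null(sim_abstract)) {
    candidates$sim_abstract <- unname(sim_abstract[candidates$pmid])
    fused <- fused + minmax_normalize(candidates$sim_abstract)
  }
  if (!is.null(sim_title)) {
    candidates$sim_title <- unname(sim_title[candidates$pmid])
    fused <- fused + minmax_normalize(candidates$sim_title)
  }
  candidates$fused_score <- fused
  ord <- order(-fused, candidates$pmid)
  out <- candidates[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  row.names(out) <- NULL
  out
}

#' Generate labelled sentence-pair training samples
#'
#' For each topic, every relevant document (grade >= threshold) yields one
#' positive pair: the document rendered as a structured head (its topic's
#' gene morphemes, the "human" element, and the document's demographic
#' category and gender, lowercased) joined with " + " to the document
#' summary, against the topic's own query text, label 1. Negatives reuse the
#' same document text against the query of a sibling topic that shares the
#' disease but differs in gene, or shares a gene but differs in disease —
#' so every negative's query differs from the positive's in exactly one of
#' the disease/gene slots. Topics without siblings contribute positives
#' only.
#'
#' @param topics list of [topic()]s.
#' @param qrels qrels data.frame from [read_qrels()].
#' @param index a [build_index()] over the collection.
#' @param mesh_map demographic MeSH fallback map.
#' @param embedder,budget,seed summary extraction configuration.
#' @param min_grade relevance threshold for positives (default 1).
#' @return data.frame with columns pmid, doc_text, query_text, topic_id,
#'   label (in that order).
#' @export
make_training_pairs <- function(topics, qrels, index,
                                mesh_map = default_mesh_map(),
                                embedder = hashing_embedder(),
                                budget = 512L, seed = 1L, min_grade = 1L) {
  topics <- unname(topics)
  ids <- vapply(topics, `[[`, "", "topic_id")
  diseases <- vapply(topics, function(t) {
    paste(tokenize(t$disease), collapse = " ")
  }, "")
  gene_sets <- lapply(topics, function(t) {
    sort(unique(unlist(lapply(t$genes, tokenize))))
  })
  siblings <- lapply(seq_along(topics), function(i) {
    same_disease <- diseases == diseases[i]
    same_gene_set <- vapply(gene_sets, identical, TRUE, y = gene_sets[[i]])
    # sibling differs in exactly one slot: same disease with a different
    # gene, or a different disease with the identical gene
    hits <- (same_disease & !same_gene_set) | (!same_disease & same_gene_set)
    setdiff(which(hits), i)
  })
  rows <- list()
  for (i in seq_along(topics)) {
    tp <- topics[[i]]
    rel <- qrels[qrels$topic_id == tp$topic_id & qrels$grade >= min_grade, ]
    for (p in rel$pmid) {
      doc <- index$docs[[p]]
      if (is.null(doc)) next
      prof <- demographic_profile(
        document(p, title = doc$title, abstract = doc$abstract), mesh_map)
      head_toks <- c(unlist(lapply(tp$genes, tokenize)), "human")
      if (prof$age_category != "Unknown") {
        head_toks <- c(head_toks, tokenize(prof$age_category))
      }
      if (prof$gender != "Unknown") {
        head_toks <- c(head_toks, tolower(prof$gender))
      }
      summary <- extracted_text(extract_abstract(doc$abstract,
                                                 embedder = embedder,
                                                 budget = budget,
                                                 seed = seed))
      doc_text <- paste(paste(head_toks, collapse = " "), "+", summary)
      rows[[length(rows) + 1L]] <-
        data.frame(pmid = p, doc_text = doc_text, query_text = query_text(tp),
                   topic_id = tp$topic_id, label = 1L,
                   stringsAsFactors = FALSE)
      for (j in siblings[[i]]) {
        rows[[length(rows) + 1L]] <-
          data.frame(pmid = p, doc_text = doc_text,
                     query_text = query_text(topics[[j]]),
                     topic_id = ids[j], label = 0L,
                     stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(pmid = character(0), doc_text = character(0),
                      query_text = character(0), topic_id = character(0),
                      label = integer(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

#' Write / read training pairs as TSV
#'
#' Column order pmid, doc_text, query_text, topic_id, label; tab-separated
#' with a header line; round-trips exactly.
#'
#' @param pairs a [make_training_pairs()] data.frame.
#' @param path file path.
#' @export
write_training_pairs <- function(pairs, path) {
  utils::write.table(pairs, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' @rdname write_training_pairs
#' @export
read_training_pairs <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    colClasses = c("character", "character", "character",
                                   "character", "integer"),
                    stringsAsFactors = FALSE, quote = "")
}
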