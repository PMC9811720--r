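#' Scoring parameters for the BM25 composite
#'
#' Saturation (`k1`, `k2`) and length-normalization (`b1`, `b2`) factors for
#' the abstract and wordlist scores. Defaults are the conventional 1.2 / 0.75.
#' `avgdl` / `avgdwl` overrides replace the corpus-derived averages (abstract
#' field and wordlist field respectively) when positive values are given.
#'
#' @param k1,k2 non-negative saturation factors.
#' @param b1,b2 length-normalization factors in `[0, 1]`.
#' @param avgdl_override,avgdwl_override optional positive reals.
#' @return an object of class `pm_params`.
#' @export
scoring_params <- function(k1 = 1.2, k2 = 1.2, b1 = 0.75, b2 = 0.75,
                           avgdl_override = NULL, avgdwl_override = NULL) {
  stopifnot(k1 >= 0, k2 >= 0, b1 >= 0, b1 <= 1, b2 >= 0, b2 <= 1)
  if (!is.null(avgdl_override)) stopifnot(avgdl_override > 0)
  if (!is.null(avgdwl_override)) stopifnot(avgdwl_override > 0)
  structure(list(k1 = k1, k2 = k2, b1 = b1, b2 = b2,
                 avgdl_override = avgdl_override,
                 avgdwl_override = avgdwl_override),
            class = "pm_params")
}

#' Build the retrieval index over a collection
#'
#' For each document, tokenizes the abstract field (title concatenated with
#' abstract) and the wordlist (chemicals + MeSH headings + keywords), and
#' accumulates document frequencies per field plus the average field lengths
#' `avgdl` and `avgdwl`. Documents with an absent keyword (or any other) list
#' simply contribute a shorter wordlist; they still count in the `avgdwl`
#' denominator.
#'
#' @param collection a `pm_collection` from [read_collection()] or a list of
#'   [document()]s.
#' @return an object of class `pm_index` with elements `n_docs`,
#'   `df_abstract`, `df_wordlist` (named integer vectors token -> document
#'   frequency), `avgdl`, `avgdwl`, and per-document token tables.
#' @export
build_index <- function(collection) {
  collection <- check_collection(unname(as.list(collection)))
  pmids <- vapply(collection, `[[`, "", "pmid")
  docs <- lapply(collection, function(d) {
    ab_tokens <- tokenize(paste(d$title, d$abstract))
    wl <- build_wordlist(d)
    list(pmid = d$pmid,
         tf_abstract = table_int(ab_tokens),
         tf_wordlist = table_int(wl$terms),
         dl = length(ab_tokens),
         dwl = wl$dwl,
         title = d$title,
         abstract = d$abstract)
  })
  names(docs) <- pmids
  df_abstract <- df_count(lapply(docs, function(d) names(d$tf_abstract)))
  df_wordlist <- df_count(lapply(docs, function(d) names(d$tf_wordlist)))
  structure(list(n_docs = length(docs),
                 df_abstract = df_abstract,
                 df_wordlist = df_wordlist,
                 avgdl = mean(vapply(docs, `[[`, 0L, "dl")),
                 avgdwl = mean(vapply(docs, `[[`, 0L, "dwl")),
                 docs = docs,
                 pmids = pmids),
            class = "pm_index")
}

table_int <- function(tokens) {
  if (length(tokens) == 0L) return(integer(0))
  tab <- table(tokens)
  stats::setNames(as.integer(tab), names(tab))
}

df_count <- function(token_sets) {
  all <- unlist(token_sets, use.names = FALSE)
  if (length(all) == 0L) return(integer(0))
  tab <- table(all)
  stats::setNames(as.integer(tab), names(tab))
}

#' @export
print.pm_index <- function(x, ...) {
  cat(sprintf("<pm_index> %d docs, avgdl %.2f, avgdwl %.2f\n",
              x$n_docs, x$avgdl, x$avgdwl))
  invisible(x)
}

#' Inverse document frequency of a token
#'
#' `ln(n_docs / df)` over the named field's document frequencies. Degenerate
#' cases return 0: a token absent from the corpus (df = 0) cannot score, and
#' a token present in every document gives log(1) = 0.
#'
#' @param token a single normalized token.
#' @param field `"abstract"` (title + abstract) or `"wordlist"`.
#' @param index a [build_index()] result.
#' @return non-negative real.
#' @export
idf <- function(token, field = c("abstract", "wordlist"), index) {
  field <- match.arg(field)
  dfs <- if (field == "abstract") index$df_abstract else index$df_wordlist
  df <- dfs[token]
  df <- ifelse(is.na(df), 0L, df)
  out <- ifelse(df == 0L | df == index$n_docs, 0, log(index$n_docs / df))
  unname(out)
}

effective_avgdl <- function(index, params) {
  params$avgdl_override %||% index$avgdl
}
effective_avgdwl <- function(index, params) {
  params$avgdwl_override %||% index$avgdwl
}

#' Query morphemes of a topic
#'
#' The flat set of normalized search-morpheme tokens used by the abstract and
#' wordlist scores: disease tokens, gene tokens (variant notation split, so
#' "BRAF (V600E)" yields both "braf" and "v600e"), expansion terms (which
#' include the "human" element after [expand_topic()]), and — when the
#' demographic text parses — the demographic category and gender tokens.
#'
#' @param tp a [topic()].
#' @return character vector of unique tokens.
#' @export
query_morphemes <- function(tp) {
  toks <- c(tokenize(tp$disease),
            unlist(lapply(tp$genes, tokenize)),
            unlist(lapply(tp$expansion_terms, tokenize)))
  if (nzchar(tp$demographic)) {
    prof <- parse_demographic(tp$demographic)
    if (prof$age_category != "Unknown") {
      toks <- c(toks, tokenize(prof$age_category))
    }
    if (prof$gender != "Unknown") toks <- c(toks, tolower(prof$gender))
  }
  unique(toks)
}

bm25_term <- function(f, idf_val, k, b, dl, avgdl) {
  idf_val * (f * (k + 1)) / (f + k * (1 - b + b * dl / avgdl))
}

#' Abstract score of a document for a topic
#'
#' BM25-style sum over the topic's query morphemes against the document's
#' abstract field (title + abstract):
#' `AS = sum_i IDF(q_i) * f_i (k1 + 1) / (f_i + k1 (1 - b1 + b1 dl/avgdl))`
#' where `f_i` is the morpheme's frequency in the field and `dl` the field's
#' token length.
#'
#' @param tp a [topic()] (expanded or not).
#' @param pmid document identifier present in the index.
#' @param index a [build_index()] result.
#' @param params a [scoring_params()].
#' @return non-negative real.
#' @export
abstract_score <- function(tp, pmid, index, params = scoring_params()) {
  doc <- index$docs[[pmid]]
  if (is.null(doc)) stop("pmid not in index: ", pmid)
  q <- query_morphemes(tp)
  if (length(q) == 0L || doc$dl == 0L) return(0)
  f <- doc$tf_abstract[q]
  f <- ifelse(is.na(f), 0L, f)
  idfs <- idf(q, "abstract", index)
  avgdl <- effective_avgdl(index, params)
  sum(bm25_term(f, idfs, params$k1, params$b1, doc$dl, avgdl)[f > 0])
}

#' Wordlist score of a document for a topic
#'
#' `tfw` is the sum of wordlist-field IDF values of the query morphemes
#' present in the document's wordlist; the score saturates it BM25-style:
#' `WS = tfw (k2 + 1) / (tfw + k2 (1 - b2 + b2 dwl/avgdwl))`. When no
#' morpheme occurs in the wordlist, WS is 0.
#'
#' @inheritParams abstract_score
#' @return non-negative real.
#' @export
wordlist_score <- function(tp, pmid, index, params = scoring_params()) {
  doc <- index$docs[[pmid]]
  if (is.null(doc)) stop("pmid not in index: ", pmid)
  q <- query_morphemes(tp)
  present <- q[q %in% names(doc$tf_wordlist)]
  if (length(present) == 0L) return(0)
  tfw <- sum(idf(present, "wordlist", index))
  if (tfw <= 0) return(0)
  avgdwl <- effective_avgdwl(index, params)
  tfw * (params$k2 + 1) /
    (tfw + params$k2 * (1 - params$b2 + params$b2 * doc$dwl / avgdwl))
}

disease_evidence_tokens <- function(tp) {
  ext <- attr(tp, "disease_expansions") %||% character(0)
  unique(c(tokenize(tp$disease), unlist(lapply(ext, tokenize))))
}

#' Co-word score of a document for a topic
#'
#' Awards a bonus when the topic's disease and a gene co-occur in the
#' document. The disease (any of its tokens, or an expansion synonym of it)
#' and the gene must each appear at least once in the union of the abstract
#' field and wordlist tokens; each qualifying gene contributes one IDF term,
#' `CWS = sum_i IDF_word(g_i, d)`, summed because a task can carry several
#' genes. The IDF of a gene token is taken over the wordlist field when the
#' token occurs in the document's wordlist, else over the abstract field; a
#' multi-token gene morpheme contributes the maximum IDF over its present
#' tokens.
#'
#' @inheritParams abstract_score
#' @return non-negative real.
#' @export
coword_score <- function(tp, pmid, index) {
  doc <- index$docs[[pmid]]
  if (is.null(doc)) stop("pmid not in index: ", pmid)
  doc_tokens <- unique(c(names(doc$tf_abstract), names(doc$tf_wordlist)))
  disease_toks <- disease_evidence_tokens(tp)
  if (!any(disease_toks %in% doc_tokens)) return(0)
  total <- 0
  for (g in tp$genes) {
    gt <- tokenize(g)
    present <- gt[gt %in% doc_tokens]
    if (length(present) == 0L) next
    idfs <- vapply(present, function(tok) {
      if (tok %in% names(doc$tf_wordlist)) idf(tok, "wordlist", index)
      else idf(tok, "abstract", index)
    }, 0)
    total <- total + max(idfs)
  }
  total
}

#' Max-min normalization of a score sequence
#'
#' `x_norm = (x - min X) / (max X - min X)`. A constant sequence maps to all
#' zeros (the degenerate-range convention); an empty sequence is an error.
#'
#' @param x non-empty numeric vector.
#' @return numeric vector in `[0, 1]`.
#' @export
minmax_normalize <- function(x) {
  if (length(x) == 0L) stop("cannot normalize an empty sequence")
  rng <- range(x)
  if (rng[1] == rng[2]) return(rep(0, length(x)))
  (x - rng[1]) / (rng[2] - rng[1])
}

#' Stage-1 retrieval: composite BM25 ranking
#'
#' Scores every indexed document with the composite
#' `raw_sum = AS + WS + CWS`, sorts in descending order (ties broken by
#' ascending pmid), truncates to the candidate depth `k`, and max-min
#' normalizes `raw_sum` over the retained candidate pool into `norm_score`.
#'
#' @inheritParams abstract_score
#' @param k candidate depth (default 1000).
#' @return data.frame with columns pmid, as_score, ws_score, cws_score,
#'   raw_sum, norm_score, rank — one row per retained candidate, rank 1..k.
#' @export
stage1_retrieve <- function(tp, index, params = scoring_params(), k = 1000L) {
  pmids <- index$pmids
  as_s <- vapply(pmids, function(p) abstract_score(tp, p, index, params), 0)
  ws_s <- vapply(pmids, function(p) wordlist_score(tp, p, index, params), 0)
  cw_s <- vapply(pmids, function(p) coword_score(tp, p, index), 0)
  raw <- as_s + ws_s + cw_s
  ord <- order(-raw, pmids)
  keep <- ord[seq_len(min(k, length(ord)))]
  out <- data.frame(pmid = pmids[keep],
                    as_score = as_s[keep], ws_score = ws_s[keep],
                    cws_score = cw_s[keep], raw_sum = raw[keep],
                    stringsAsFactors = FALSE, row.names = NULL)
  out$norm_score <- minmax_normalize(out$raw_sum)
  out$rank <- seq_len(nrow(out))
  out
}
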