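#' Split an abstract into sentences
#'
#' Rule-based splitter: sentences end at ".", "!" or "?" followed by
#' whitespace, with common abbreviations ("i.e.", "e.g.", "et al.", "vs.",
#' "Fig." ...) protected from splitting. Joining the returned sentences with
#' single spaces reconstructs the input modulo whitespace.
#'
#' @param text character scalar.
#' @return character vector of sentences (empty for empty input).
#' @export
split_sentences <- function(text) {
  if (is.na(text) || !nzchar(trimws(text))) return(character(0))
  abbrevs <- c("i.e.", "e.g.", "et al.", "etc.", "vs.", "cf.", "ca.",
               "approx.", "Fig.", "Figs.", "Dr.", "Mr.", "Mrs.", "Ms.",
               "St.", "no.", "No.")
  protected <- text
  for (ab in abbrevs) {
    protected <- gsub(ab, gsub(".", "\x01", ab, fixed = TRUE),
                      protected, fixed = TRUE)
  }
  parts <- strsplit(protected, "(?<=[.!?])\\s+", perl = TRUE)[[1]]
  parts <- gsub("\x01", ".", parts, fixed = TRUE)
  parts <- trimws(parts)
  parts[nzchar(parts)]
}

#' Deterministic feature-hashing sentence embedder
#'
#' A bag-of-words embedder that hashes each token into one of `dim` signed
#' buckets and L2-normalizes the resulting sentence vector. It is fully
#' deterministic and dependency-free, and satisfies the embedder contract
#' used by [extract_abstract()]: sentences sharing vocabulary land close in
#' the embedding space, which is all the clustering step requires. A
#' transformer sentence encoder (e.g. a 768-dimensional biomedical BERT) can
#' be supplied through the same contract for production use.
#'
#' @param dim embedding dimension (default 32).
#' @return an object of class `pm_embedder` with elements `embed(sentences)`
#'   (returns an `n x dim` matrix), `dim`, and `deterministic`.
#' @export
hashing_embedder <- function(dim = 32L) {
  stopifnot(dim >= 2L)
  embed <- function(sentences) {
    mat <- matrix(0, nrow = length(sentences), ncol = dim)
    for (i in seq_along(sentences)) {
      for (tok in tokenize(sentences[[i]])) {
        h <- token_hash(tok)
        bucket <- (h %% dim) + 1L
        sign <- if ((h %/% dim) %% 2 == 0) 1 else -1
        mat[i, bucket] <- mat[i, bucket] + sign
      }
      nrm <- sqrt(sum(mat[i, ]^2))
      if (nrm > 0) mat[i, ] <- mat[i, ] / nrm
    }
    mat
  }
  structure(list(embed = embed, dim = as.integer(dim), deterministic = TRUE),
            class = "pm_embedder")
}

# 31-ary polynomial rolling hash over UTF-8 bytes, kept below 2^31 so double
# arithmetic stays exact.
token_hash <- function(token) {
  h <- 0
  for (b in as.integer(charToRaw(token))) {
    h <- (h * 31 + b) %% 2147483647
  }
  h
}

with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

#' Cluster sentence embeddings with k-means
#'
#' Seeded k-means over the embedding rows: k-means++-style seeding, Lloyd
#' updates with a 300-iteration cap, 10 restarts keeping the lowest
#' within-cluster sum of squares, and empty clusters re-seeded from the
#' point farthest from its centroid. `n_clusters` is clamped to the number
#' of distinct embedding rows; centroids are the means of all assigned rows
#' (duplicates included).
#'
#' @param embeddings numeric matrix, one row per sentence.
#' @param n_clusters requested number of clusters N (>= 1).
#' @param seed integer seed making the clustering reproducible.
#' @param nstart number of restarts.
#' @param iter_max Lloyd iteration cap per restart.
#' @return list with `cluster` (integer assignment per row), `centers`
#'   (centroid matrix), `n_clusters` (the N actually used).
#' @export
cluster_sentences <- function(embeddings, n_clusters, seed = 1L,
                              nstart = 10L, iter_max = 300L) {
  if (is.null(dim(embeddings)) || nrow(embeddings) == 0L) {
    stop("cannot cluster an empty embedding set")
  }
  stopifnot(n_clusters >= 1L)
  n_eff <- min(as.integer(n_clusters), nrow(unique(embeddings)))
  km <- with_seed(seed, kmeanspp(embeddings, n_eff, nstart, iter_max))
  list(cluster = km$cluster, centers = km$centers, n_clusters = n_eff)
}

kmeanspp <- function(x, k, nstart, iter_max) {
  best <- NULL
  for (s in seq_len(nstart)) {
    centers <- x[kpp_init(x, k), , drop = FALSE]
    assign <- nearest_center(x, centers)
    for (it in seq_len(iter_max)) {
      for (c_id in seq_len(k)) {
        members <- which(assign == c_id)
        if (length(members) == 0L) {
          # re-seed an empty cluster from the globally farthest point
          d <- rowSums((x - centers[assign, , drop = FALSE])^2)
          centers[c_id, ] <- x[which.max(d), ]
        } else {
          centers[c_id, ] <- colMeans(x[members, , drop = FALSE])
        }
      }
      new_assign <- nearest_center(x, centers)
      if (identical(new_assign, assign)) break
      assign <- new_assign
    }
    wss <- sum((x - centers[assign, , drop = FALSE])^2)
    if (is.null(best) || wss < best$wss - 1e-12) {
      best <- list(cluster = assign, centers = centers, wss = wss)
    }
  }
  best
}

kpp_init <- function(x, k) {
  n <- nrow(x)
  idx <- integer(k)
  idx[1] <- sample.int(n, 1)
  if (k == 1L) return(idx)
  d2 <- rowSums((x - matrix(x[idx[1], ], n, ncol(x), byrow = TRUE))^2)
  for (j in 2:k) {
    if (sum(d2) <= 0) {
      cand <- setdiff(seq_len(n), idx[seq_len(j - 1L)])
      idx[j] <- if (length(cand) == 1L) cand else sample(cand, 1)
    } else {
      idx[j] <- sample.int(n, 1, prob = d2)
    }
    d2 <- pmin(d2, rowSums((x - matrix(x[idx[j], ], n, ncol(x),
                                       byrow = TRUE))^2))
  }
  idx
}

nearest_center <- function(x, centers) {
  d2 <- outer(rowSums(x^2), rep(1, nrow(centers))) -
    2 * x %*% t(centers) +
    outer(rep(1, nrow(x)), rowSums(centers^2))
  max.col(-d2, ties.method = "first")
}

#' Select centroid-nearest sentences under a token budget
#'
#' Iterates over clusters in round-robin passes; each pass takes, per
#' cluster, the not-yet-selected sentence with the smallest Euclidean
#' distance to that cluster's centroid, and stops before any selection would
#' exceed the word budget. Selected sentences are emitted in their original
#' abstract order.
#'
#' @param clustering a [cluster_sentences()] result.
#' @param embeddings the embedding matrix the clustering was built from.
#' @param sentences character vector of the original sentences.
#' @param budget maximum total word count (default 512).
#' @return an `pm_extracted` object: list with `selected` (data.frame
#'   sentence_index, text, cluster_id in original order), `token_count`,
#'   `n_clusters`.
#' @export
select_by_centroid <- function(clustering, embeddings, sentences,
                               budget = 512L) {
  n <- length(sentences)
  words <- vapply(sentences, count_words, 0L)
  dists <- vapply(seq_len(n), function(i) {
    sqrt(sum((embeddings[i, ] - clustering$centers[clustering$cluster[i], ])^2))
  }, 0)
  selected <- logical(n)
  total <- 0L
  repeat {
    took_any <- FALSE
    for (cl in seq_len(clustering$n_clusters)) {
      cand <- which(!selected & clustering$cluster == cl)
      if (length(cand) == 0L) next
      best <- cand[order(dists[cand], cand)][1]
      if (total + words[best] > budget) {
        return(extracted_abstract(selected, sentences, clustering, total))
      }
      selected[best] <- TRUE
      total <- total + words[best]
      took_any <- TRUE
    }
    if (!took_any) break
  }
  extracted_abstract(selected, sentences, clustering, total)
}

extracted_abstract <- function(selected, sentences, clustering, total) {
  idx <- which(selected)
  structure(
    list(selected = data.frame(sentence_index = idx,
                               text = sentences[idx],
                               cluster_id = clustering$cluster[idx],
                               stringsAsFactors = FALSE, row.names = NULL),
         token_count = as.integer(total),
         n_clusters = clustering$n_clusters),
    class = "pm_extracted")
}

#' @export
print.pm_extracted <- function(x, ...) {
  cat(sprintf("<pm_extracted> %d sentences, %d words, %d clusters\n",
              nrow(x$selected), x$token_count, x$n_clusters))
  invisible(x)
}

#' Text of an extracted abstract
#' @param x a `pm_extracted` object.
#' @return single string joining the selected sentences in original order.
#' @export
extracted_text <- function(x) {
  paste(x$selected$text, collapse = " ")
}

#' Compress an abstract to a token budget by cluster-based extraction
#'
#' The similarity backends cap their input at 512 tokens, so longer
#' abstracts are compressed extractively: sentences are embedded, clustered
#' into `n_clusters` groups with k-means, and centroid-nearest sentences are
#' selected round-robin until the budget is reached, preserving the original
#' sentence order and wording. An abstract already within the budget passes
#' through unchanged.
#'
#' @param doc a [document()] or a character scalar (the abstract text).
#' @param embedder a sentence embedder such as [hashing_embedder()].
#' @param n_clusters preassigned number of clusters N (default 4).
#' @param budget word budget (default 512).
#' @param seed clustering seed.
#' @return a `pm_extracted` object (see [select_by_centroid()]).
#' @export
extract_abstract <- function(doc, embedder = hashing_embedder(),
                             n_clusters = 4L, budget = 512L, seed = 1L) {
  text <- if (inherits(doc, "pm_document")) doc$abstract else doc
  sentences <- split_sentences(text)
  if (length(sentences) == 0L) {
    return(structure(list(selected = data.frame(sentence_index = integer(0),
                                                text = character(0),
                                                cluster_id = integer(0)),
                          token_count = 0L, n_clusters = 0L),
                     class = "pm_extracted"))
  }
  emb <- embedder$embed(sentences)
  clustering <- cluster_sentences(emb, n_clusters, seed = seed)
  select_by_centroid(clustering, emb, sentences, budget = budget)
}
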