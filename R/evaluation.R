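#' @name evaluation
#' @title trec_eval-compatible rank-quality metrics
#' @description Binary metrics (P@k, R-Prec, MAP) treat grade >= 1 as
#'   relevant; NDCG uses the raw graded judgments with exponential gain.
#'   Documents missing from the qrels are unjudged and count as
#'   non-relevant, the standard pooling convention. Means over topics are
#'   arithmetic (macro) means.
NULL

#' Precision at cutoff k
#'
#' `|top-k retrieved that are relevant| / k`. A run shorter than `k` is
#' padded implicitly with non-relevant slots; unjudged documents count as
#' non-relevant.
#'
#' @param ranked character vector of pmids in rank order.
#' @param relevant character vector (set) of relevant pmids.
#' @param k cutoff, >= 1.
#' @return real in `[0, 1]`.
#' @export
precision_at_k <- function(ranked, relevant, k) {
  stopifnot(k >= 1)
  top <- ranked[seq_len(min(k, length(ranked)))]
  sum(top %in% relevant) / k
}

#' Recall at cutoff k
#' @inheritParams precision_at_k
#' @return real in `[0, 1]`; 0 when there are no relevant documents.
#' @export
recall_at_k <- function(ranked, relevant, k) {
  stopifnot(k >= 1)
  if (length(relevant) == 0L) return(0)
  top <- ranked[seq_len(min(k, length(ranked)))]
  sum(top %in% relevant) / length(relevant)
}

#' R-precision
#'
#' Precision at depth R, where R is the number of relevant documents for the
#' topic; 0 when there are none.
#'
#' @inheritParams precision_at_k
#' @export
r_precision <- function(ranked, relevant) {
  r <- length(relevant)
  if (r == 0L) return(0)
  precision_at_k(ranked, relevant, r)
}

#' Average precision
#'
#' Mean over all R relevant documents of the precision at each relevant
#' document's rank; relevant documents never retrieved contribute 0.
#'
#' @inheritParams precision_at_k
#' @export
average_precision <- function(ranked, relevant) {
  r <- length(relevant)
  if (r == 0L) return(0)
  hits <- ranked %in% relevant
  if (!any(hits)) return(0)
  ranks <- which(hits)
  sum(cumsum(hits)[ranks] / ranks) / r
}

#' Normalized discounted cumulative gain
#'
#' DCG with exponential gain `2^grade - 1` and `log2(rank + 1)` discount,
#' evaluated at the full run depth and normalized by the DCG of the ideal
#' ordering of all judged documents.
#'
#' @param ranked character vector of pmids in rank order.
#' @param grades named integer vector pmid -> relevance grade (the topic's
#'   qrels); unlisted pmids are unjudged (grade 0).
#' @return real in `[0, 1]`.
#' @export
ndcg <- function(ranked, grades) {
  g <- grades[ranked]
  g[is.na(g)] <- 0L
  dcg <- sum((2^g - 1) / log2(seq_along(g) + 1))
  ideal <- sort(grades, decreasing = TRUE)
  idcg <- sum((2^ideal - 1) / log2(seq_along(ideal) + 1))
  if (idcg == 0) return(0)
  dcg / idcg
}

qrels_by_topic <- function(qrels) {
  split(qrels, qrels$topic_id)
}

topic_relevant <- function(q, min_grade = 1L) {
  q$pmid[q$grade >= min_grade]
}

#' Precision-recall curve at fixed cutoffs
#'
#' Mean precision and mean recall over topics at each cutoff (the nine
#' standard depths 5, 10, 15, 20, 30, 100, 200, 500, 1000 by default).
#'
#' @param run run data.frame (topic_id, pmid, rank, ...).
#' @param qrels qrels data.frame.
#' @param cutoffs integer vector of depths.
#' @return data.frame with columns cutoff, precision, recall.
#' @export
pr_curve <- function(run, qrels,
                     cutoffs = c(5, 10, 15, 20, 30, 100, 200, 500, 1000)) {
  per <- evaluate_topics(run, qrels)
  do.call(rbind, lapply(cutoffs, function(k) {
    p <- vapply(per, function(x) precision_at_k(x$ranked, x$relevant, k), 0)
    r <- vapply(per, function(x) recall_at_k(x$ranked, x$relevant, k), 0)
    data.frame(cutoff = k, precision = mean(p), recall = mean(r))
  }))
}

evaluate_topics <- function(run, qrels, min_grade = 1L) {
  qr <- qrels_by_topic(qrels)
  topics <- unique(run$topic_id)
  missing <- setdiff(topics, names(qr))
  if (length(missing)) {
    warning("topics absent from qrels skipped: ",
            paste(missing, collapse = ", "))
    topics <- setdiff(topics, missing)
  }
  out <- lapply(topics, function(tid) {
    sub <- run[run$topic_id == tid, ]
    sub <- sub[order(sub$rank), ]
    q <- qr[[tid]]
    list(ranked = sub$pmid,
         relevant = topic_relevant(q, min_grade),
         grades = stats::setNames(q$grade, q$pmid))
  })
  stats::setNames(out, topics)
}

#' Full metric report for a run
#'
#' Per-topic and mean P@k at the nine standard cutoffs, R-Prec, MAP (mean
#' average precision) and NDCG, plus the composite index
#' `p10_x_rprec = mean P@10 x mean R-Prec`, an F-measure-style summary that
#' penalizes optimizing either metric at the expense of the other.
#'
#' @param run run data.frame.
#' @param qrels qrels data.frame.
#' @return an object of class `pm_report`: list with `per_topic`
#'   (data.frame) and `summary` (named list: map, ndcg, p10, rprec,
#'   p10_x_rprec, and p_at_<k> entries).
#' @export
evaluate_run <- function(run, qrels) {
  cutoffs <- c(5, 10, 15, 20, 30, 100, 200, 500, 1000)
  per <- evaluate_topics(run, qrels)
  if (length(per) == 0L) stop("no topic shared between run and qrels")
  per_topic <- do.call(rbind, lapply(names(per), function(tid) {
    x <- per[[tid]]
    row <- data.frame(topic_id = tid,
                      ap = average_precision(x$ranked, x$relevant),
                      ndcg = ndcg(x$ranked, x$grades),
                      rprec = r_precision(x$ranked, x$relevant),
                      stringsAsFactors = FALSE)
    for (k in cutoffs) {
      row[[paste0("p_at_", k)]] <- precision_at_k(x$ranked, x$relevant, k)
    }
    row
  }))
  summ <- list(map = mean(per_topic$ap), ndcg = mean(per_topic$ndcg),
               p10 = mean(per_topic$p_at_10), rprec = mean(per_topic$rprec))
  summ$p10_x_rprec <- summ$p10 * summ$rprec
  for (k in cutoffs) {
    summ[[paste0("p_at_", k)]] <- mean(per_topic[[paste0("p_at_", k)]])
  }
  structure(list(per_topic = per_topic, summary = summ), class = "pm_report")
}

#' @export
print.pm_report <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "<pm_report> %d topics | MAP %.4f NDCG %.4f P@10 %.4f R-Prec %.4f P@10*R-Prec %.4f\n",
    nrow(x$per_topic), s$map, s$ndcg, s$p10, s$rprec, s$p10_x_rprec))
  invisible(x)
}
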