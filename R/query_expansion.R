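#' Load a query-expansion table
#'
#' A declarative synonym table mapping a normalized source term to its
#' expansion morphemes, supplied as JSON `{"term": ["synonym", ...], ...}`.
#' Keys are normalized (lowercased, punctuation collapsed); self-loops (a
#' term listed as its own expansion) are rejected. A MeSH-derived table can
#' be plugged in through the same format.
#'
#' @param path JSON file path, or a named list already in memory.
#' @return an object of class `pm_expansion_table` (named list).
#' @export
read_expansion_table <- function(path) {
  raw <- if (is.character(path)) {
    jsonlite::fromJSON(path, simplifyVector = FALSE)
  } else {
    path
  }
  entries <- list()
  for (key in names(raw)) {
    nk <- paste(tokenize(key), collapse = " ")
    vals <- unique(vapply(unlist(raw[[key]]), as.character, ""))
    if (any(vapply(vals, function(v)
      identical(paste(tokenize(v), collapse = " "), nk), TRUE))) {
      stop("expansion table has a self-loop for term: ", key)
    }
    entries[[nk]] <- unname(vals)
  }
  structure(entries, class = "pm_expansion_table")
}

#' An empty expansion table
#' @return a `pm_expansion_table` with no entries.
#' @export
empty_expansion_table <- function() {
  structure(stats::setNames(list(), character(0)),
            class = "pm_expansion_table")
}

lookup_expansions <- function(table, term) {
  key <- paste(tokenize(term), collapse = " ")
  unlist(table[[key]]) %||% character(0)
}

#' Split a gene morpheme into name and variant
#'
#' Variant notation "BRAF (V600E)" is split at the parenthesis into the two
#' separable morphemes "BRAF" and "V600E"; a plain symbol passes through.
#'
#' @param gene character scalar.
#' @return character vector of morphemes.
#' @export
split_gene_morphemes <- function(gene) {
  m <- regmatches(gene, regexec("^\\s*([^(]+?)\\s*\\(([^)]+)\\)\\s*$", gene))[[1]]
  if (length(m) == 3L) c(m[2], m[3]) else trimws(gene)
}

#' Expand a topic's morphemes from a synonym table
#'
#' Looks up the disease and each gene morpheme (with variant notation split,
#' so "BRAF (V600E)" is looked up as "BRAF" and as "V600E") in the expansion
#' table, deduplicates, and always appends the literal search element
#' "human" — used to separate human studies from animal ones. The original
#' disease/gene morphemes are never modified, and the operation is
#' idempotent. Disease-derived expansions are additionally recorded in the
#' `disease_expansions` attribute so the co-word score can treat them as
#' disease evidence.
#'
#' @param tp a [topic()].
#' @param table a [read_expansion_table()] result.
#' @return the topic with `expansion_terms` populated.
#' @export
expand_topic <- function(tp, table = empty_expansion_table()) {
  disease_exp <- unique(c(attr(tp, "disease_expansions") %||% character(0),
                          lookup_expansions(table, tp$disease)))
  gene_exp <- unique(unlist(lapply(tp$genes, function(g) {
    unlist(lapply(split_gene_morphemes(g),
                  function(m) lookup_expansions(table, m)))
  })) %||% character(0))
  tp$expansion_terms <- unique(c(tp$expansion_terms, disease_exp, gene_exp,
                                 "human"))
  attr(tp, "disease_expansions") <- disease_exp
  tp
}
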