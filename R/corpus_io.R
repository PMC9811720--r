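#' Construct a bibliographic document record
#'
#' One MEDLINE-style record carrying the six fields the retrieval pipeline
#' uses. Title and abstract are stored verbatim; the three controlled /
#' free-vocabulary lists may be empty.
#'
#' @param pmid unique identifier, a non-empty string (digits by convention).
#' @param title free text title.
#' @param abstract free text abstract, possibly empty.
#' @param chemicals character vector of chemical substance terms.
#' @param mesh_headings character vector of MeSH heading terms.
#' @param keywords character vector of author keywords.
#' @return an object of class `pm_document` (a named list).
#' @export
document <- function(pmid, title = "", abstract = "",
                     chemicals = character(0),
                     mesh_headings = character(0),
                     keywords = character(0)) {
  pmid <- as.character(pmid)
  if (length(pmid) != 1L || is.na(pmid) || !nzchar(pmid)) {
    stop("pmid must be a non-empty string")
  }
  structure(
    list(pmid = pmid,
         title = as.character(title %||% ""),
         abstract = as.character(abstract %||% ""),
         chemicals = as.character(chemicals %||% character(0)),
         mesh_headings = as.character(mesh_headings %||% character(0)),
         keywords = as.character(keywords %||% character(0))),
    class = "pm_document")
}

`%||%` <- function(a, b) if (is.null(a) || (length(a) == 1L && is.na(a))) b else a

#' @export
print.pm_document <- function(x, ...) {
  cat(sprintf("<pm_document %s> %s\n", x$pmid, x$title))
  invisible(x)
}

check_collection <- function(docs) {
  pmids <- vapply(docs, `[[`, "", "pmid")
  dup <- pmids[duplicated(pmids)]
  if (length(dup)) {
    stop("duplicate pmid in collection: ", paste(unique(dup), collapse = ", "))
  }
  names(docs) <- pmids
  structure(docs, class = "pm_collection")
}

#' Read a document collection
#'
#' Reads either the JSONL dialect (one document object per line with fields
#' `pmid`, `title`, `abstract`, `chemicals`, `mesh_headings`, `keywords`) or
#' MEDLINE-flavoured PubMed XML (`PubmedArticle` records; `ArticleTitle`,
#' `AbstractText`, `ChemicalList`, `MeshHeadingList`, `KeywordList` are
#' mapped). Missing fields default to empty, never to an error.
#'
#' @param path file path.
#' @param dialect `"jsonl"` or `"medline_xml"`.
#' @return a `pm_collection`: a named list of [document()] objects keyed by
#'   pmid.
#' @export
read_collection <- function(path, dialect = c("jsonl", "medline_xml")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such file: ", path)
  docs <- switch(dialect,
                 jsonl = read_collection_jsonl(path),
                 medline_xml = read_collection_medline(path))
  check_collection(docs)
}

read_collection_jsonl <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  lapply(seq_along(lines), function(i) {
    rec <- tryCatch(jsonlite::fromJSON(lines[[i]], simplifyVector = TRUE),
                    error = function(e) {
                      stop(sprintf("malformed JSON at record %d: %s",
                                   i, conditionMessage(e)), call. = FALSE)
                    })
    if (is.null(rec$pmid)) stop(sprintf("record %d has no pmid", i))
    document(pmid = rec$pmid,
             title = rec$title %||% "",
             abstract = rec$abstract %||% "",
             chemicals = unlist(rec$chemicals) %||% character(0),
             mesh_headings = unlist(rec$mesh_headings) %||% character(0),
             keywords = unlist(rec$keywords) %||% character(0))
  })
}

read_collection_medline <- function(path) {
  xml <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop("malformed XML: ",
                                           conditionMessage(e), call. = FALSE))
  arts <- xml2::xml_find_all(xml, ".//PubmedArticle")
  if (length(arts) == 0L) arts <- xml2::xml_find_all(xml, ".//MedlineCitation")
  lapply(seq_along(arts), function(i) {
    a <- arts[[i]]
    pmid <- xml2::xml_text(xml2::xml_find_first(a, ".//PMID"))
    if (is.na(pmid) || !nzchar(pmid)) {
      stop(sprintf("record %d has no PMID", i))
    }
    title <- xml2::xml_text(xml2::xml_find_first(a, ".//ArticleTitle"))
    abst <- xml2::xml_find_all(a, ".//Abstract/AbstractText")
    abstract <- if (length(abst)) paste(xml2::xml_text(abst), collapse = " ") else ""
    chem <- xml2::xml_text(
      xml2::xml_find_all(a, ".//ChemicalList/Chemical/NameOfSubstance"))
    mesh <- xml2::xml_text(
      xml2::xml_find_all(a, ".//MeshHeadingList/MeshHeading/DescriptorName"))
    keyw <- xml2::xml_text(xml2::xml_find_all(a, ".//KeywordList/Keyword"))
    document(pmid = pmid, title = title %||% "", abstract = abstract,
             chemicals = chem, mesh_headings = mesh, keywords = keyw)
  })
}

#' Write a collection in the JSONL dialect
#'
#' @param collection a `pm_collection` or list of documents.
#' @param path output file path.
#' @export
write_collection <- function(collection, path) {
  lines <- vapply(collection, function(d) {
    jsonlite::toJSON(list(pmid = d$pmid, title = d$title,
                          abstract = d$abstract, chemicals = d$chemicals,
                          mesh_headings = d$mesh_headings,
                          keywords = d$keywords),
                     auto_unbox = TRUE)
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Build the controlled-vocabulary wordlist of a document
#'
#' The wordlist pools the chemical substances, MeSH headings and keywords of
#' a record into one multiset of tokens. Multi-word terms are tokenized into
#' words ("CDK4 Amplification" contributes 2 tokens) and a term repeated
#' across lists is kept with multiplicity.
#'
#' @param doc a [document()].
#' @return list with `terms` (character vector of tokens, with multiplicity)
#'   and `dwl` (integer token count).
#' @export
build_wordlist <- function(doc) {
  terms <- c(unlist(lapply(doc$chemicals, tokenize)),
             unlist(lapply(doc$mesh_headings, tokenize)),
             unlist(lapply(doc$keywords, tokenize)))
  terms <- as.character(terms %||% character(0))
  list(terms = terms, dwl = length(terms))
}

#' Construct a retrieval topic
#'
#' One precision-medicine patient case: disease, one or more gene morphemes
#' (name plus optional variant, e.g. "BRAF (V600E)"), and a free-text
#' demographic such as "38-year-old male". `expansion_terms` starts empty and
#' is filled by [expand_topic()].
#'
#' @param topic_id unique topic identifier, e.g. "2017-1".
#' @param disease free-text disease name.
#' @param genes character vector of gene morphemes, length >= 1.
#' @param demographic free-text demographic.
#' @param expansion_terms character vector of extra morphemes.
#' @return an object of class `pm_topic`.
#' @export
topic <- function(topic_id, disease, genes, demographic = "",
                  expansion_terms = character(0)) {
  if (length(genes) < 1L) stop("topic must carry at least one gene")
  structure(
    list(topic_id = as.character(topic_id),
         disease = as.character(disease),
         genes = as.character(genes),
         demographic = as.character(demographic %||% ""),
         expansion_terms = as.character(expansion_terms)),
    class = "pm_topic")
}

#' @export
print.pm_topic <- function(x, ...) {
  cat(sprintf("<pm_topic %s> %s / %s / %s\n", x$topic_id, x$disease,
              paste(x$genes, collapse = "; "), x$demographic))
  invisible(x)
}

#' Read topics from JSON
#'
#' Expects a JSON array of objects with fields `topic_id`, `disease`,
#' `genes` (string or array), and optional `demographic`.
#'
#' @param path file path.
#' @return list of [topic()] objects.
#' @export
read_topics <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  tps <- lapply(raw, function(r) {
    topic(topic_id = r$topic_id, disease = r$disease,
          genes = unlist(r$genes), demographic = r$demographic %||% "")
  })
  ids <- vapply(tps, `[[`, "", "topic_id")
  if (anyDuplicated(ids)) stop("duplicate topic_id in ", path)
  names(tps) <- ids
  tps
}

#' Write topics to JSON
#' @param topics list of [topic()] objects.
#' @param path output path.
#' @export
write_topics <- function(topics, path) {
  out <- lapply(unname(topics), function(t) {
    list(topic_id = t$topic_id, disease = t$disease,
         genes = as.list(t$genes), demographic = t$demographic)
  })
  jsonlite::write_json(out, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Read TREC-format relevance judgments
#'
#' Whitespace-delimited lines `topic 0 pmid grade`. Grades are non-negative
#' integers (0/1/2 in the TREC PM dialect).
#'
#' @param path qrels file path.
#' @return data.frame with columns topic_id, pmid, grade.
#' @export
read_qrels <- function(path) {
  tab <- utils::read.table(path, header = FALSE, colClasses = "character",
                           col.names = c("topic_id", "iter", "pmid", "grade"))
  qrels <- data.frame(topic_id = tab$topic_id, pmid = tab$pmid,
                      grade = as.integer(tab$grade),
                      stringsAsFactors = FALSE)
  if (any(qrels$grade < 0L)) stop("negative relevance grade in ", path)
  key <- paste(qrels$topic_id, qrels$pmid)
  if (anyDuplicated(key)) stop("duplicate (topic, pmid) in qrels")
  qrels
}

#' Write TREC-format relevance judgments
#' @param qrels data.frame with topic_id, pmid, grade.
#' @param path output path.
#' @export
write_qrels <- function(qrels, path) {
  writeLines(sprintf("%s 0 %s %d", qrels$topic_id, qrels$pmid, qrels$grade),
             path)
  invisible(path)
}

validate_run <- function(run) {
  stopifnot(all(c("topic_id", "pmid", "rank", "score", "run_tag")
                %in% names(run)))
  for (tid in unique(run$topic_id)) {
    sub <- run[run$topic_id == tid, ]
    sub <- sub[order(sub$rank), ]
    if (!identical(as.integer(sub$rank), seq_len(nrow(sub)))) {
      stop("ranks for topic ", tid, " are not 1..k without gaps")
    }
    if (anyDuplicated(sub$pmid)) {
      stop("duplicate pmid in run for topic ", tid)
    }
    if (is.unsorted(rev(sub$score))) {
      stop("scores increase with rank for topic ", tid)
    }
  }
  invisible(run)
}

#' Write a ranked run in TREC exchange format
#'
#' Lines `topic Q0 pmid rank score tag`. The run is validated first: within a
#' topic, ranks must be 1..k without gaps, pmids unique, scores non-increasing
#' with rank.
#'
#' @param run data.frame with topic_id, pmid, rank, score, run_tag.
#' @param path output path.
#' @export
write_run <- function(run, path) {
  validate_run(run)
  run <- run[order(run$topic_id, run$rank), ]
  writeLines(sprintf("%s Q0 %s %d %.17g %s", run$topic_id, run$pmid,
                     as.integer(run$rank), run$score, run$run_tag), path)
  invisible(path)
}

#' Read a TREC-format run file
#' @param path run file path.
#' @return validated data.frame with topic_id, pmid, rank, score, run_tag.
#' @export
read_run <- function(path) {
  tab <- utils::read.table(path, header = FALSE, colClasses = "character",
                           col.names = c("topic_id", "q0", "pmid", "rank",
                                         "score", "run_tag"))
  run <- data.frame(topic_id = tab$topic_id, pmid = tab$pmid,
                    rank = as.integer(tab$rank), score = as.numeric(tab$score),
                    run_tag = tab$run_tag, stringsAsFactors = FALSE)
  validate_run(run)
}
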