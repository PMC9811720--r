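#' Normalize text to index tokens
#'
#' The canonical token policy used throughout the package: lowercase, map
#' every run of non-alphanumeric characters to a single space, split on
#' whitespace. Digits are kept, so "BRAF (V600E)" becomes c("braf", "v600e")
#' and "38-year-old" becomes c("38", "year", "old"). No stemming is applied
#' here; stemming is used only for gender-word matching (see
#' [extract_gender()]).
#'
#' @param x character vector of free text (length >= 0).
#' @return character vector of lowercase tokens (possibly empty).
#' @export
#' @examples
#' tokenize("CDK4 Amplification")
tokenize <- function(x) {
  if (length(x) == 0L) return(character(0))
  x <- tolower(paste(x, collapse = " "))
  x <- gsub("[^a-z0-9]+", " ", x)
  toks <- strsplit(trimws(x), "\\s+")[[1]]
  toks[nzchar(toks)]
}

#' Count whitespace-delimited words
#'
#' Token counter used for the extraction budget: a token is a
#' whitespace-delimited word of the verbatim text (no normalization).
#'
#' @param x character scalar.
#' @return integer word count.
#' @export
count_words <- function(x) {
  if (is.na(x) || !nzchar(trimws(x))) return(0L)
  length(strsplit(trimws(x), "\\s+")[[1]])
}
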