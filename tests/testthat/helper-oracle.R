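# Independent literal re-implementations used as oracles. These scan raw
# token lists directly (no index, no shared code with the package internals
# beyond the exported tokenizer) and transcribe the scoring formulas
# term by term.

oracle_idf <- function(tok, field_tokens) {
  n <- length(field_tokens)
  df <- sum(vapply(field_tokens, function(t) tok %in% t, TRUE))
  if (df == 0 || df == n) 0 else log(n / df)
}

oracle_as <- function(q_tokens, i, abstract_tokens, k1 = 1.2, b1 = 0.75) {
  dl <- length(abstract_tokens[[i]])
  avgdl <- mean(lengths(abstract_tokens))
  total <- 0
  for (q in unique(q_tokens)) {
    f <- sum(abstract_tokens[[i]] == q)
    if (f == 0) next
    idf <- oracle_idf(q, abstract_tokens)
    total <- total + idf * f * (k1 + 1) /
      (f + k1 * (1 - b1 + b1 * dl / avgdl))
  }
  total
}

oracle_ws <- function(q_tokens, i, wordlist_tokens, k2 = 1.2, b2 = 0.75) {
  dwl <- length(wordlist_tokens[[i]])
  avgdwl <- mean(lengths(wordlist_tokens))
  present <- unique(q_tokens[q_tokens %in% wordlist_tokens[[i]]])
  if (length(present) == 0) return(0)
  tfw <- sum(vapply(present, oracle_idf, 0, wordlist_tokens))
  if (tfw <= 0) return(0)
  tfw * (k2 + 1) / (tfw + k2 * (1 - b2 + b2 * dwl / avgdwl))
}

oracle_cws <- function(disease_tokens, gene_token_sets, i,
                       abstract_tokens, wordlist_tokens) {
  doc_union <- unique(c(abstract_tokens[[i]], wordlist_tokens[[i]]))
  if (!any(disease_tokens %in% doc_union)) return(0)
  total <- 0
  for (gt in gene_token_sets) {
    present <- gt[gt %in% doc_union]
    if (length(present) == 0) next
    idfs <- vapply(present, function(tok) {
      if (tok %in% wordlist_tokens[[i]]) oracle_idf(tok, wordlist_tokens)
      else oracle_idf(tok, abstract_tokens)
    }, 0)
    total <- total + max(idfs)
  }
  total
}

# Random toy corpus for oracle equivalence: plain alphanumeric tokens so the
# normalizer is the identity on them.
random_oracle_corpus <- function(n_docs, max_len = 30, vocab_size = 15) {
  vocab <- sprintf("w%02d", seq_len(vocab_size))
  docs <- lapply(seq_len(n_docs), function(i) {
    ab <- sample(vocab, sample(3:max_len, 1), replace = TRUE)
    wl <- sample(vocab, sample(0:8, 1), replace = TRUE)
    list(abstract = ab, wordlist = wl)
  })
  disease <- sample(vocab, sample(1:2, 1))
  genes <- replicate(sample(1:2, 1),
                     paste(sample(vocab, sample(1:2, 1)), collapse = " "))
  collection <- lapply(seq_len(n_docs), function(i) {
    document(pmid = sprintf("%04d", i),
             title = "",
             abstract = paste(docs[[i]]$abstract, collapse = " "),
             keywords = docs[[i]]$wordlist)
  })
  list(abstract_tokens = lapply(docs, `[[`, "abstract"),
       wordlist_tokens = lapply(docs, `[[`, "wordlist"),
       collection = collection,
       topic = topic("tx", paste(disease, collapse = " "), genes))
}

# Brute-force metric definitions
brute_p_at_k <- function(ranked, relevant, k) {
  hits <- 0
  for (r in seq_len(k)) {
    if (r <= length(ranked) && ranked[r] %in% relevant) hits <- hits + 1
  }
  hits / k
}

brute_ap <- function(ranked, relevant) {
  if (length(relevant) == 0) return(0)
  total <- 0
  for (doc in relevant) {
    pos <- match(doc, ranked)
    if (!is.na(pos)) {
      total <- total + sum(ranked[seq_len(pos)] %in% relevant) / pos
    }
  }
  total / length(relevant)
}

brute_ndcg <- function(ranked, grades) {
  dcg <- 0
  for (r in seq_along(ranked)) {
    g <- unname(grades[ranked[r]])
    if (length(g) == 0 || is.na(g)) g <- 0
    dcg <- dcg + (2^g - 1) / log2(r + 1)
  }
  ideal <- sort(unname(grades), decreasing = TRUE)
  idcg <- 0
  for (r in seq_along(ideal)) idcg <- idcg + (2^ideal[r] - 1) / log2(r + 1)
  if (idcg == 0) 0 else dcg / idcg
}

# Adjusted Rand index between two labelings
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n <- length(a)
  expected <- sum_a * sum_b / comb2(n)
  maxi <- (sum_a + sum_b) / 2
  if (maxi == expected) return(1)
  (sum_ij - expected) / (maxi - expected)
}

# Small MEDLINE-flavoured XML fixture written on the fly
write_medline_fixture <- function(path) {
  writeLines(c(
    "<?xml version=\"1.0\"?>",
    "<PubmedArticleSet>",
    "  <PubmedArticle>",
    "    <MedlineCitation>",
    "      <PMID>12345678</PMID>",
    "      <Article>",
    "        <ArticleTitle>Vemurafenib response in melanoma</ArticleTitle>",
    "        <Abstract>",
    "          <AbstractText>A 38-year-old male with metastatic melanoma.</AbstractText>",
    "        </Abstract>",
    "      </Article>",
    "      <ChemicalList>",
    "        <Chemical><NameOfSubstance>Vemurafenib</NameOfSubstance></Chemical>",
    "      </ChemicalList>",
    "      <MeshHeadingList>",
    "        <MeshHeading><DescriptorName>Melanoma</DescriptorName></MeshHeading>",
    "        <MeshHeading><DescriptorName>Humans</DescriptorName></MeshHeading>",
    "      </MeshHeadingList>",
    "    </MedlineCitation>",
    "  </PubmedArticle>",
    "</PubmedArticleSet>"), path)
  path
}
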