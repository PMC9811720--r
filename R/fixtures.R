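#' Specification for a synthetic retrieval fixture
#'
#' Describes a self-contained toy collection with planted relevance
#' structure: each topic's relevant documents carry the topic's disease and
#' gene tokens (in the abstract and/or the controlled-vocabulary wordlist)
#' at a controllable injection rate, plus a rendered demographic phrase;
#' hard distractors carry the disease without the gene (the "Missing Gene"
#' annotation pattern); the remaining documents are Zipf-weighted background
#' vocabulary. Defaults give the standard regression fixture: 500 documents,
#' 5 topics, 10 relevant documents per topic, strong signal.
#'
#' @param n_docs total document count.
#' @param n_topics number of topics (max 8 with the built-in name pools).
#' @param n_relevant_per_topic planted relevant documents per topic.
#' @param vocab_size background vocabulary size.
#' @param abstract_length_range min/max abstract length in tokens.
#' @param wordlist_length_range min/max background wordlist length in terms.
#' @param signal_strength expected extra disease/gene token injections per
#'   relevant document (1 + Poisson(signal_strength - 1) occurrences each).
#' @param coword_fraction fraction of relevant documents in which disease
#'   and gene co-occur (the rest drop the gene from abstract and wordlist
#'   alike, i.e. lose the co-word condition).
#' @param distractor_fraction fraction of n_docs turned into judged
#'   irrelevant disease-only distractors.
#' @param demographic_mix named probability vector over age categories used
#'   to render "N-year-old male/female" phrases.
#' @param seed RNG seed; the whole fixture is a pure function of the spec.
#' @return an object of class `pm_fixture_spec`.
#' @export
fixture_spec <- function(n_docs = 500L, n_topics = 5L,
                         n_relevant_per_topic = 10L, vocab_size = 500L,
                         abstract_length_range = c(40L, 80L),
                         wordlist_length_range = c(5L, 15L),
                         signal_strength = 3,
                         coword_fraction = 1,
                         distractor_fraction = 0.05,
                         demographic_mix = c(Young = 0.25, `Middle age` = 0.4,
                                             Aged = 0.25, `Aged 80` = 0.1),
                         seed = 42L) {
  stopifnot(n_topics * n_relevant_per_topic <= n_docs,
            n_topics >= 1L, n_topics <= 8L,
            coword_fraction >= 0, coword_fraction <= 1,
            distractor_fraction >= 0, distractor_fraction < 1,
            signal_strength >= 0,
            abs(sum(demographic_mix) - 1) < 1e-8)
  structure(list(n_docs = as.integer(n_docs), n_topics = as.integer(n_topics),
                 n_relevant_per_topic = as.integer(n_relevant_per_topic),
                 vocab_size = as.integer(vocab_size),
                 abstract_length_range = as.integer(abstract_length_range),
                 wordlist_length_range = as.integer(wordlist_length_range),
                 signal_strength = signal_strength,
                 coword_fraction = coword_fraction,
                 distractor_fraction = distractor_fraction,
                 demographic_mix = demographic_mix,
                 seed = as.integer(seed)),
            class = "pm_fixture_spec")
}

FIXTURE_DISEASES <- c("melanoma", "liposarcoma", "glioblastoma",
                      "cholangiocarcinoma", "neuroblastoma", "osteosarcoma",
                      "meningioma", "gastric cancer")
FIXTURE_GENES <- c("BRAF (V600E)", "CDK4 (Amplification)", "KRAS (G12C)",
                   "EGFR (L858R)", "ALK (Fusion)", "TP53 (R175H)",
                   "NTRK1 (Fusion)", "IDH1 (R132H)")

AGE_RANGES <- list(Newborn = c(0, 1 / 12), Infant = c(0.2, 1.9),
                   Preschool = c(2, 5), Child = c(6, 12),
                   Adolescent = c(13, 18), Young = c(19, 34),
                   `Middle age` = c(35, 59), Aged = c(60, 79),
                   `Aged 80` = c(80, 95))

render_demographic <- function(category, gender) {
  rng <- AGE_RANGES[[category]]
  age <- if (category == "Newborn") {
    return(sprintf("3-week-old %s", tolower(gender)))
  } else {
    sample(seq(ceiling(rng[1]), floor(rng[2])), 1)
  }
  sprintf("%d-year-old %s", age, tolower(gender))
}

zipf_weights <- function(n) (1 / seq_len(n)) / sum(1 / seq_len(n))

tokens_to_sentences <- function(tokens, words_per_sentence = 9L) {
  n <- length(tokens)
  if (n == 0L) return("")
  starts <- seq(1L, n, by = words_per_sentence)
  paste(vapply(starts, function(s) {
    paste0(paste(tokens[s:min(s + words_per_sentence - 1L, n)],
                 collapse = " "), ".")
  }, ""), collapse = " ")
}

#' Generate a synthetic collection, topics, qrels and expansion table
#'
#' Deterministic under the spec's seed: two calls with the same spec give
#' byte-identical output. Relevant documents are judged at grade 2 and carry
#' the topic's disease and gene morphemes (plus a matching demographic
#' phrase and "Humans" MeSH check-tags); distractors carry the disease only
#' and are judged at grade 0; the rest of the collection is unjudged
#' background.
#'
#' @param spec a [fixture_spec()].
#' @return list with `collection` (a `pm_collection`), `topics`, `qrels`,
#'   `expansion_table`, and `relevant` (named list topic_id -> pmids, the
#'   ground truth).
#' @export
generate_fixture <- function(spec = fixture_spec()) {
  stopifnot(inherits(spec, "pm_fixture_spec"))
  with_seed(spec$seed, generate_fixture_impl(spec))
}

generate_fixture_impl <- function(spec) {
  vocab <- sprintf("term%04d", seq_len(spec$vocab_size))
  wl_vocab <- sprintf("Heading %04d", seq_len(max(50L, spec$vocab_size %/% 5L)))
  zw <- zipf_weights(spec$vocab_size)

  genders <- rep(c("Male", "Female"), length.out = spec$n_topics)
  topics <- lapply(seq_len(spec$n_topics), function(i) {
    cat_i <- sample(names(spec$demographic_mix), 1,
                    prob = spec$demographic_mix)
    topic(topic_id = sprintf("T%02d", i),
          disease = FIXTURE_DISEASES[i],
          genes = FIXTURE_GENES[i],
          demographic = render_demographic(cat_i, genders[i]))
  })
  names(topics) <- vapply(topics, `[[`, "", "topic_id")

  n_rel_total <- spec$n_topics * spec$n_relevant_per_topic
  n_distract <- min(round(spec$distractor_fraction * spec$n_docs),
                    spec$n_docs - n_rel_total)
  pmids <- sprintf("%d", sample(10000000L:99999999L, spec$n_docs))

  bg_tokens <- function(n) sample(vocab, n, replace = TRUE, prob = zw)
  bg_wordlist <- function() {
    k <- sample(spec$wordlist_length_range[1]:spec$wordlist_length_range[2], 1)
    sample(wl_vocab, min(k, length(wl_vocab)))
  }
  inject_count <- function() {
    if (spec$signal_strength == 0) return(0L)
    1L + stats::rpois(1, max(spec$signal_strength - 1, 0))
  }
  signal_on <- spec$signal_strength > 0

  docs <- vector("list", spec$n_docs)
  qrel_rows <- list()
  relevant <- stats::setNames(vector("list", spec$n_topics), names(topics))
  slot <- 1L

  for (i in seq_len(spec$n_topics)) {
    tp <- topics[[i]]
    d_toks <- tokenize(tp$disease)
    g_toks <- unlist(lapply(tp$genes, tokenize))
    for (r in seq_len(spec$n_relevant_per_topic)) {
      pmid <- pmids[slot]; slot <- slot + 1L
      has_coword <- stats::runif(1) < spec$coword_fraction
      len <- sample(spec$abstract_length_range[1]:spec$abstract_length_range[2], 1)
      body <- bg_tokens(len)
      inj <- c(rep(d_toks, inject_count()),
               if (has_coword) rep(g_toks, inject_count()))
      pos <- sort(sample(length(body), min(length(inj), length(body))))
      body[pos] <- inj[seq_along(pos)]
      demo <- parse_demographic(tp$demographic)
      head_phrase <- if (signal_on) {
        sprintf("A %s with %s %s.", tp$demographic, tp$disease,
                if (has_coword) paste(g_toks, collapse = " ") else "")
      } else {
        ""
      }
      mesh <- c(bg_wordlist(),
                if (signal_on) c("Humans",
                                 if (demo$gender != "Unknown") demo$gender))
      chem <- if (signal_on && has_coword) {
        paste(g_toks, collapse = " ")
      } else {
        character(0)
      }
      kw <- if (signal_on) c(tp$disease, "human") else character(0)
      docs[[slot - 1L]] <- document(
        pmid = pmid,
        title = if (signal_on && has_coword) {
          sprintf("Study of %s in %s", paste(g_toks, collapse = " "),
                  tp$disease)
        } else if (signal_on) {
          sprintf("Clinical observations in %s", tp$disease)
        } else {
          paste("Notes on", paste(bg_tokens(3), collapse = " "))
        },
        abstract = trimws(paste(head_phrase, tokens_to_sentences(body))),
        chemicals = chem, mesh_headings = mesh, keywords = kw)
      relevant[[i]] <- c(relevant[[i]], pmid)
      qrel_rows[[length(qrel_rows) + 1L]] <-
        data.frame(topic_id = tp$topic_id, pmid = pmid, grade = 2L,
                   stringsAsFactors = FALSE)
    }
  }

  for (j in seq_len(n_distract)) {
    tp <- topics[[((j - 1L) %% spec$n_topics) + 1L]]
    pmid <- pmids[slot]; slot <- slot + 1L
    d_toks <- tokenize(tp$disease)
    len <- sample(spec$abstract_length_range[1]:spec$abstract_length_range[2], 1)
    body <- bg_tokens(len)
    inj <- rep(d_toks, inject_count())
    pos <- sort(sample(length(body), min(length(inj), length(body))))
    body[pos] <- inj[seq_along(pos)]
    docs[[slot - 1L]] <- document(
      pmid = pmid,
      title = if (signal_on) sprintf("Observations on %s", tp$disease)
              else paste("Notes on", paste(bg_tokens(3), collapse = " ")),
      abstract = tokens_to_sentences(body),
      mesh_headings = c(bg_wordlist(), if (signal_on) "Humans"),
      keywords = if (signal_on) c(tp$disease, "human") else character(0))
    qrel_rows[[length(qrel_rows) + 1L]] <-
      data.frame(topic_id = tp$topic_id, pmid = pmid, grade = 0L,
                 stringsAsFactors = FALSE)
  }

  while (slot <= spec$n_docs) {
    pmid <- pmids[slot]; slot <- slot + 1L
    len <- sample(spec$abstract_length_range[1]:spec$abstract_length_range[2], 1)
    docs[[slot - 1L]] <- document(
      pmid = pmid,
      title = paste("Notes on", paste(bg_tokens(3), collapse = " ")),
      abstract = tokens_to_sentences(bg_tokens(len)),
      mesh_headings = bg_wordlist())
  }

  expansion <- stats::setNames(
    lapply(seq_len(spec$n_topics),
           function(i) list(paste(FIXTURE_DISEASES[i], "neoplasm"))),
    FIXTURE_DISEASES[seq_len(spec$n_topics)])

  list(collection = check_collection(docs),
       topics = topics,
       qrels = do.call(rbind, qrel_rows),
       expansion_table = read_expansion_table(expansion),
       relevant = relevant)
}

#' Generate an abstract with planted topical sentence groups
#'
#' Builds an abstract whose sentences fall into `n_groups` groups with
#' disjoint token pools, interleaved in round-robin order, so a bag-of-words
#' embedder separates the groups cleanly. The ground-truth group labels are
#' returned for cluster-recovery assertions.
#'
#' @param n_groups number of topical groups (>= 1).
#' @param sentences_per_group sentences in each group.
#' @param seed RNG seed.
#' @param words_per_sentence tokens per sentence.
#' @param pool_size distinct tokens per group pool.
#' @return list with `text` (the abstract), `sentences`, `labels` (integer
#'   group per sentence, in sentence order).
#' @export
generate_clustered_abstract <- function(n_groups, sentences_per_group,
                                        seed = 1L, words_per_sentence = 8L,
                                        pool_size = 10L) {
  stopifnot(n_groups >= 1L, sentences_per_group >= 1L,
            words_per_sentence <= pool_size)
  with_seed(seed, {
    pools <- lapply(seq_len(n_groups), function(g) {
      sprintf("grp%02dtok%02d", g, seq_len(pool_size))
    })
    labels <- integer(n_groups * sentences_per_group)
    sentences <- character(n_groups * sentences_per_group)
    k <- 1L
    for (s in seq_len(sentences_per_group)) {
      for (g in seq_len(n_groups)) {
        toks <- sample(pools[[g]], words_per_sentence)
        sentences[k] <- paste0(paste(toks, collapse = " "), ".")
        labels[k] <- g
        k <- k + 1L
      }
    }
    list(text = paste(sentences, collapse = " "),
         sentences = sentences, labels = labels)
  })
}
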