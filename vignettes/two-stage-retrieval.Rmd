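---
title: "Two-stage retrieval for precision-medicine literature: model and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-stage retrieval for precision-medicine literature}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pmretrieve)
```

## The retrieval problem

A precision-medicine retrieval case is a patient: a disease, one or more
gene variants, and a demographic ("melanoma / BRAF (V600E) / 64-year-old
male"). The task is to rank MEDLINE-style bibliographic records —
PMID, title, abstract, chemical list, MeSH headings, keywords — by their
relevance to the case. Relevance here is compositional: a record about the
right disease with the wrong gene, or about the right gene in mice, is a
near miss that a plain term-matching ranker scores highly. The pipeline in
this package attacks that with two stages: a lexical stage built around an
extended BM25 composite that rewards disease–gene co-occurrence, followed
by a semantic re-ranking stage over the top candidates.

## Stage 1: the BM25 composite

Every document contributes three scores, computed from an inverted index
over two fields: the *abstract field* (title concatenated with abstract)
and the *wordlist* (chemicals + MeSH headings + keywords pooled as one
token multiset).

**Abstract score.** For query morphemes $q_i$ (disease tokens, gene
tokens, expansion terms, demographic tokens, and the "human" element):

$$AS(Q,d)=\sum_i IDF(q_i)\,\frac{f_i\,(k_1+1)}{f_i+k_1\left(1-b_1+b_1\,\frac{dl}{avgdl}\right)}$$

with $f_i$ the morpheme frequency in the abstract field, $dl$ the field
length, $avgdl$ the collection mean, and $IDF(q)=\ln(N/df_q)$. Degenerate
document frequencies score zero: an absent term cannot contribute, and a
term present in every document carries no information ($\ln 1 = 0$).

**Wordlist score.** The controlled-vocabulary field is short, so
per-morpheme saturation is replaced by saturation of the pooled IDF mass
$tfw$, the sum of wordlist-field IDFs of the morphemes present in the
document's wordlist:

$$WS(Q,d)=\frac{tfw\,(k_2+1)}{tfw+k_2\left(1-b_2+b_2\,\frac{dwl}{avgdwl}\right)}$$

**Co-word score.** The decisive signal for precision-medicine relevance is
that disease and gene appear *in the same record*. When the disease (any
of its tokens, or a synonym from the expansion table) and a gene $g_i$
each occur at least once in the union of the document's abstract-field and
wordlist tokens,

$$CWS(Q,d)=\sum_i IDF_{word}(g_i,d),$$

summed over qualifying genes because a case can carry several. We read the
co-occurrence condition over the *union* of the two fields rather than
requiring both: many records carry the gene only as a chemical/MeSH term
and the disease only in prose, and the AND reading would zero the score
exactly where the bonus is most useful. The IDF of a gene token is taken
over the wordlist field when the token occurs in the document's wordlist
(the curated signal), else over the abstract field; a multi-token gene
morpheme contributes the maximum IDF over its present tokens, keeping one
IDF term per gene.

The composite is $x = AS + WS + CWS$; the collection is sorted by $x$
descending (ties broken by ascending PMID for determinism), truncated to
the candidate depth $k = 1000$, and max–min normalized over the retained
pool:

$$x_{norm}=\frac{x-\min X}{\max X-\min X}$$

A constant pool maps to all zeros; any constant works because the value
only ever enters an additive fusion. We normalize over the retained
candidates — the same pool over which stage-2 similarities are normalized
— so both fusion addends live on the same $[0,1]$ scale.

### Parameters

| parameter | default | meaning |
|---|---|---|
| $k_1,k_2$ | 1.2 | term-frequency saturation (dimensionless) |
| $b_1,b_2$ | 0.75 | length normalization in $[0,1]$ |
| $avgdl$, $avgdwl$ | corpus means | overridable (e.g. 85 / 13 for a PubMed-scale corpus) |
| depth $k$ | 1000 | stage-1 candidate pool |

These are the conventional BM25 settings; the package deliberately does
not optimize them per collection. Natural logarithms are used throughout —
the log base scales all scores by a constant and never changes a ranking.

## Structured demographics

Ages are extracted with regular expressions covering the
"N-year(s)-old" / "N year(s) old" families plus month and week variants
(converted to fractional years), and classified into the standard
demographic categories by half-open intervals $[lower, upper)$: Newborn
$[0, 1/12)$, Infant $[1/12, 2)$, Preschool $[2,6)$, Child $[6,13)$,
Adolescent $[13,19)$, Young $[19,35)$, Middle age $[35,60)$, Aged
$[60,80)$, Aged 80 $[80,\infty)$. The published category table shares its
endpoints (60 ends "Middle age" and starts "Aged"); the half-open
convention makes the partition total and exclusive, with a shared endpoint
belonging to the upper category. "Fetus" and "Adult" are textual
categories: they are emitted only from the literal tokens, and "Adult"
only when no numeric age is present, since a numeric age always has a
finer category. Gender is stem-matched over the six-word vocabulary
female/woman/girl and male/man/boy with plural folding; matching is
token-level, so "human" never matches "man". When the abstract carries no
demographic evidence the document's MeSH check-tags are consulted through
an editable map ("Middle Aged" → Middle age, "Aged, 80 and over" →
Aged 80, ...).

The extracted category and gender tokens join the query morphemes, which
is how demographics enter scoring: the field's collections carry these
same words (in check-tags and case reports), so a matching demographic
lifts a document the way any other discriminative morpheme does. The
alternative — filtering or down-weighting mismatches — is deliberately
not done: demographic extraction is too noisy to make a hard filter safe.

## Query expansion

Expansion is declarative: a JSON table mapping a normalized term to
synonym morphemes (a MeSH-derived table plugs in through the same format).
The disease and each gene morpheme — variant notation "BRAF (V600E)" is
split into "BRAF" and "V600E", since name and variant expand
independently — are looked up, results are deduplicated, and the literal
element "human" is always appended, separating human studies from animal
work. Expansion is idempotent and purely additive: with an empty table the
pipeline reduces exactly to the unexpanded baseline plus "human".
Disease-derived expansions are remembered separately so the co-word
condition can accept a synonym as disease evidence without treating gene
aliases as diseases.

## Stage 2: extraction and similarity re-ranking

Pair-similarity backends cap their input (512 tokens for abstracts, 128
for titles), so long abstracts are compressed extractively, preserving
original sentences and their order:

1. sentences are embedded (one vector per sentence);
2. k-means clusters the vectors into $N$ preassigned groups;
3. centroid-nearest sentences are selected per cluster, round-robin
   across clusters, until the next selection would exceed the word budget.

A token is a whitespace-delimited word. Round-robin multi-pass selection
fills the budget fairly when one sentence per cluster underfills it.
Distances are Euclidean, consistent with the k-means objective. $N$
defaults to 4 — abstracts conventionally carry background / methods /
results / conclusion strata — and is clamped to the number of distinct
sentence embeddings. The k-means routine uses k-means++-style seeding
under a fixed seed, Lloyd updates capped at 300 iterations, 10 restarts
keeping the lowest within-cluster sum of squares, and re-seeds an empty
cluster from the point farthest from its centroid; with a deterministic
embedder the whole extraction is a pure function of (text, seed).

Two embedder/scorer backends ship. The *feature-hashing embedder* (signed
32-dimension bag-of-words hashing, L2-normalized) and the *lexical-overlap
scorer* (Jaccard overlap of normalized token sets) are deterministic,
dependency-free reference backends: they make every pipeline property
testable offline. A transformer sentence encoder and a fine-tuned
sentence-pair classifier with a sigmoid head (768-dimension biomedical
BERT being the natural production choice) plug in through the same
`Embedder` / `PairScorer` contracts; training hyperparameters for such a
backend (4 epochs; batch 32 for abstracts, 64 for titles; input caps
512/128; learning rate 5e-4) are carried as configuration, and
`make_training_pairs()` exports its training data, but no transformer code
lives in this package.

Similarities are computed per candidate for the query text (disease,
genes, demographic category, gender — lowercase, space-joined), max–min
normalized over the candidate pool per topic, and added to the normalized
stage-1 score with equal weights:

$$fused = x_{norm} + \mathrm{minmax}(sim_{abstract}) \,[+\,
\mathrm{minmax}(sim_{title})]$$

A constant scorer therefore reproduces the stage-1 ranking exactly — a
useful neutrality check — and the fused score is bounded by one plus the
number of enabled similarity fields.

## Training-pair generation

Sentence-pair backends need hard negatives. Retrieval cases cluster into
two families — the same disease with different genes, and different
diseases with the same gene. Each relevant document yields one positive:
the document rendered as a structured head (its topic's gene morphemes,
the "human" element, the document's demographic category and gender)
joined to its extracted summary, against its own topic's query, label 1.
Negatives reuse the same document text against the query of each sibling
topic that differs in *exactly one* slot: same disease / different gene
set, or different disease / identical gene set. A negative that differed
in both slots would be trivially separable and teach the scorer nothing;
the one-slot rule keeps negatives maximally confusable. Topics without
siblings contribute positives only.

## Evaluation

The metric suite follows trec_eval semantics: P@k at the nine standard
cutoffs (5–1000), R-precision, MAP, and NDCG with exponential gain
$2^{grade}-1$, $\log_2(rank+1)$ discount, evaluated at the full run depth
and normalized by the ideal ordering of all judged documents. Binary
metrics treat grade ≥ 1 as relevant; unjudged documents count as
non-relevant (the pooling convention); topic means are arithmetic
(macro). The composite index $P@10 \times R\text{-}Prec$ summarizes the
precision/coverage trade-off the way F1 balances precision and recall:
optimizing the top of the ranking at the expense of depth (or vice versa)
lowers it. The NDCG gain function is a documented choice — published
evaluations do not always state theirs, so absolute NDCG values are only
comparable across runs scored with the same formulation.

## The synthetic fixture generator

Real collections for this task are tens of millions of records with
pooled human judgments; nothing at that scale belongs in a test suite.
The generator builds collections whose relevance structure is known *by
construction*: each topic's relevant documents carry the topic's disease
and gene tokens at a controllable injection rate (in abstract and/or
wordlist, governed by `coword_fraction`), a rendered demographic phrase
matching the topic's case, and "human"-marker tags; hard distractors
carry the disease without the gene — the classic near-miss annotation
pattern; the rest is Zipf-weighted background vocabulary, which keeps IDF
values non-degenerate. Planted relevant documents are judged at grade 2,
distractors at 0, background is unjudged. Everything is a pure function
of the spec's seed.

The default spec — 500 documents, 5 topics, 10 relevant per topic, strong
signal (about three injections of each signal token per relevant
document), full co-word rate, 5% distractors — is the regression
condition: on it, stage-1 P@10 reaches at least 0.9 and the full pipeline
with the lexical-overlap scorer reaches P@10 = 1.0, by construction.
Sizes were chosen so the whole regression runs in seconds on one CPU
while still giving every score component a non-trivial distribution. A
zero-signal spec is the matching negative control: retrieval quality
drops to the topical base rate (10/500).

What passing these fixtures does *not* show: robustness to real
biomedical prose (synonymy, hedging, negation), to noisy gene
nomenclature, or to judgment sparsity — the generator plants token-level
signals, so it validates the scoring, fusion, extraction and evaluation
machinery, not linguistic coverage. Those properties belong to the
pluggable production backends and to collection-scale evaluation.

## Numerical and degenerate-input conventions

- Max–min over a constant pool returns all zeros; an empty pool is an
  error.
- IDF with $df = 0$ or $df = N$ contributes zero.
- Ranking ties break by ascending PMID, everywhere, so runs are
  reproducible across platforms.
- An empty abstract splits into zero sentences and extracts to an empty
  selection; a single sentence wider than the budget yields an empty
  selection rather than an over-budget one.
- Qrels topics absent from a run are ignored; run topics absent from the
  qrels are skipped with a warning.
- R-precision and AP of a topic with no relevant documents are 0.

## Known limitations

- The reference similarity backends are lexical; they cannot score
  paraphrases. They are contracts plus baselines, not the production
  model.
- The MEDLINE XML reader covers the six fields this pipeline uses, not
  the full DTD.
- Age ranges ("aged 40–50 years") resolve to their first number; the
  demographic regex family is English-only.
- Expansion is table-driven; no ontology traversal is performed.
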