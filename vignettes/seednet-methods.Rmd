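---
title: "Seed-term co-occurrence networks: model, parameters and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Seed-term co-occurrence networks: model, parameters and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seednet)
```

## The question the pipeline answers

Given a corpus of news articles or social-media posts, how is a small set of
focal terms — the *seed lemmas*, by default the German lemmas
*Fehlinformation* (misinformation) and *Desinformation* (disinformation) —
framed? The operationalization is lexical: look at every sentence that
contains a seed lemma, record which other lemmas appear in those sentences,
and study the structure of that co-occurrence neighbourhood as a weighted
network whose clusters are read as themes.

The pipeline is five stages, each exposed as its own function so any stage
can be replaced or inspected:

1. **Filtering** (`filter_by_descriptors`): documents that never mention the
   topic of interest are removed. The default descriptor list holds 15
   pandemic-related tokens across German, French, Italian and English
   (`covid_descriptors()`).
2. **Segmentation and lemmatization** (`lemmatize_corpus`): documents are
   split into sentences — the co-occurrence window — and tokens are reduced
   to lemmas so that inflectional variants count as one term.
3. **Co-occurrence statistics** (`compute_frequencies`): the central
   statistic, described next.
4. **Network construction and clustering** (`build_network`, `louvain`):
   the weighted lemma graph and its modularity classes.
5. **Export** (`write_gexf`, `rank_clusters`, `write_table`): GEXF for
   network-visualization tools plus CSV reports.

## The co-occurrence statistic

Let $S$ be the set of seed sentences (sentences containing at least one
seed lemma after lemmatization and surface-form mapping), $n = |S|$. For a
lemma $\ell$ that is not itself a seed,

$$
f(\ell) \;=\; \frac{\#\{\,s \in S : \ell \in s\,\}}{n} \in (0, 1],
$$

the fraction of seed sentences containing $\ell$. Three consequences of
this definition are deliberate:

* **The denominator is the number of seed sentences**, not all sentences or
  all documents. The statistic is a conditional frequency — "given that a
  sentence talks about mis/disinformation, how often is $\ell$ present?" —
  and this is the only normalization under which the upper end 1.0 of the
  0–1 scale is attainable (a lemma present in *every* seed sentence).
* **Set semantics within a sentence**: a lemma occurring three times in one
  sentence counts once. The unit of counting is the sentence, not the token
  pair.
* **Absence is not zero**: lemmas that never share a sentence with a seed
  are simply not in the table (the "crossed cells" of a co-occurrence
  plot). Every stored frequency is therefore strictly positive.

Pairwise counts $c(a, b)$ — in how many seed sentences $a$ and $b$ both
appear — are computed for *all* lemma pairs including the seeds themselves,
so the seed–lemma edge weight in the network is the pairwise sentence count
with that specific seed. With a single seed this equals the lemma's raw
count; with two seed nodes it splits the lemma's count between them rather
than double-counting it on both.

Both statistics are exact integer ratios (integer counts divided at
presentation time); tests compare them at absolute tolerance 1e-12 or with
`expect_identical`.

The two seeds are pooled by default, matching the pooled reading "either
seed present". Per-seed analysis needs no extra code path: construct
`seed_lexicon(seed_lemmas = "desinformation", ...)` and rerun from
`lemmatize_corpus` on. A per-document window (`compute_frequencies(...,
window = "document")`) is exposed for sensitivity analysis but is not the
default — sentences are the defined context.

## Preprocessing choices

**Descriptor matching is whole-token, case-insensitive.** The default list
contains both "corona" and "coronavirus"; under substring matching half the
list would be redundant, so the list itself implies token-level intent.
Tokens are split on whitespace and punctuation *except internal hyphens*:
"covid-19" is one token (and matches the listed descriptor "covid-19"),
while "Coronavirus-Test" is one token that matches nothing — a compound is
not a mention of its head. Filtering is idempotent and order-preserving.

**Sentence segmentation** is rule-based: a run of `.`, `!`, `?` followed by
whitespace terminates a sentence unless the token ending in the period is
on a per-language abbreviation list ("Dr.", "z.B.", ...). Newlines always
split, because social-media posts frequently separate statements by line
breaks without terminal punctuation. A period not followed by whitespace
never splits, which keeps decimals ("3.5") and internal abbreviation dots
intact. The concatenated sentences cover every non-whitespace character of
the input, so no text is silently lost.

**Lemmatization is a pluggable backend.** Production users can wrap any
model in `lemmatizer_backend()`; the package ships
`fallback_lemmatizer()`, a deterministic dictionary + suffix-rule
lemmatizer (exception dictionary first, then conservative suffix stripping
that only fires when the stripped stem is a known lemma). It is exactly as
good as its dictionary — no statistical tagging, no disambiguation — but it
is deterministic, idempotent, and needs no model artifacts, which is what a
reproducible test suite requires. Deterministic here is a contract, not an
optimization: the whole pipeline is reproducible byte-for-byte only if the
backend is.

**Stopwords**: small built-in function-word lists per language (default
policy), no removal, or a user file. Seed lemmas are never removed
regardless of policy. Numeric-only tokens are always dropped.

**Unicode**: all text and all term lists are NFC-normalized and lowercased
at the boundary, so "Pandémie" in decomposed form from one export equals
the composed form from another.

## The semantic network and its clustering

Nodes are the seed lemmas (size fixed at 1.0 — a seed is in every seed
sentence by construction) plus every lemma with $f(\ell) \ge$
`min_node_freq`, sized by $f(\ell)$. Edges are lemma pairs with
$c(a,b) \ge$ `min_edge_count`, weighted by the count. Non-seed nodes left
isolated are dropped; if no edge survives the thresholds the network is
empty and the stage fails loudly rather than emitting a trivial graph.

Clusters are modularity classes of the resolution-scaled Newman–Girvan
objective

$$
Q_\gamma \;=\; \sum_c \left[\frac{W_c}{W}
  - \gamma\left(\frac{S_c}{2W}\right)^{\!2}\right],
$$

with $W$ the total edge weight, $W_c$ the intra-community weight, $S_c$
the summed weighted degree of community $c$, and $\gamma$ the resolution
parameter multiplying the configuration-model null term. This is the form
used by the Louvain implementations in common network tools; the default
$\gamma = 0.5$ favours coarser, larger themes than standard modularity
($\gamma = 1$). Edge weights enter as weights — co-occurrence strength is
information, not noise — with an unweighted mode (`weighted = FALSE`)
available because some tools report modularity classes on the binarized
graph. Useful closed forms: any single-community partition scores exactly
$1 - \gamma$; two disjoint unit triangles at $\gamma = 1$ score $0.5$
under the natural partition, which exhaustive enumeration confirms is the
optimum.

`louvain()` is a from-scratch two-phase optimizer: greedy single-node moves
until no move improves $Q_\gamma$, then aggregation of communities into
super-nodes (intra-community weight becomes a self-loop), repeated until
stable. Determinism is engineered, not assumed:

* the node visiting order is one seeded permutation per level
  (`rng_seed + level`), drawn without touching the caller's RNG state;
* among equal-gain moves the current community wins, otherwise the lowest
  community id (gain ties at absolute tolerance 1e-12);
* community ids are renumbered densely from 0 by first appearance over the
  bytewise-sorted node list.

Identical inputs and `rng_seed` therefore give identical partitions and
byte-identical GEXF, CSV and JSON outputs — an explicit acceptance
property. Because the optimizer starts from singletons and only accepts
improving moves, the returned $Q_\gamma$ is never below the all-singletons
value; on every battery graph with up to 8 nodes it attains the global
optimum found by enumerating all set partitions, and for $\gamma \to 0$ it
returns one community on any connected graph. Louvain remains a heuristic:
global optimality is *verified* on small graphs, not guaranteed in
general.

Cluster reporting (`rank_clusters`) operationalizes "largest, most
prominent themes first": node count descending, ties by total node size,
then by smallest member lemma. All string ordering in the package is
bytewise (C locale) so results do not depend on the session locale.

Graph layout is intentionally out of scope; the GEXF export (undirected,
weighted, node attributes `size` and `modularity_class`, full double
precision) hands topology to dedicated visualization tools.

## The synthetic corpus generator

Real corpora of this kind are typically proprietary exports that cannot be
redistributed, so validation uses `generate_corpus()`, a planted-topic
generator whose structure mirrors what the analysis assumes about such
corpora:

* each document belongs to exactly one of `k_topics` topics (hard,
  document-level membership — the simplest structure consistent with
  reading clusters as themes);
* each sentence is a seed sentence with probability `p_seed_sentence`
  (default 0.3); seed sentences alternate deterministically between the two
  seed lemmas, exercising the pooled-seed logic;
* a seed sentence contains each lemma of its document's topic vocabulary
  independently with `p_topic_lemma` (default 0.8) and each background
  lemma with `p_noise_lemma` (default 0.02); non-seed sentences draw
  background lemmas only (a sentence that would come out empty receives one
  uniformly chosen background lemma, since sentences are non-empty by
  definition);
* each document carries a descriptor token ("corona", as an own one-token
  sentence, so it never perturbs the seed-sentence statistics) with
  probability `p_descriptor_doc` (default 0.9) — the complement is the
  fraction the descriptor filter should remove;
* documents have 3–6 sentences by default; all draws come from one seeded
  RNG, so generation is fully deterministic given `rng_seed`.

The ground truth records lemma-to-topic and document-to-topic assignments
and each topic lemma's expected frequency, `p_topic_lemma` times the
topic's realized share of seed sentences. Recovery is scored as the
adjusted Rand index between planted topics and modularity classes,
restricted to planted lemmas present in the network (`recovery_score`,
delegated to `mclust::adjustedRandIndex` and cross-checked in the tests
against an independent pair-counting implementation). Under the
well-separated reference condition — 3 topics × 10 lemmas,
`p_topic_lemma = 0.8`, `p_noise_lemma = 0.02`, 500 documents,
$\gamma = 0.5$ — the pipeline recovers the planted structure with
ARI ≥ 0.9 in at least 4 of 5 seeded runs (in practice, ARI = 1).

What the generator does **not** emulate — and hence what passing tests do
not show about real data: natural syntax and morphology beyond optional
"-en" inflection suffixes, code-switching and multilingual mixing inside a
document, bursty or correlated topic usage over time, overlapping topic
membership, and realistic metadata. The generator validates the *machinery*
(counting, graph construction, optimization, export), not the linguistic
adequacy of any particular lemmatizer on real German text.

## Numerical and degenerate-input choices

* Frequencies are exact integer ratios; text output uses `%.17g` so
  read-back is bit-exact.
* Louvain gain comparisons use absolute tolerance 1e-12; modularity is
  recomputed from the final assignment rather than accumulated, so the
  reported $Q_\gamma$ cannot drift from the partition.
* Zero seed sentences is a distinct, named error ("no seed sentences
  found"), not an empty table; an all-filtered network is an error, not an
  empty graph; an empty descriptor list is a configuration error.
* Unparseable dates become `NA` with a warning rather than dropping the
  document — the analysis is not longitudinal, so a bad date should not
  cost a text.
* Documents in an unsupported language are kept with code "und" and the
  union of all stopword lists; `language_filter` exists because mixed-
  language corpora can otherwise blur German-lemma figures, and the right
  policy (filter, translate, or analyze jointly) is the analyst's call.

## Problem sizes used in the shipped checks

The test suite and the acceptance script are sized for a laptop run:
random-corpus oracle comparisons use up to 50 sentences × 20 lemmas (100
corpora), exhaustive modularity enumeration goes up to 8 nodes (4,140
partitions), and end-to-end recovery runs use 500 synthetic documents.
These sizes were chosen as the smallest at which each property is
informative; the implementation itself has no such limits, and corpora of a
few thousand documents run in seconds.

## Known limitations

* The fallback lemmatizer's German dictionary is intentionally small;
  real-corpus work should plug in a proper morphological lemmatizer via
  `lemmatizer_backend()`.
* Sentence segmentation is rule-based; exotic punctuation, quotes around
  terminators, or abbreviation lists missing a form can over- or
  under-split.
* Louvain with a resolution parameter inherits the known behaviours of
  modularity optimization (resolution limit, degeneracy of near-optimal
  partitions); the seeded determinism makes runs reproducible, not the
  optimum unique.
* Association is raw sentence co-occurrence by design: no PMI, tf-idf or
  embedding similarity, so high-frequency lemmas dominate unless filtered
  by `min_node_freq` / stopword policy.
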