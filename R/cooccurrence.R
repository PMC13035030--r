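#' Select the seed-containing sentences
#'
#' @param sentences A `tokenized_sentences` data.frame from
#'   [lemmatize_corpus()].
#' @return The subset with `contains_seed = TRUE`, order preserved.
#' @export
collect_seed_sentences <- function(sentences) {
  stopifnot(is.data.frame(sentences), "contains_seed" %in% names(sentences))
  out <- sentences[sentences$contains_seed, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Sentence -> unique lemma set; multiplicity within a sentence is collapsed
# because the statistic counts sentences, not token pairs.
sentence_sets <- function(sentences) lapply(sentences$lemmas, unique)

#' Seed co-occurrence frequencies and pairwise sentence co-occurrence counts
#'
#' The central statistic: for every non-seed lemma, the fraction of
#' seed-containing sentences in which it appears (a conditional frequency on
#' the 0-1 scale; a lemma present in every seed sentence scores exactly 1).
#' Lemmas that never share a sentence with a seed are simply absent from the
#' table — they are the "crossed cells" of a co-occurrence plot. Pairwise
#' counts record, for every unordered lemma pair (seed lemmas included), in
#' how many seed sentences both appear.
#'
#' @param seed_sentences Seed-containing `tokenized_sentences`, e.g. from
#'   [collect_seed_sentences()]. Must be non-empty.
#' @param lexicon A [seed_lexicon()]; its `seed_lemmas` are excluded from
#'   `freq` (their conditional frequency is 1 by construction) but kept in
#'   `lemma_totals` and in the pair counts.
#' @param window "sentence" (default) counts each sentence separately;
#'   "document" first merges all listed sentences of a document into one
#'   lemma set, giving a per-document variant of the statistic.
#' @return An object of class `cooc_table`: a list with
#'   `n_seed_sentences`, `freq` (named numeric in (0, 1]),
#'   `lemma_totals` (named integer), `pair_counts` (data.frame `lemma_a`,
#'   `lemma_b`, `count` with `lemma_a` < `lemma_b` bytewise) and
#'   `seed_lemmas`.
#' @export
compute_frequencies <- function(seed_sentences, lexicon = seed_lexicon(),
                                window = c("sentence", "document")) {
  window <- match.arg(window)
  if (!is.data.frame(seed_sentences) || nrow(seed_sentences) == 0L)
    stage_stop("cooccurrence", "no seed sentences found")
  sets <- sentence_sets(seed_sentences)
  if (window == "document") {
    sets <- lapply(split(sets, seed_sentences$doc_id), function(s)
      unique(unlist(s)))
    sets <- sets[unique(seed_sentences$doc_id)]  # stable document order
  }
  n <- length(sets)
  seeds <- lexicon$seed_lemmas

  totals_tab <- table(unlist(sets))
  lemma_totals <- stats::setNames(as.integer(totals_tab), names(totals_tab))
  lemma_totals <- lemma_totals[lex_order(names(lemma_totals))]

  non_seed <- setdiff(names(lemma_totals), seeds)
  freq <- lemma_totals[non_seed] / n

  a_all <- character(0); b_all <- character(0)
  for (u in sets) {
    if (length(u) < 2L) next
    u <- u[lex_order(u)]
    pr <- utils::combn(u, 2L)
    a_all <- c(a_all, pr[1L, ]); b_all <- c(b_all, pr[2L, ])
  }
  if (length(a_all)) {
    key <- paste0(a_all, "\x1f", b_all)
    tab <- table(key)
    parts <- stringi::stri_split_fixed(names(tab), "\x1f", n = 2L)
    pair_counts <- data.frame(
      lemma_a = vapply(parts, `[`, character(1), 1L),
      lemma_b = vapply(parts, `[`, character(1), 2L),
      count = as.integer(tab),
      stringsAsFactors = FALSE
    )
    pair_counts <- pair_counts[lex_order(pair_counts$lemma_a,
                                         pair_counts$lemma_b), , drop = FALSE]
    rownames(pair_counts) <- NULL
  } else {
    pair_counts <- data.frame(lemma_a = character(0), lemma_b = character(0),
                              count = integer(0), stringsAsFactors = FALSE)
  }

  structure(
    list(n_seed_sentences = n,
         freq = freq,
         lemma_totals = lemma_totals,
         pair_counts = pair_counts,
         seed_lemmas = seeds),
    class = "cooc_table"
  )
}

#' @export
print.cooc_table <- function(x, ...) {
  cat(sprintf("<cooc_table> %d seed sentences, %d co-occurring lemmas, %d pairs\n",
              x$n_seed_sentences, length(x$freq), nrow(x$pair_counts)))
  invisible(x)
}

#' Look up a pairwise sentence co-occurrence count
#'
#' @param table A `cooc_table`.
#' @param a,b Lemma strings (order irrelevant).
#' @return Integer count (0 if the pair never co-occurs).
#' @export
pair_count <- function(table, a, b) {
  stopifnot(inherits(table, "cooc_table"))
  o <- lex_order(c(a, b))
  lo <- c(a, b)[o[1L]]; hi <- c(a, b)[o[2L]]
  hit <- table$pair_counts$lemma_a == lo & table$pair_counts$lemma_b == hi
  if (any(hit)) table$pair_counts$count[hit][1L] else 0L
}

#' Top lemmas by seed co-occurrence frequency
#'
#' @param table A `cooc_table`.
#' @param k Number of lemmas to return (>= 1); if larger than the table, the
#'   whole table is returned sorted.
#' @return data.frame with columns `lemma` and `frequency`, sorted by
#'   descending frequency, ties broken lexicographically.
#' @export
top_k_lemmas <- function(table, k) {
  stopifnot(inherits(table, "cooc_table"), k >= 1)
  lem <- names(table$freq)
  ord <- lex_order(-table$freq, lem)
  take <- utils::head(ord, k)
  data.frame(lemma = lem[take], frequency = unname(table$freq[take]),
             stringsAsFactors = FALSE)
}
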