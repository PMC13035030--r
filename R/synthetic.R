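#' Specification of a planted-topic synthetic corpus
#'
#' Describes the generative model behind [generate_corpus()]: documents get
#' one topic each; a minority of sentences carry a seed lemma; within a seed
#' sentence the active topic's vocabulary appears with high probability and
#' background vocabulary leaks in as noise; non-seed sentences contain
#' background vocabulary only; most documents carry a topical descriptor
#' token so the descriptor filter retains them.
#'
#' @param n_docs Number of documents (> 0).
#' @param sentences_per_doc Integer range `c(lo, hi)` of sentences per
#'   document.
#' @param k_topics Number of planted topics (> 0).
#' @param vocab_per_topic Topic-specific lemmas per topic (> 0).
#' @param background_vocab Number of background lemmas (> 0).
#' @param p_seed_sentence Probability a sentence is a seed sentence, in
#'   (0, 1].
#' @param p_topic_lemma Probability each active-topic lemma appears in a
#'   seed sentence, in (0, 1].
#' @param p_noise_lemma Probability each background lemma appears in a
#'   sentence, in [0, 1).
#' @param p_descriptor_doc Probability a document carries a descriptor
#'   token, in (0, 1].
#' @param rng_seed Integer seed; generation is fully deterministic given it.
#' @param inflect If `TRUE`, topic/background lemmas are sometimes emitted
#'   with an "-en" inflection suffix, exercising the fallback lemmatizer's
#'   suffix rules.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_docs = 300L,
                           sentences_per_doc = c(3L, 6L),
                           k_topics = 3L,
                           vocab_per_topic = 10L,
                           background_vocab = 30L,
                           p_seed_sentence = 0.3,
                           p_topic_lemma = 0.8,
                           p_noise_lemma = 0.02,
                           p_descriptor_doc = 0.9,
                           rng_seed = 1L,
                           inflect = FALSE) {
  problems <- character(0)
  chk <- function(ok, msg) if (!ok) problems <<- c(problems, msg)
  chk(is.numeric(n_docs) && n_docs >= 1, "n_docs must be >= 1")
  chk(is.numeric(sentences_per_doc) && length(sentences_per_doc) == 2L &&
        sentences_per_doc[1] >= 1 &&
        sentences_per_doc[2] >= sentences_per_doc[1],
      "sentences_per_doc must be an increasing range with lo >= 1")
  chk(is.numeric(k_topics) && k_topics >= 1, "k_topics must be >= 1")
  chk(is.numeric(vocab_per_topic) && vocab_per_topic >= 1,
      "vocab_per_topic must be >= 1")
  chk(is.numeric(background_vocab) && background_vocab >= 1,
      "background_vocab must be >= 1")
  chk(is.numeric(p_seed_sentence) && p_seed_sentence > 0 &&
        p_seed_sentence <= 1, "p_seed_sentence must lie in (0, 1]")
  chk(is.numeric(p_topic_lemma) && p_topic_lemma > 0 && p_topic_lemma <= 1,
      "p_topic_lemma must lie in (0, 1]")
  chk(is.numeric(p_noise_lemma) && p_noise_lemma >= 0 && p_noise_lemma < 1,
      "p_noise_lemma must lie in [0, 1)")
  chk(is.numeric(p_descriptor_doc) && p_descriptor_doc > 0 &&
        p_descriptor_doc <= 1, "p_descriptor_doc must lie in (0, 1]")
  if (length(problems))
    stop("invalid synthetic_spec: ", paste(problems, collapse = "; "),
         call. = FALSE)
  structure(
    list(n_docs = as.integer(n_docs),
         sentences_per_doc = as.integer(sentences_per_doc),
         k_topics = as.integer(k_topics),
         vocab_per_topic = as.integer(vocab_per_topic),
         background_vocab = as.integer(background_vocab),
         p_seed_sentence = p_seed_sentence,
         p_topic_lemma = p_topic_lemma,
         p_noise_lemma = p_noise_lemma,
         p_descriptor_doc = p_descriptor_doc,
         rng_seed = as.integer(rng_seed),
         inflect = isTRUE(inflect)),
    class = "synthetic_spec"
  )
}

#' Generate a synthetic corpus with planted topic structure
#'
#' Emits a [corpus()] whose documents follow the generative model of
#' [synthetic_spec()], plus the ground truth needed to score recovery:
#' which lemma belongs to which topic, which document belongs to which
#' topic, and the expected seed co-occurrence frequency of every topic
#' lemma (`p_topic_lemma` times the topic's realized share of seed
#' sentences). Topic vocabularies, the background vocabulary and the seed
#' lemmas are pairwise disjoint by construction. Seed sentences alternate
#' deterministically between the lexicon's seed lemmas, so pooled-seed
#' analysis is exercised.
#'
#' @param spec A [synthetic_spec()].
#' @param lexicon A [seed_lexicon()]; its seed lemmas are planted and its
#'   first descriptor covering the generated language ("corona") marks
#'   documents for the descriptor filter.
#' @param channel Channel label for the generated documents.
#' @return List with elements `corpus` (a [corpus()]) and `truth` (class
#'   `ground_truth`: `lemma_topic`, `doc_topic`, `expected_freq`,
#'   `n_seed_sentences`).
#' @export
generate_corpus <- function(spec, lexicon = seed_lexicon(),
                            channel = c("social", "news")) {
  stopifnot(inherits(spec, "synthetic_spec"))
  channel <- match.arg(channel)
  topic_vocab <- lapply(seq_len(spec$k_topics), function(t)
    sprintf("topic%d-w%02d", t, seq_len(spec$vocab_per_topic)))
  bg_vocab <- sprintf("bg-w%03d", seq_len(spec$background_vocab))
  seeds <- lexicon$seed_lemmas
  descriptor <- "corona"

  res <- with_seed(spec$rng_seed, {
    doc_topic <- sample.int(spec$k_topics, spec$n_docs, replace = TRUE)
    seed_counter <- 0L
    seed_sent_by_topic <- integer(spec$k_topics)
    texts <- character(spec$n_docs)
    maybe_inflect <- function(words) {
      if (!spec$inflect || !length(words)) return(words)
      flip <- stats::runif(length(words)) < 0.3
      words[flip] <- paste0(words[flip], "en")
      words
    }
    for (i in seq_len(spec$n_docs)) {
      t <- doc_topic[i]
      n_sent <- sample(seq(spec$sentences_per_doc[1],
                           spec$sentences_per_doc[2]), 1L)
      sents <- character(n_sent)
      for (s in seq_len(n_sent)) {
        if (stats::runif(1) < spec$p_seed_sentence) {
          seed_counter <- seed_counter + 1L
          seed_sent_by_topic[t] <- seed_sent_by_topic[t] + 1L
          seed_lemma <- seeds[(seed_counter - 1L) %% length(seeds) + 1L]
          tl <- topic_vocab[[t]][stats::runif(spec$vocab_per_topic) <
                                   spec$p_topic_lemma]
          bl <- bg_vocab[stats::runif(spec$background_vocab) <
                           spec$p_noise_lemma]
          words <- c(seed_lemma, maybe_inflect(c(tl, bl)))
        } else {
          bl <- bg_vocab[stats::runif(spec$background_vocab) <
                           spec$p_noise_lemma]
          if (!length(bl)) bl <- sample(bg_vocab, 1L)
          words <- maybe_inflect(bl)
        }
        sents[s] <- paste0(paste(words, collapse = " "), ".")
      }
      if (stats::runif(1) < spec$p_descriptor_doc)
        sents <- c(sents, paste0(descriptor, "."))
      texts[i] <- paste(sents, collapse = " ")
    }
    list(doc_topic = doc_topic, texts = texts,
         seed_sent_by_topic = seed_sent_by_topic)
  })

  docs <- data.frame(
    doc_id = sprintf("syn_%05d", seq_len(spec$n_docs)),
    text = res$texts,
    date = as.Date("2020-01-01") + (seq_len(spec$n_docs) - 1L) %% 800L,
    source = "synthetic-generator",
    language = "de",
    channel = channel,
    stringsAsFactors = FALSE
  )
  corp <- corpus(docs, provenance = sprintf(
    "synthetic: k=%d, n_docs=%d, rng_seed=%d",
    spec$k_topics, spec$n_docs, spec$rng_seed))

  lemma_topic <- stats::setNames(
    rep(seq_len(spec$k_topics), each = spec$vocab_per_topic),
    unlist(topic_vocab))
  n_seed <- sum(res$seed_sent_by_topic)
  share <- if (n_seed > 0) res$seed_sent_by_topic / n_seed
           else rep(0, spec$k_topics)
  expected_freq <- stats::setNames(
    spec$p_topic_lemma * share[lemma_topic], names(lemma_topic))
  truth <- structure(
    list(lemma_topic = lemma_topic,
         doc_topic = stats::setNames(res$doc_topic, docs$doc_id),
         expected_freq = expected_freq,
         n_seed_sentences = n_seed),
    class = "ground_truth"
  )
  list(corpus = corp, truth = truth)
}

#' Agreement between planted topics and recovered modularity classes
#'
#' Adjusted Rand index between the planted lemma-to-topic assignment and
#' the modularity classes of a partition, restricted to planted topic
#' lemmas that are present in the partition. 1 means identical clusterings
#' up to relabeling; 0 is chance-level agreement.
#'
#' @param truth A `ground_truth` from [generate_corpus()].
#' @param partition A `semnet_partition` (or named membership vector).
#' @return The ARI, a number in [-1, 1].
#' @export
recovery_score <- function(truth, partition) {
  stopifnot(inherits(truth, "ground_truth"))
  m <- if (inherits(partition, "semnet_partition")) partition$membership
       else partition
  if (!length(m)) stop("partition is empty", call. = FALSE)
  common <- intersect(names(truth$lemma_topic), names(m))
  if (!length(common))
    stop("no overlapping lemmas between ground truth and partition",
         call. = FALSE)
  mclust::adjustedRandIndex(truth$lemma_topic[common], m[common])
}
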