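# Independent brute-force oracles. These deliberately share no code with the
# package internals they check.

# Build a tokenized_sentences data.frame from a list of lemma vectors.
make_sentences <- function(lemma_sets, seeds = c("fehlinformation",
                                                 "desinformation"),
                           doc_id = "d1") {
  n <- length(lemma_sets)
  out <- data.frame(doc_id = rep(doc_id, length.out = n),
                    sent_index = seq_len(n) - 1L,
                    contains_seed = vapply(lemma_sets, function(l)
                      any(l %in% seeds), logical(1)),
                    stringsAsFactors = FALSE)
  out$lemmas <- lemma_sets
  out <- out[c("doc_id", "sent_index", "lemmas", "contains_seed")]
  class(out) <- c("tokenized_sentences", "data.frame")
  out
}

# Brute-force seed co-occurrence statistics: explicit double loops over
# sentences and lemma pairs.
oracle_cooc <- function(lemma_sets, seeds) {
  seed_sets <- Filter(function(s) any(s %in% seeds), lemma_sets)
  n <- length(seed_sets)
  vocab <- sort(unique(unlist(seed_sets)))
  totals <- integer(0)
  for (v in vocab) {
    cnt <- 0L
    for (s in seed_sets) if (v %in% s) cnt <- cnt + 1L
    totals[v] <- cnt
  }
  freq <- totals[setdiff(vocab, seeds)] / n
  pairs <- list()
  for (i in seq_along(vocab)) {
    for (j in seq_along(vocab)) {
      if (i >= j) next
      a <- vocab[i]; b <- vocab[j]
      cnt <- 0L
      for (s in seed_sets) if (a %in% s && b %in% s) cnt <- cnt + 1L
      if (cnt > 0L) pairs[[paste(a, b, sep = "\x1f")]] <- cnt
    }
  }
  list(n = n, freq = freq, totals = totals, pairs = pairs)
}

# All set partitions of n elements via restricted growth strings.
enumerate_partitions <- function(n) {
  out <- list()
  rec <- function(prefix, maxid) {
    k <- length(prefix)
    if (k == n) { out[[length(out) + 1L]] <<- prefix; return(invisible()) }
    for (v in seq_len(maxid + 1L)) rec(c(prefix, v), max(maxid, v))
  }
  rec(1L, 1L)
  out
}

# Globally optimal resolution modularity by exhaustive enumeration.
oracle_best_modularity <- function(network, gamma) {
  n <- nrow(network$nodes)
  best <- -Inf
  for (p in enumerate_partitions(n)) {
    m <- stats::setNames(p, network$nodes$lemma)
    q <- modularity_score(network, m, resolution = gamma)
    if (q > best) best <- q
  }
  best
}

# Pair-counting adjusted Rand index from the contingency table.
oracle_ari <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n2 <- comb2(length(a))
  expected <- sum_a * sum_b / n2
  maxi <- (sum_a + sum_b) / 2
  if (maxi == expected) return(1)
  (sum_ij - expected) / (maxi - expected)
}

# Random lemma-set fixtures for property tests.
random_sentences <- function(n_sent, vocab_size, seeds, seed) {
  vocab <- sprintf("w%02d", seq_len(vocab_size))
  withr::with_seed(seed, {
    lapply(seq_len(n_sent), function(i) {
      s <- sample(vocab, sample(1:5, 1), replace = FALSE)
      if (stats::runif(1) < 0.5)
        s <- c(sample(seeds, 1), s)
      s
    })
  })
}

# Small unit-weight semnet from an edge list given as a 2-column matrix.
graph_fixture <- function(edges_chr, weights = NULL) {
  nodes <- sort(unique(as.vector(edges_chr)))
  if (is.null(weights)) weights <- rep(1, nrow(edges_chr))
  semnet(nodes, data.frame(from = edges_chr[, 1], to = edges_chr[, 2],
                           weight = weights, stringsAsFactors = FALSE))
}

two_triangles <- function() {
  graph_fixture(rbind(c("a", "b"), c("a", "c"), c("b", "c"),
                      c("d", "e"), c("d", "f"), c("e", "f")))
}
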