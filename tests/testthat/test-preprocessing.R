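mini_corpus <- function(texts, language = "de", channel = "news") {
  corpus(data.frame(
    doc_id = sprintf("d%02d", seq_along(texts)),
    text = texts,
    date = as.Date("2021-06-01"),
    source = "test",
    language = language,
    channel = channel,
    stringsAsFactors = FALSE
  ), provenance = "fixture")
}

test_that("descriptor filter keeps whole-token matches only", {
  corp <- mini_corpus(c(
    "Die Pandemie dauert an",            # "Pandemie" is a descriptor
    "Guten Morgen zusammen!",            # no descriptor
    "Der Coronavirus-Test war negativ",  # hyphen compound: not "coronavirus"
    "Das Covid-19 Zertifikat gilt",      # "covid-19" matches as one token
    "Impfung gegen das Coronavirus"      # "coronavirus"
  ))
  kept <- suppressMessages(filter_by_descriptors(corp, seed_lexicon()))
  expect_equal(kept$documents$doc_id, c("d01", "d04", "d05"))
})

test_that("descriptor filter counts a hand-annotated mixed fixture", {
  texts <- c(sprintf("Bericht %d über die Seuche im Land", 1:4),
             sprintf("Wetterbericht Nummer %d für morgen", 1:6))
  corp <- mini_corpus(texts)
  kept <- suppressMessages(filter_by_descriptors(corp, seed_lexicon()))
  expect_equal(length(kept), 4L)
  expect_true(all(grepl("Seuche", kept$documents$text)))
})

test_that("descriptor filtering is idempotent and order-preserving", {
  gen <- generate_corpus(synthetic_spec(n_docs = 50, rng_seed = 11))
  once <- suppressMessages(filter_by_descriptors(gen$corpus))
  twice <- suppressMessages(filter_by_descriptors(once))
  expect_identical(once$documents, twice$documents)
  expect_identical(once$documents$doc_id,
                   intersect(gen$corpus$documents$doc_id,
                             once$documents$doc_id))
})

test_that("an empty descriptor list is a configuration error", {
  corp <- mini_corpus("Text über die Pandemie")
  lex <- seed_lexicon()
  lex$descriptor_terms <- character(0)
  expect_error(filter_by_descriptors(corp, lex), "descriptor term list")
})

test_that("sentence segmentation splits on terminators and newlines", {
  expect_equal(segment_sentences("A. B? C!"), c("A.", "B?", "C!"))
  expect_equal(segment_sentences("Kein Terminator hier"),
               "Kein Terminator hier")
  expect_equal(segment_sentences("Erste Zeile\nZweite Zeile"),
               c("Erste Zeile", "Zweite Zeile"))
  # decimal points and ellipses do not split mid-number / mid-token
  expect_equal(segment_sentences("Es waren 3.5 Prozent. Mehr nicht."),
               c("Es waren 3.5 Prozent.", "Mehr nicht."))
})

test_that("abbreviations do not terminate sentences", {
  expect_equal(segment_sentences("Dr. Müller kam."), "Dr. Müller kam.")
  expect_equal(segment_sentences("Das gilt z.B. hier. Und dort."),
               c("Das gilt z.B. hier.", "Und dort."))
  # custom abbreviation list overrides the built-in one
  expect_equal(segment_sentences("Dr. Müller kam.", abbreviations = "Nr."),
               c("Dr.", "Müller kam."))
})

test_that("segmentation covers every non-whitespace character", {
  texts <- c("A. B? C!", "Dr. Müller kam. Dann ging er.",
             "Zeile eins\nz.B. Zeile zwei! Ohne Ende")
  for (tx in texts) {
    sents <- segment_sentences(tx)
    expect_identical(gsub("\\s", "", paste(sents, collapse = "")),
                     gsub("\\s", "", tx))
  }
})

test_that("lemmatization maps inflections, seeds and surface forms", {
  corp <- mini_corpus("Fehlinformationen verbreiten sich.")
  sents <- lemmatize_corpus(corp)
  expect_equal(nrow(sents), 1L)
  expect_equal(sents$lemmas[[1]], c("fehlinformation", "verbreiten"))
  expect_true(sents$contains_seed[1])

  # foreign-language surface forms map onto the seed lemmas
  corp2 <- mini_corpus("Reading about misinformation here", language = "en")
  s2 <- lemmatize_corpus(corp2)
  expect_true("fehlinformation" %in% s2$lemmas[[1]])
  expect_true(s2$contains_seed[1])
})

test_that("numeric-only and punctuation-only sentences are dropped, hyphens kept", {
  corp <- mini_corpus(c("42 100. !!! Die Corona-Impfung wirkt."))
  sents <- lemmatize_corpus(corp)
  expect_equal(nrow(sents), 1L)
  expect_true("corona-impfung" %in% sents$lemmas[[1]])
  expect_false(any(c("42", "100") %in% sents$lemmas[[1]]))
})

test_that("seed sentence count matches a hand count on a six-sentence fixture", {
  corp <- mini_corpus(paste(
    "Desinformation schadet allen.",
    "Das Wetter war heute schön.",
    "Niemand las den Bericht.",
    "Die Desinformation nahm zu!",
    "Alles blieb ruhig.",
    "Das Dorf schlief."))
  sents <- lemmatize_corpus(corp)
  expect_equal(nrow(sents), 6L)
  expect_equal(sum(sents$contains_seed), 2L)
  expect_equal(sents$sent_index, 0:5)
})

test_that("the fallback lemmatizer is deterministic and idempotent", {
  lz <- fallback_lemmatizer(known_lemmas = c("topic1-w01"))
  toks <- c("fehlinformationen", "verbreiten", "lügen", "topic1-w01en",
            "unbekannteswort")
  once <- lz$fn(toks, "de")
  expect_identical(once, lz$fn(toks, "de"))
  expect_identical(lz$fn(once, "de"), once)
  expect_equal(once, c("fehlinformation", "verbreiten", "lüge",
                       "topic1-w01", "unbekannteswort"))
})

test_that("stopword policies: builtin drops function words, none keeps them", {
  corp <- mini_corpus("Die Desinformation ist ein Problem.")
  with_sw <- lemmatize_corpus(corp)
  expect_false(any(c("die", "ist", "ein") %in% with_sw$lemmas[[1]]))
  no_sw <- lemmatize_corpus(corp, config = run_config(stopword_policy = "none"))
  expect_true("die" %in% no_sw$lemmas[[1]])
  # seeds are never removed even if someone lists them as stopwords
  f <- tempfile(); writeLines(c("desinformation", "problem"), f)
  custom <- lemmatize_corpus(corp, config = run_config(
    stopword_policy = "custom", stopword_file = f))
  expect_true("desinformation" %in% custom$lemmas[[1]])
  expect_false("problem" %in% custom$lemmas[[1]])
})

test_that("contains_seed ignores sentence order and lemma duplication", {
  base <- list(c("fehlinformation", "a", "b"), c("c", "d"))
  shuffled <- list(c("c", "d"), c("b", "fehlinformation", "a",
                                  "fehlinformation"))
  s1 <- make_sentences(base)
  s2 <- make_sentences(shuffled)
  expect_equal(sort(s1$contains_seed), sort(s2$contains_seed))
})

test_that("a failing backend reports the document id", {
  corp <- mini_corpus("Etwas Text über Corona.")
  bad <- lemmatizer_backend("broken", "de",
                            function(tokens, language) stop("boom"))
  expect_error(lemmatize_corpus(corp, backend = bad), "d01")
})
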