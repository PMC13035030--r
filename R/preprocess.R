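#' Built-in stopword list
#'
#' Small per-language function-word lists shipped with the package. Used by
#' [lemmatize_corpus()] when `stopword_policy = "builtin"`; for documents of
#' undetermined language ("und") the union of all four lists applies.
#'
#' @param language ISO 639-1 code: "de", "fr", "it", "en", or "und".
#' @return Character vector of lowercase stopwords.
#' @export
builtin_stopwords <- function(language = c("de", "fr", "it", "en", "und")) {
  language <- match.arg(language)
  langs <- if (language == "und") c("de", "fr", "it", "en") else language
  unique(unlist(lapply(langs, function(l)
    read_lines_utf8(pkg_file("extdata", sprintf("stopwords_%s.txt", l))))))
}

builtin_abbreviations <- function(language) {
  f <- system.file("extdata", sprintf("abbrev_%s.txt", language),
                   package = "seednet")
  if (!nzchar(f)) f <- pkg_file("extdata", "abbrev_de.txt")
  read_lines_utf8(f)
}

#' Keep only documents mentioning at least one topical descriptor
#'
#' A document is retained when at least one of its tokens matches a
#' descriptor term as a case-insensitive whole token. Tokens are split on
#' whitespace and punctuation, except that internal hyphens are kept, so the
#' descriptor "covid-19" matches the token "Covid-19" but "covid" does not
#' match inside "coronavirus". Document order is preserved; retained and
#' removed counts are reported via `message()`.
#'
#' @param x A [corpus()]; must be non-empty.
#' @param lexicon A [seed_lexicon()] providing `descriptor_terms`.
#' @return The filtered [corpus()].
#' @export
filter_by_descriptors <- function(x, lexicon = seed_lexicon()) {
  stopifnot(inherits(x, "corpus"))
  if (nrow(x$documents) == 0L)
    stage_stop("filter", "corpus is empty")
  if (!inherits(lexicon, "seed_lexicon") ||
      length(lexicon$descriptor_terms) == 0L)
    stage_stop("filter", "descriptor term list is empty")
  toks <- tokenize(x$documents$text)
  keep <- vapply(toks, function(t) any(t %in% lexicon$descriptor_terms),
                 logical(1))
  message(sprintf("filter_by_descriptors: %d retained, %d removed",
                  sum(keep), sum(!keep)))
  out <- x
  out$documents <- x$documents[keep, , drop = FALSE]
  rownames(out$documents) <- NULL
  out$provenance <- paste0(x$provenance, " | descriptor-filtered")
  out
}

#' Split a text into sentences
#'
#' Rule-based segmentation: a run of `.`, `!` or `?` followed by whitespace
#' (or end of line) terminates a sentence, unless the token ending in the
#' period is on the abbreviation exception list ("Dr.", "z.B.", ...).
#' Newlines always split, which accommodates social-media posts that lack
#' terminal punctuation. A text without any terminator is one sentence. The
#' concatenated sentences cover every non-whitespace character of the input.
#'
#' @param text A single character string (non-empty).
#' @param language ISO 639-1 code selecting the built-in abbreviation list.
#' @param abbreviations Optional character vector overriding the built-in
#'   abbreviation list (entries include the trailing period, e.g. "Dr.").
#' @return Character vector of sentence strings, in order.
#' @export
#' @examples
#' segment_sentences("Eins. Zwei? Drei!")
#' segment_sentences("Dr. Müller kam.")
segment_sentences <- function(text, language = "de", abbreviations = NULL) {
  stopifnot(is.character(text), length(text) == 1L)
  text <- stringi::stri_trans_nfc(text)
  if (!nzchar(trimws(text)))
    stop("cannot segment empty text", call. = FALSE)
  if (is.null(abbreviations))
    abbreviations <- builtin_abbreviations(language)
  lines <- stringi::stri_split_regex(text, "\\r?\\n")[[1]]
  lines <- lines[nzchar(trimws(lines))]
  out <- character(0)
  for (line in lines) {
    locs <- stringi::stri_locate_all_regex(line, "[.!?]+")[[1]]
    cuts <- integer(0)
    if (!is.na(locs[1, 1])) {
      n <- nchar(line)
      for (r in seq_len(nrow(locs))) {
        s <- locs[r, 1]; e <- locs[r, 2]
        # terminator only when followed by whitespace/EOL ("3.5" stays whole)
        after_ok <- e == n ||
          stringi::stri_detect_regex(substr(line, e + 1L, e + 1L), "\\s")
        if (!after_ok) next
        if (substr(line, s, e) == "." || grepl("\\.$", substr(line, s, e))) {
          # token ending at the period: back to the previous whitespace
          pre <- substr(line, 1L, e)
          tok <- stringi::stri_extract_last_regex(pre, "\\S+")
          if (!is.na(tok) && tok %in% abbreviations) next
        }
        cuts <- c(cuts, e)
      }
    }
    starts <- c(1L, cuts + 1L)
    ends <- c(cuts, nchar(line))
    for (i in seq_along(starts)) {
      if (starts[i] > ends[i]) next
      s <- stringi::stri_trim_both(substr(line, starts[i], ends[i]))
      if (nzchar(s)) out <- c(out, s)
    }
  }
  out
}

#' Define a lemmatizer backend
#'
#' Backends are pluggable: any deterministic function mapping a token vector
#' (lowercase, NFC) and a language code to a lemma vector of the same length
#' can drive [lemmatize_corpus()]. A backend must never emit empty lemmas
#' and must be deterministic (same input, same output).
#'
#' @param name Backend name (recorded in run metadata).
#' @param supported_languages Language codes the backend accepts.
#' @param fn `function(tokens, language)` returning one lemma per token.
#' @return An object of class `lemmatizer`.
#' @export
lemmatizer_backend <- function(name, supported_languages, fn) {
  stopifnot(is.character(name), is.function(fn))
  structure(list(name = name,
                 supported_languages = supported_languages,
                 fn = fn),
            class = "lemmatizer")
}

#' Deterministic dictionary + suffix-rule lemmatizer
#'
#' The reference backend shipped with the package: an exception dictionary
#' (German inflected form to lemma, extensible) backed by conservative
#' suffix stripping. A token is (1) looked up in the dictionary; (2) if it
#' already is a known lemma, returned unchanged; (3) otherwise suffixes
#' "en", "es", "e", "n", "s" are tried in that order and the stripped stem
#' is accepted only if it is a known lemma; (4) otherwise the token is its
#' own lemma. Step 2 before step 3 makes the backend idempotent: lemmatizing
#' its own output is a no-op.
#'
#' Unlike a statistical model, this backend has no language understanding —
#' it is exactly as good as its dictionary — but it is fully deterministic
#' and needs no model download, which is what the test suite and the
#' synthetic pipeline require.
#'
#' @param dictionary Named character vector (names = inflected forms,
#'   values = lemmas). Defaults to the German dictionary shipped under
#'   `extdata/lemma_dict_de.tsv`.
#' @param known_lemmas Extra lemmas to treat as already-canonical (the
#'   synthetic generator passes its planted vocabulary here so inflected
#'   variants strip back to it).
#' @return A `lemmatizer` backend named "dictionary-fallback".
#' @export
fallback_lemmatizer <- function(dictionary = NULL, known_lemmas = character(0)) {
  if (is.null(dictionary)) {
    tab <- utils::read.delim(pkg_file("extdata", "lemma_dict_de.tsv"),
                             header = FALSE, colClasses = "character",
                             fileEncoding = "UTF-8")
    dictionary <- stats::setNames(norm_term(tab[[2]]), norm_term(tab[[1]]))
  } else {
    dictionary <- stats::setNames(norm_term(unname(dictionary)),
                                  norm_term(names(dictionary)))
  }
  known <- unique(c(unname(dictionary), norm_term(known_lemmas)))
  suffixes <- c("en", "es", "e", "n", "s")
  fn <- function(tokens, language) {
    vapply(tokens, function(tok) {
      hit <- dictionary[tok]
      if (!is.na(hit)) return(unname(hit))
      if (tok %in% known) return(tok)
      for (sfx in suffixes) {
        if (endsWith(tok, sfx)) {
          stem <- substr(tok, 1L, nchar(tok) - nchar(sfx))
          if (nzchar(stem) && stem %in% known) return(stem)
        }
      }
      tok
    }, character(1), USE.NAMES = FALSE)
  }
  lemmatizer_backend("dictionary-fallback",
                     c("de", "fr", "it", "en", "und"), fn)
}

#' Segment, tokenize and lemmatize a corpus into sentences
#'
#' Every document is split into sentences; each sentence is tokenized
#' (lowercase, NFC, internal hyphens kept so compounds like "corona-impfung"
#' stay one lemma), numeric-only tokens are dropped, tokens are lemmatized
#' by the backend, seed surface forms from other languages are mapped onto
#' the seed lemmas, and stopwords are removed according to the configured
#' policy (seed lemmas are never removed). Sentences left without lemmas are
#' dropped.
#'
#' @param x A [corpus()].
#' @param lexicon A [seed_lexicon()].
#' @param backend A `lemmatizer` (default [fallback_lemmatizer()]).
#' @param config A [run_config()]; `language_filter` restricts the corpus,
#'   `stopword_policy`/`stopword_file` control stopword removal.
#' @return A data.frame of class `tokenized_sentences` with columns
#'   `doc_id`, `sent_index` (0-based position of the sentence within its
#'   document), `lemmas` (list column) and `contains_seed`.
#' @export
lemmatize_corpus <- function(x, lexicon = seed_lexicon(),
                             backend = fallback_lemmatizer(),
                             config = run_config()) {
  stopifnot(inherits(x, "corpus"), inherits(backend, "lemmatizer"))
  docs <- x$documents
  if (!is.null(config$language_filter))
    docs <- docs[docs$language == config$language_filter, , drop = FALSE]

  stop_sets <- new.env(parent = emptyenv())
  stopwords_for <- function(lang) {
    if (config$stopword_policy == "none") return(character(0))
    if (config$stopword_policy == "custom") {
      if (is.null(stop_sets$custom))
        stop_sets$custom <- norm_term(read_lines_utf8(config$stopword_file))
      return(stop_sets$custom)
    }
    if (is.null(stop_sets[[lang]]))
      assign(lang, builtin_stopwords(lang), envir = stop_sets)
    stop_sets[[lang]]
  }

  seeds <- lexicon$seed_lemmas
  smap <- lexicon$extra_seed_surface_forms

  res_doc <- character(0); res_idx <- integer(0)
  res_lem <- list(); res_seed <- logical(0)
  for (i in seq_len(nrow(docs))) {
    did <- docs$doc_id[i]
    lang <- docs$language[i]
    sents <- segment_sentences(docs$text[i], language = lang)
    if (!length(sents)) next
    toks_all <- tokenize(sents)
    for (j in seq_along(toks_all)) {
      toks <- toks_all[[j]]
      toks <- toks[!is_numeric_token(toks)]
      if (!length(toks)) next
      lem <- tryCatch(backend$fn(toks, lang), error = function(e)
        stage_stop("lemmatize", sprintf("backend '%s' failed on doc '%s': %s",
                                        backend$name, did,
                                        conditionMessage(e))))
      if (length(lem) != length(toks) || any(!nzchar(lem)))
        stage_stop("lemmatize",
                   sprintf("backend '%s' violated its contract on doc '%s'",
                           backend$name, did))
      lem <- norm_term(lem)
      mapped <- lem %in% names(smap)
      if (any(mapped)) lem[mapped] <- unname(smap[lem[mapped]])
      sw <- stopwords_for(lang)
      lem <- lem[!(lem %in% sw) | lem %in% seeds]
      if (!length(lem)) next
      res_doc <- c(res_doc, did)
      res_idx <- c(res_idx, j - 1L)
      res_lem <- c(res_lem, list(lem))
      res_seed <- c(res_seed, any(lem %in% seeds))
    }
  }
  out <- data.frame(doc_id = res_doc, sent_index = res_idx,
                    contains_seed = res_seed, stringsAsFactors = FALSE)
  out$lemmas <- res_lem
  out <- out[c("doc_id", "sent_index", "lemmas", "contains_seed")]
  class(out) <- c("tokenized_sentences", "data.frame")
  out
}
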