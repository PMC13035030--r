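#' Topical descriptor terms for pandemic-related corpus filtering
#'
#' The default 15-term descriptor list used to discard documents that never
#' mention the pandemic: English, German, French and Italian tokens for
#' covid / corona / virus / pandemic / epidemic / outbreak, including the
#' hyphenated form "covid-19". Matching is whole-token and case-insensitive,
#' so the list is stored lowercase.
#'
#' @return Character vector of lowercase, NFC-normalized descriptor tokens.
#' @export
#' @examples
#' covid_descriptors()
covid_descriptors <- function() {
  norm_term(c(
    "covid", "corona", "virus", "covid-19", "coronavirus",
    "pandemic", "epidemic", "outbreak",
    "pandémie", "épidémie", "pandemie", "epidemie",
    "seuche", "pandemia", "epidemia"
  ))
}

#' Seed lexicon: seed lemmas, descriptor terms and seed surface forms
#'
#' Bundles the three term sets that condition the whole analysis: the seed
#' lemmas whose sentence-level neighbourhood is measured (by default the
#' German lemmas for misinformation and disinformation), the topical
#' descriptor tokens used for corpus filtering, and extra surface forms in
#' other languages that are mapped onto the seed lemmas after lemmatization.
#'
#' @param seed_lemmas Character vector of seed lemmas (lowercased and
#'   NFC-normalized on construction). Must be non-empty.
#' @param descriptor_terms Character vector of descriptor tokens for
#'   [filter_by_descriptors()]. Must be non-empty.
#' @param extra_seed_surface_forms Named character vector mapping surface
#'   forms (names) to the seed lemma they stand for (values). May be empty.
#' @return An object of class `seed_lexicon`.
#' @export
#' @examples
#' lex <- seed_lexicon()
#' lex$seed_lemmas
seed_lexicon <- function(seed_lemmas = c("fehlinformation", "desinformation"),
                         descriptor_terms = covid_descriptors(),
                         extra_seed_surface_forms = c(
                           "misinformation"   = "fehlinformation",
                           "disinformation"   = "desinformation",
                           "désinformation" = "desinformation",
                           "disinformazione"  = "desinformation"
                         )) {
  if (length(seed_lemmas) == 0L)
    stop("seed_lemmas must be non-empty", call. = FALSE)
  if (length(descriptor_terms) == 0L)
    stop("descriptor_terms must be non-empty", call. = FALSE)
  seed_lemmas <- unique(norm_term(seed_lemmas))
  descriptor_terms <- unique(norm_term(descriptor_terms))
  map <- character(0)
  if (length(extra_seed_surface_forms)) {
    if (is.null(names(extra_seed_surface_forms)) ||
        any(!nzchar(names(extra_seed_surface_forms))))
      stop("extra_seed_surface_forms must be a named vector (surface -> seed)",
           call. = FALSE)
    map <- norm_term(unname(extra_seed_surface_forms))
    names(map) <- norm_term(names(extra_seed_surface_forms))
    bad <- setdiff(unique(map), seed_lemmas)
    if (length(bad))
      stop("surface forms map to unknown seeds: ", paste(bad, collapse = ", "),
           call. = FALSE)
  }
  structure(
    list(seed_lemmas = seed_lemmas,
         descriptor_terms = descriptor_terms,
         extra_seed_surface_forms = map),
    class = "seed_lexicon"
  )
}

#' @export
print.seed_lexicon <- function(x, ...) {
  cat("<seed_lexicon>\n")
  cat("  seeds:      ", paste(x$seed_lemmas, collapse = ", "), "\n")
  cat("  descriptors:", length(x$descriptor_terms), "terms\n")
  cat("  surface forms:", length(x$extra_seed_surface_forms), "\n")
  invisible(x)
}

#' Run configuration for the co-occurrence network pipeline
#'
#' @param resolution Resolution parameter gamma of the modularity objective
#'   (> 0). Smaller values produce fewer, coarser clusters; default 0.5.
#' @param top_k Number of top-ranked lemmas reported by [top_k_lemmas()];
#'   default 30.
#' @param min_node_freq Minimum seed co-occurrence frequency (in [0, 1]) for
#'   a lemma to become a network node; default 0 (keep all co-occurring
#'   lemmas).
#' @param min_edge_count Minimum sentence co-occurrence count for an edge;
#'   default 1.
#' @param rng_seed Integer seed driving every stochastic step (Louvain node
#'   visiting order, synthetic generation).
#' @param language_filter Optional ISO 639-1 code; when set, only documents
#'   in that language are analyzed.
#' @param stopword_policy One of "builtin" (per-language function-word lists
#'   shipped with the package), "none", or "custom" (supply
#'   `stopword_file`).
#' @param stopword_file Path to a UTF-8 stopword list (one token per line);
#'   required when `stopword_policy = "custom"`.
#' @return An object of class `run_config`.
#' @export
#' @examples
#' run_config(resolution = 0.5, rng_seed = 42)
run_config <- function(resolution = 0.5,
                       top_k = 30L,
                       min_node_freq = 0,
                       min_edge_count = 1L,
                       rng_seed = 1L,
                       language_filter = NULL,
                       stopword_policy = c("builtin", "none", "custom"),
                       stopword_file = NULL) {
  stopword_policy <- match.arg(stopword_policy)
  if (!is.numeric(resolution) || length(resolution) != 1L || resolution <= 0)
    stop("resolution must be a positive number", call. = FALSE)
  if (!is.numeric(top_k) || length(top_k) != 1L || top_k < 1)
    stop("top_k must be >= 1", call. = FALSE)
  if (!is.numeric(min_node_freq) || min_node_freq < 0 || min_node_freq > 1)
    stop("min_node_freq must lie in [0, 1]", call. = FALSE)
  if (!is.numeric(min_edge_count) || min_edge_count < 0)
    stop("min_edge_count must be >= 0", call. = FALSE)
  if (stopword_policy == "custom" && is.null(stopword_file))
    stop("stopword_policy = 'custom' requires stopword_file", call. = FALSE)
  structure(
    list(resolution = as.numeric(resolution),
         top_k = as.integer(top_k),
         min_node_freq = as.numeric(min_node_freq),
         min_edge_count = as.integer(min_edge_count),
         rng_seed = as.integer(rng_seed),
         language_filter = language_filter,
         stopword_policy = stopword_policy,
         stopword_file = stopword_file),
    class = "run_config"
  )
}

#' Read a flat key=value configuration file into a run_config
#'
#' Keys mirror the arguments of [run_config()] one to one; unknown keys are
#' an error. Lines starting with `#` and blank lines are ignored.
#'
#' @param path Path to a UTF-8 `key = value` file.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  lines <- read_lines_utf8(path)
  lines <- lines[!startsWith(lines, "#")]
  kv <- stringi::stri_split_regex(lines, "\\s*=\\s*", n = 2L)
  bad <- lengths(kv) != 2L
  if (any(bad))
    stop("malformed config line: ", lines[bad][1L], call. = FALSE)
  keys <- vapply(kv, `[`, character(1), 1L)
  vals <- vapply(kv, `[`, character(1), 2L)
  known <- c("resolution", "top_k", "min_node_freq", "min_edge_count",
             "rng_seed", "language_filter", "stopword_policy", "stopword_file")
  unknown <- setdiff(keys, known)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  args <- stats::setNames(as.list(vals), keys)
  for (k in c("resolution", "top_k", "min_node_freq", "min_edge_count",
              "rng_seed"))
    if (k %in% names(args)) args[[k]] <- as.numeric(args[[k]])
  do.call(run_config, args)
}
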