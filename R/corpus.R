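#' Construct a document corpus
#'
#' A corpus is an ordered collection of documents with stable ordering and
#' unique document ids. Text is NFC-normalized at construction so diacritics
#' compare equal regardless of how the source file encoded them.
#'
#' @param documents data.frame with columns `doc_id`, `text`, `date`
#'   (`Date`, may be `NA`), `source`, `language` (one of de/fr/it/en/und),
#'   `channel` ("news" or "social").
#' @param provenance Free-text description of where the corpus came from
#'   (file, query, generator settings).
#' @return An object of class `corpus`.
#' @export
corpus <- function(documents, provenance = "") {
  required <- c("doc_id", "text", "date", "source", "language", "channel")
  missing_cols <- setdiff(required, names(documents))
  if (length(missing_cols))
    stop("documents is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  documents <- documents[required]
  documents$doc_id <- as.character(documents$doc_id)
  documents$text <- stringi::stri_trans_nfc(as.character(documents$text))
  documents$source <- as.character(documents$source)
  documents$language <- as.character(documents$language)
  documents$channel <- as.character(documents$channel)
  if (!inherits(documents$date, "Date"))
    documents$date <- as.Date(as.character(documents$date))

  dup <- documents$doc_id[duplicated(documents$doc_id)]
  if (length(dup))
    stop("duplicate doc_id: ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  blank <- !nzchar(trimws(documents$text))
  if (any(blank))
    stop("empty text in document(s): ",
         paste(documents$doc_id[blank], collapse = ", "), call. = FALSE)
  ok_lang <- c("de", "fr", "it", "en", "und")
  off <- !(documents$language %in% ok_lang)
  if (any(off)) {
    warning("unsupported language code(s) set to 'und': ",
            paste(unique(documents$language[off]), collapse = ", "),
            call. = FALSE)
    documents$language[off] <- "und"
  }
  if (any(!documents$channel %in% c("news", "social")))
    stop("channel must be 'news' or 'social'", call. = FALSE)
  rownames(documents) <- NULL
  structure(list(documents = documents, provenance = provenance),
            class = "corpus")
}

#' @export
print.corpus <- function(x, ...) {
  cat(sprintf("<corpus> %d documents (%s)\n",
              nrow(x$documents), x$provenance))
  invisible(x)
}

#' @export
length.corpus <- function(x) nrow(x$documents)

# Bytewise (C-locale) lexicographic order: locale-independent determinism.
lex_order <- function(...) order(..., method = "radix")

#' Read a tabular corpus from CSV or JSONL
#'
#' Reads one document per row/line. Column names are supplied explicitly via
#' `schema_map` rather than auto-detected: exports from commercial media
#' databases vary by vintage, and an explicit mapping keeps ingestion
#' deterministic and testable.
#'
#' @param path Path to a UTF-8 CSV (RFC 4180) or JSONL file.
#' @param schema_map Named list/vector mapping canonical fields to column
#'   names in the file. `text` is required; `date`, `source`, `language`
#'   and `doc_id` are optional. A missing `language` mapping yields "und";
#'   a missing `doc_id` mapping generates ids `doc_00001`, ... in file
#'   order.
#' @param channel "news" or "social"; recorded on every document.
#' @param format "auto" (by extension), "csv" or "jsonl".
#' @param date_format Input date pattern for [base::as.Date()]; rows whose
#'   date does not parse keep the document with a `NA` date and a warning.
#' @return A [corpus()]. Rows with empty text are dropped; the retained and
#'   dropped counts are reported via `message()`.
#' @export
read_corpus <- function(path, schema_map = list(text = "text"),
                        channel = c("news", "social"),
                        format = c("auto", "csv", "jsonl"),
                        date_format = "%Y-%m-%d") {
  channel <- match.arg(channel)
  format <- match.arg(format)
  if (!file.exists(path))
    stop("cannot read corpus file: ", path, call. = FALSE)
  if (format == "auto") {
    format <- if (grepl("\\.jsonl$", path, ignore.case = TRUE)) "jsonl"
              else "csv"
  }
  schema_map <- as.list(schema_map)
  if (is.null(schema_map$text))
    stop("schema_map must name the text column", call. = FALSE)

  if (format == "csv") {
    tab <- utils::read.csv(path, colClasses = "character",
                           check.names = FALSE, fileEncoding = "UTF-8")
  } else {
    lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    recs <- lapply(lines, function(l) jsonlite::fromJSON(l))
    cols <- unique(unlist(lapply(recs, names)))
    tab <- as.data.frame(
      lapply(stats::setNames(cols, cols), function(cn)
        vapply(recs, function(r)
          if (is.null(r[[cn]])) NA_character_ else as.character(r[[cn]]),
          character(1))),
      check.names = FALSE, stringsAsFactors = FALSE
    )
  }

  for (field in intersect(names(schema_map),
                          c("text", "date", "source", "language", "doc_id"))) {
    col <- schema_map[[field]]
    if (!col %in% names(tab))
      stop(sprintf("schema_map: column '%s' (field '%s') not found in %s",
                   col, field, path), call. = FALSE)
  }

  get_col <- function(field, default) {
    col <- schema_map[[field]]
    if (is.null(col)) rep(default, nrow(tab)) else tab[[col]]
  }
  text <- tab[[schema_map$text]]
  text[is.na(text)] <- ""
  keep <- nzchar(trimws(text))
  n_dropped <- sum(!keep)

  doc_id <- get_col("doc_id", NA_character_)
  if (all(is.na(doc_id)))
    doc_id <- sprintf("doc_%05d", seq_len(nrow(tab)))
  date_chr <- get_col("date", NA_character_)
  date <- as.Date(date_chr, format = date_format)
  bad_date <- !is.na(date_chr) & nzchar(date_chr) & is.na(date) & keep
  if (any(bad_date))
    warning(sum(bad_date), " unparseable date(s) set to NA", call. = FALSE)

  docs <- data.frame(
    doc_id = doc_id[keep],
    text = text[keep],
    date = date[keep],
    source = {
      s <- get_col("source", "unknown")[keep]
      s[is.na(s)] <- "unknown"; s
    },
    language = {
      l <- norm_term(get_col("language", "und")[keep])
      l[is.na(l) | !nzchar(l)] <- "und"; l
    },
    channel = channel,
    stringsAsFactors = FALSE
  )
  message(sprintf("read_corpus: %d documents retained, %d empty rows dropped",
                  nrow(docs), n_dropped))
  corpus(docs, provenance = paste0("file:", path))
}

#' Write a corpus to CSV or JSONL
#'
#' Emits the same flat schema [read_corpus()] ingests (columns `doc_id`,
#' `text`, `date`, `source`, `language`, `channel`), so generated corpora
#' round-trip through the reader.
#'
#' @param x A [corpus()].
#' @param path Output path; extension `.jsonl` selects JSONL, anything else
#'   CSV.
#' @return Invisibly, `path`.
#' @export
write_corpus <- function(x, path) {
  stopifnot(inherits(x, "corpus"))
  d <- x$documents
  d$date <- ifelse(is.na(d$date), "", format(d$date, "%Y-%m-%d"))
  if (grepl("\\.jsonl$", path, ignore.case = TRUE)) {
    con <- file(path, open = "wb")
    on.exit(close(con))
    for (i in seq_len(nrow(d))) {
      writeLines(jsonlite::toJSON(as.list(d[i, , drop = FALSE]),
                                  auto_unbox = TRUE),
                 con, useBytes = TRUE)
    }
  } else {
    write_csv_utf8(d, path)
  }
  invisible(path)
}

# Deterministic, byte-stable CSV writer (UTF-8, RFC 4180 quoting).
write_csv_utf8 <- function(d, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  esc <- function(v) {
    v <- as.character(v)
    need <- grepl('[",\n\r]', v)
    v[need] <- paste0('"', gsub('"', '""', v[need]), '"')
    v
  }
  writeLines(paste(esc(names(d)), collapse = ","), con, useBytes = TRUE)
  if (nrow(d)) {
    rows <- do.call(paste, c(lapply(d, esc), sep = ","))
    writeLines(rows, con, useBytes = TRUE)
  }
  invisible(path)
}

#' Write an analysis table to CSV
#'
#' Generic CSV exporter for the pipeline's tabular results. For a
#' co-occurrence table it writes the frequency table (columns `lemma`,
#' `count`, `n_seed_sentences`, `frequency`) sorted by descending frequency
#' with lexicographic order between tied lemmas; for a plain data.frame
#' (e.g. a cluster report) it writes the rows in their given, already
#' deterministic order. Frequencies are written at full double precision so
#' re-reading reproduces the values exactly.
#'
#' @param x A `cooc_table` or data.frame.
#' @param path Output CSV path; the parent directory must exist.
#' @param ... Unused.
#' @return Invisibly, `path`.
#' @export
write_table <- function(x, path, ...) UseMethod("write_table")

#' @rdname write_table
#' @export
write_table.cooc_table <- function(x, path, ...) {
  lem <- names(x$freq)
  ord <- lex_order(-x$freq, lem)
  d <- data.frame(
    lemma = lem[ord],
    count = as.integer(x$lemma_totals[lem][ord]),
    n_seed_sentences = x$n_seed_sentences,
    frequency = num_chr(unname(x$freq[ord])),
    stringsAsFactors = FALSE
  )
  write_csv_utf8(d, path)
}

#' @rdname write_table
#' @export
write_table.data.frame <- function(x, path, ...) {
  d <- x
  for (cn in names(d)) {
    if (is.double(d[[cn]])) d[[cn]] <- num_chr(d[[cn]])
  }
  write_csv_utf8(d, path)
}

#' Write pairwise sentence co-occurrence counts to CSV
#'
#' Columns `lemma_a`, `lemma_b`, `count`; each unordered pair appears once
#' with `lemma_a < lemma_b` bytewise, rows sorted lexicographically.
#'
#' @param x A `cooc_table`.
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_pair_counts <- function(x, path) {
  stopifnot(inherits(x, "cooc_table"))
  p <- x$pair_counts
  p <- p[lex_order(p$lemma_a, p$lemma_b), , drop = FALSE]
  rownames(p) <- NULL
  write_csv_utf8(p, path)
}

#' Read back a frequency table written by [write_table()]
#'
#' @param path CSV path produced by `write_table()` on a `cooc_table`.
#' @return data.frame with columns `lemma`, `count`, `n_seed_sentences`,
#'   `frequency` (numeric).
#' @export
read_freq_table <- function(path) {
  d <- utils::read.csv(path, colClasses = "character",
                       check.names = FALSE, fileEncoding = "UTF-8")
  d$count <- as.integer(d$count)
  d$n_seed_sentences <- as.integer(d$n_seed_sentences)
  d$frequency <- as.numeric(d$frequency)
  d
}
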