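# Internal helpers shared across modules.

#' @importFrom stringi stri_trans_nfc stri_trans_tolower stri_extract_all_regex
#' @importFrom stringi stri_detect_regex stri_split_regex stri_trim_both
NULL

# Lowercase + Unicode NFC. All user-supplied terms and all corpus text pass
# through this so that umlauts/diacritics compare equal across sources.
norm_term <- function(x) {
  stringi::stri_trans_tolower(stringi::stri_trans_nfc(x))
}

# Whole tokens: runs of letters/digits, with internal hyphens kept so that
# "covid-19" or "corona-impfung" stay single tokens.
TOKEN_RE <- "[\\p{L}\\p{N}]+(?:-[\\p{L}\\p{N}]+)*"

tokenize <- function(x) {
  toks <- stringi::stri_extract_all_regex(norm_term(x), TOKEN_RE)
  lapply(toks, function(t) if (length(t) == 1L && is.na(t[1L])) character(0) else t)
}

# Numeric-only tokens ("19", "2020-21") carry no lexical content.
is_numeric_token <- function(tok) {
  stringi::stri_detect_regex(tok, "^[\\p{N}]+(?:-[\\p{N}]+)*$")
}

# Run `expr` under a fixed RNG seed without disturbing the caller's RNG state.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# Stage-attributed failure: errors abort with the pipeline stage name so a
# failed run names the stage, not an internal call.
stage_stop <- function(stage, ...) {
  stop(sprintf("[%s] %s", stage, paste0(...)), call. = FALSE)
}

pkg_file <- function(...) {
  system.file(..., package = "seednet", mustWork = TRUE)
}

read_lines_utf8 <- function(path) {
  x <- readLines(path, encoding = "UTF-8", warn = FALSE)
  x <- stringi::stri_trim_both(x)
  x[nzchar(x)]
}

# Numbers in text outputs (CSV, GEXF, JSON paths) are formatted with %.17g:
# round-trips through as.numeric() are exact for doubles.
num_chr <- function(x) {
  vapply(x, function(v) sprintf("%.17g", v), character(1))
}
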