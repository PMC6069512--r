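## Lexicon loading and supplement-mention location.
##
## All lexicon files are UTF-8 TSV with "#" comment lines:
##   supplements:   canonical<TAB>comma-separated variants
##   indicators:    lemma<TAB>class (C|D|S|U) [<TAB>weak]
##   negators:      one word per line
##   abbreviations: abbrev<TAB>expansion
##   stopwords:     one word per line
##   lemmas:        inflected<TAB>lemma  (normalizer exception dictionary)
##   words:         one known lemma per line (e-restoration list)

read_lexicon_lines <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  list(lines = lines[keep], lineno = which(keep))
}

parse_error <- function(path, lineno, msg) {
  stop(sprintf("%s, line %d: %s", basename(path), lineno, msg), call. = FALSE)
}

## Matching key for variant comparison: apostrophes and periods are
## stripped on both sides, so "st. john's wort" matches "st johns wort".
variant_key <- function(x) gsub("[.']", "", tolower(x))

#' Read a supplement lexicon file
#'
#' Each record maps one canonical supplement name to its surface variants
#' (misspellings, brand or compound forms). The canonical name is always a
#' variant of itself; a variant string claimed by two supplements is a
#' validation error because the ambiguity cannot be resolved downstream.
#'
#' @param path TSV file, `canonical<TAB>comma-separated-variants`
#' @return a `supplement_lexicon` object
#' @seealso [load_lexicons()], [find_mentions()]
#' @export
read_supplement_lexicon <- function(path) {
  lx <- read_lexicon_lines(path)
  if (length(lx$lines) == 0L) {
    stop(sprintf("%s: empty supplement lexicon", basename(path)), call. = FALSE)
  }
  entries <- list()
  for (i in seq_along(lx$lines)) {
    parts <- strsplit(lx$lines[i], "\t", fixed = TRUE)[[1]]
    if (length(parts) < 1L || !nzchar(parts[1])) {
      parse_error(path, lx$lineno[i], "missing canonical name")
    }
    canonical <- tolower(trimws(parts[1]))
    variants <- character(0)
    if (length(parts) >= 2L && nzchar(parts[2])) {
      variants <- tolower(trimws(strsplit(parts[2], ",", fixed = TRUE)[[1]]))
    }
    variants <- unique(c(canonical, variants[nzchar(variants)]))
    if (canonical %in% names(entries)) {
      parse_error(path, lx$lineno[i],
                  sprintf("duplicate canonical name '%s'", canonical))
    }
    entries[[canonical]] <- variants
  }
  new_supplement_lexicon(entries, source = path)
}

new_supplement_lexicon <- function(entries, source = NA_character_) {
  ## within one supplement, variants that collide after apostrophe/period
  ## stripping are the same surface form: keep the first spelling
  entries <- lapply(entries, function(v) v[!duplicated(variant_key(v))])
  all_keys <- unlist(lapply(entries, variant_key), use.names = FALSE)
  dup <- unique(all_keys[duplicated(all_keys)])
  if (length(dup)) {
    stop(sprintf("variant(s) mapped to more than one supplement: %s",
                 paste(dup, collapse = ", ")), call. = FALSE)
  }
  ## Precompute the token form of every variant for mention matching,
  ## longest token run first so greedy matching prefers full phrases.
  canon <- rep(names(entries), lengths(entries))
  variant <- unlist(entries, use.names = FALSE)
  toks <- strsplit(variant_key(variant), "\\s+")
  ord <- order(-lengths(toks))
  structure(
    list(entries = entries,
         match_table = list(canonical = canon[ord],
                            variant = variant[ord],
                            tokens = toks[ord]),
         source = source),
    class = "supplement_lexicon")
}

#' @export
print.supplement_lexicon <- function(x, ...) {
  cat(sprintf("<supplement_lexicon> %d supplements, %d variants\n",
              length(x$entries), length(unlist(x$entries))))
  invisible(x)
}

#' Read indicator and negation lexicons
#'
#' Status indicators are single lemmas, each assigned to exactly one use
#' status class (C, D, S or U). An optional third field `weak` marks
#' attributive intake verbs ("take", "use", "try") that defer to an
#' indicator immediately before them ("stop taking", "recommend taking").
#' Negators are listed one per line and must be disjoint from indicators.
#'
#' @param path TSV file, `lemma<TAB>class[<TAB>weak]`
#' @param negator_path plain word list
#' @return an `indicator_lexicon` object
#' @export
read_indicator_lexicon <- function(path, negator_path) {
  lx <- read_lexicon_lines(path)
  if (length(lx$lines) == 0L) {
    stop(sprintf("%s: empty indicator lexicon", basename(path)), call. = FALSE)
  }
  lemma <- character(0); cls <- character(0); weak <- character(0)
  for (i in seq_along(lx$lines)) {
    parts <- strsplit(lx$lines[i], "\t", fixed = TRUE)[[1]]
    if (length(parts) < 2L) parse_error(path, lx$lineno[i], "expected lemma<TAB>class")
    w <- tolower(trimws(parts[1])); k <- trimws(parts[2])
    if (!k %in% STATUS_CLASSES) {
      parse_error(path, lx$lineno[i], sprintf("class '%s' not one of C|D|S|U", k))
    }
    if (w %in% lemma) parse_error(path, lx$lineno[i], sprintf("duplicate indicator '%s'", w))
    lemma <- c(lemma, w); cls <- c(cls, k)
    if (length(parts) >= 3L && trimws(parts[3]) == "weak") weak <- c(weak, w)
  }
  nx <- read_lexicon_lines(negator_path)
  negators <- tolower(trimws(nx$lines))
  overlap <- intersect(negators, lemma)
  if (length(overlap)) {
    stop(sprintf("negator(s) also listed as indicators: %s",
                 paste(overlap, collapse = ", ")), call. = FALSE)
  }
  structure(
    list(classes = stats::setNames(cls, lemma), weak = weak,
         negators = negators, source = path),
    class = "indicator_lexicon")
}

#' @export
print.indicator_lexicon <- function(x, ...) {
  tab <- table(factor(x$classes, levels = STATUS_CLASSES))
  cat(sprintf("<indicator_lexicon> %d indicators (C:%d D:%d S:%d U:%d), %d negators\n",
              length(x$classes), tab["C"], tab["D"], tab["S"], tab["U"],
              length(x$negators)))
  invisible(x)
}

#' Read an abbreviation expansion map
#'
#' @param path TSV file, `abbrev<TAB>expansion`; keys are matched
#'   case-insensitively as whole tokens.
#' @return an `abbreviation_map` object (named character vector)
#' @export
read_abbreviation_map <- function(path) {
  lx <- read_lexicon_lines(path)
  key <- character(0); val <- character(0)
  for (i in seq_along(lx$lines)) {
    parts <- strsplit(lx$lines[i], "\t", fixed = TRUE)[[1]]
    if (length(parts) < 2L) parse_error(path, lx$lineno[i], "expected abbrev<TAB>expansion")
    k <- tolower(trimws(parts[1])); v <- trimws(parts[2])
    if (!nzchar(k)) parse_error(path, lx$lineno[i], "empty abbreviation key")
    if (k == tolower(v)) parse_error(path, lx$lineno[i],
                                     sprintf("key '%s' equals its expansion", k))
    if (k %in% key) parse_error(path, lx$lineno[i], sprintf("duplicate key '%s'", k))
    key <- c(key, k); val <- c(val, v)
  }
  structure(stats::setNames(val, key), class = "abbreviation_map")
}

read_wordlist <- function(path) tolower(trimws(read_lexicon_lines(path)$lines))

read_lemma_dict <- function(path) {
  lx <- read_lexicon_lines(path)
  key <- character(0); val <- character(0)
  for (i in seq_along(lx$lines)) {
    parts <- strsplit(lx$lines[i], "\t", fixed = TRUE)[[1]]
    if (length(parts) < 2L) parse_error(path, lx$lineno[i], "expected form<TAB>lemma")
    key <- c(key, tolower(trimws(parts[1]))); val <- c(val, tolower(trimws(parts[2])))
  }
  stats::setNames(val, key)
}

#' Load the full lexicon bundle
#'
#' Reads the supplement, indicator, negation, abbreviation, stop-word and
#' normalizer lexicons from a directory (by default the packaged lexicons,
#' which cover the 25 study supplements and the status-indicator and
#' negation word lists). Stop words never shadow indicators or negators:
#' any overlap is dropped from the stop-word list at load time.
#'
#' @param dir directory holding `supplements.tsv`, `indicators.tsv`,
#'   `negators.txt`, `abbreviations.tsv`, `stopwords.txt`, `lemmas.tsv`
#'   and `words.txt`
#' @return a `sup_lexicons` list with elements `supplements`, `indicators`,
#'   `abbreviations`, `stopwords`, and the normalizer resources
#' @examples
#' lex <- load_lexicons()
#' length(lex$supplements$entries)  # 25
#' @export
load_lexicons <- function(dir = sup_extdata("lexicons")) {
  supplements <- read_supplement_lexicon(file.path(dir, "supplements.tsv"))
  indicators <- read_indicator_lexicon(file.path(dir, "indicators.tsv"),
                                       file.path(dir, "negators.txt"))
  abbreviations <- read_abbreviation_map(file.path(dir, "abbreviations.tsv"))
  stopwords <- read_wordlist(file.path(dir, "stopwords.txt"))
  stopwords <- setdiff(stopwords, c(names(indicators$classes), indicators$negators))
  lemma_dict <- read_lemma_dict(file.path(dir, "lemmas.tsv"))
  known <- unique(c(read_wordlist(file.path(dir, "words.txt")),
                    names(indicators$classes), indicators$negators,
                    unname(lemma_dict)))
  structure(
    list(supplements = supplements, indicators = indicators,
         abbreviations = abbreviations, stopwords = stopwords,
         lemma_dict = lemma_dict, known_lemmas = known, dir = dir),
    class = "sup_lexicons")
}

#' @export
print.sup_lexicons <- function(x, ...) {
  cat("<sup_lexicons>\n")
  print(x$supplements); print(x$indicators)
  cat(sprintf("  %d abbreviations, %d stop words\n",
              length(x$abbreviations), length(x$stopwords)))
  invisible(x)
}

## Cached default lexicons (read once per session).
the <- new.env(parent = emptyenv())
default_lexicons <- function() {
  if (is.null(the$lexicons)) the$lexicons <- load_lexicons()
  the$lexicons
}

#' Write lexicons back to files
#'
#' Inverse of the readers; reloading a written lexicon yields an
#' identical structure.
#'
#' @param lex object returned by one of the readers
#' @param path output file
#' @return `path`, invisibly
#' @rdname write_lexicons
#' @export
write_supplement_lexicon <- function(lex, path) {
  lines <- vapply(names(lex$entries), function(cn) {
    v <- setdiff(lex$entries[[cn]], cn)
    paste0(cn, "\t", paste(v, collapse = ","))
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_lexicons
#' @param negator_path output file for the negation word list
#' @export
write_indicator_lexicon <- function(lex, path, negator_path) {
  lines <- paste0(names(lex$classes), "\t", unname(lex$classes),
                  ifelse(names(lex$classes) %in% lex$weak, "\tweak", ""))
  writeLines(lines, path, useBytes = TRUE)
  writeLines(lex$negators, negator_path, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_lexicons
#' @export
write_abbreviation_map <- function(lex, path) {
  writeLines(paste0(names(lex), "\t", unname(lex)), path, useBytes = TRUE)
  invisible(path)
}

#' Locate supplement mentions in a token sequence
#'
#' Scans lowercased tokens left to right for maximal, non-overlapping
#' matches of any lexicon variant. Multi-token variants are matched as
#' contiguous token runs, longest variant first, so "fish oil" is one
#' two-token mention and never a partial match. Apostrophes and periods
#' are ignored on both sides of the comparison.
#'
#' @param tokens character vector of lowercased tokens
#' @param lex a `supplement_lexicon`
#' @return data frame with one row per mention: `canonical`, `surface`,
#'   `start`, `end` (1-based, inclusive token indices)
#' @examples
#' lex <- load_lexicons()$supplements
#' find_mentions(tokenize("Continue fish oil to reduce inflammation"), lex)
#' @export
find_mentions <- function(tokens, lex) {
  stopifnot(inherits(lex, "supplement_lexicon"))
  n <- length(tokens)
  keys <- variant_key(tokens)
  mt <- lex$match_table
  out_can <- character(0); out_sur <- character(0)
  out_s <- integer(0); out_e <- integer(0)
  i <- 1L
  while (i <= n) {
    hit <- FALSE
    for (v in seq_along(mt$tokens)) {
      vt <- mt$tokens[[v]]
      k <- length(vt)
      if (i + k - 1L <= n && identical(keys[i:(i + k - 1L)], vt)) {
        out_can <- c(out_can, mt$canonical[v])
        out_sur <- c(out_sur, paste(tokens[i:(i + k - 1L)], collapse = " "))
        out_s <- c(out_s, i); out_e <- c(out_e, i + k - 1L)
        i <- i + k
        hit <- TRUE
        break
      }
    }
    if (!hit) i <- i + 1L
  }
  data.frame(canonical = out_can, surface = out_sur,
             start = out_s, end = out_e, stringsAsFactors = FALSE)
}
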