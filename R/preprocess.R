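## Preprocessing chain: lowercasing, abbreviation expansion, tokenization,
## stop-word/punctuation/digit removal, and surrogate lexical normalization.

#' Expand clinical abbreviations in raw text
#'
#' Replaces every whole-token, case-insensitive occurrence of a map key
#' ("cont", "d/c", "d/ced", ...) with its full-word form; all other text,
#' including whitespace and attached trailing punctuation, is preserved
#' byte for byte. Expansion runs before tokenization so that keys
#' containing slashes survive intact.
#'
#' @param text character vector of raw sentences
#' @param map an `abbreviation_map` (default: packaged map)
#' @return character vector with abbreviations expanded
#' @examples
#' expand_abbreviations("pt will cont fish oil")
#' expand_abbreviations("fish oil d/c on admission")
#' @export
expand_abbreviations <- function(text, map = default_lexicons()$abbreviations) {
  stopifnot(is.character(text))
  vapply(text, function(s) {
    if (!nzchar(s)) return(s)
    m <- gregexpr("\\S+", s)[[1]]
    if (m[1] == -1L) return(s)
    pieces <- regmatches(s, gregexpr("\\S+", s))[[1]]
    out <- vapply(pieces, function(p) {
      tm <- regexpr("[.,;:!?]+$", p)
      trail <- if (tm > 0L) substring(p, tm) else ""
      core <- substr(p, 1L, nchar(p) - nchar(trail))
      key <- tolower(core)
      if (nzchar(key) && key %in% names(map)) paste0(map[[key]], trail) else p
    }, character(1), USE.NAMES = FALSE)
    regmatches(s, gregexpr("\\S+", s)) <- list(out)
    s
  }, character(1), USE.NAMES = FALSE)
}

#' Tokenize a sentence
#'
#' Lowercases, splits on whitespace, and strips leading/trailing
#' characters outside `[a-z0-9']` from each token. Internal punctuation
#' (slashes, hyphens) is preserved, so "d/c" remains one token; tokens
#' that are punctuation only (e.g. a bare en-dash) are dropped.
#'
#' @param text a single character string
#' @return character vector of raw tokens (possibly empty)
#' @examples
#' tokenize("Stop Vitamin E supplement.")
#' @export
tokenize <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  if (is.na(text) || !nzchar(trimws(text))) return(character(0))
  toks <- strsplit(tolower(trimws(text)), "\\s+")[[1]]
  toks <- sub("^[^a-z0-9']+", "", toks)
  toks <- sub("[^a-z0-9']+$", "", toks)
  toks[nzchar(toks)]
}

## ---- surrogate lexical normalizer --------------------------------------
## A dictionary lemmatizer with a conservative suffix-stripping fallback.
## It collapses inflectional variants (plural -s/-es/-ies, past -ed,
## progressive -ing) onto a base lemma; a known-lemma list drives
## restoration of a stripped final "e" ("continu" -> "continue").

lemmatize_token <- function(tok, lex) {
  dict <- lex$lemma_dict
  if (tok %in% names(dict)) return(unname(dict[[tok]]))
  known <- lex$known_lemmas
  n <- nchar(tok)
  finish <- function(stem) {
    if (stem %in% names(dict)) return(unname(dict[[stem]]))
    stem
  }
  ## -ies / -ied -> -y
  if (n > 4L && grepl("(ies|ied)$", tok)) {
    return(finish(paste0(substr(tok, 1L, n - 3L), "y")))
  }
  ## -es after sibilants
  if (n > 4L && grepl("(ses|xes|zes|ches|shes)$", tok)) {
    return(finish(substr(tok, 1L, n - 2L)))
  }
  ## -ing / -ed (e-restoration against the known-lemma list; stems
  ## shorter than 3 characters are only accepted via that list)
  for (suf in c("ing", "ed")) {
    k <- nchar(suf)
    if (n > k + 1L && substr(tok, n - k + 1L, n) == suf) {
      stem <- substr(tok, 1L, n - k)
      if (stem %in% known) return(finish(stem))
      if (paste0(stem, "e") %in% known) return(finish(paste0(stem, "e")))
      if (nchar(stem) < 3L) return(tok)
      m <- nchar(stem)
      last <- substr(stem, m, m); prev <- substr(stem, m - 1L, m - 1L)
      if (m > 2L && last == prev && !last %in% c("l", "s", "e")) {
        und <- substr(stem, 1L, m - 1L)
        return(finish(und))
      }
      return(finish(stem))
    }
  }
  ## plural -s (not -ss, -us, -is)
  if (n > 3L && grepl("[^su]s$", tok) && !grepl("is$", tok)) {
    return(finish(substr(tok, 1L, n - 1L)))
  }
  tok
}

lemmatize <- function(tokens, lex) {
  vapply(tokens, lemmatize_token, character(1), lex = lex, USE.NAMES = FALSE)
}

#' Normalize raw tokens
#'
#' Applies the standard cleanup to a lowercased raw token sequence:
#' stop words, pure-punctuation and pure-digit tokens are removed, residual
#' digits and punctuation are stripped from the survivors, and each token
#' is mapped to a canonical lexical form by the surrogate normalizer.
#' Tokens belonging to a supplement-lexicon variant ("vitamin e",
#' "coenzyme q10") are exempt from removal and normalization, so the
#' target mention always survives.
#'
#' Two cleaned layers are produced: `clean_tokens` (stop/punct/digit
#' removal only, used for raw-unigram features) and `norm_tokens`
#' (additionally lemmatized, used for rule matching and all normalized
#' feature types); both align 1:1 with each other and carry an `alignment`
#' index into the raw tokens.
#'
#' @param raw_tokens lowercased tokens from [tokenize()]
#' @param lexicons a `sup_lexicons` bundle
#' @param sentence_id optional id carried through
#' @return a `tokenized_sentence` object
#' @examples
#' lex <- load_lexicons()
#' normalize_tokens(tokenize("She has started ginkgo for memory issues"), lex)
#' @export
normalize_tokens <- function(raw_tokens, lexicons = default_lexicons(),
                             sentence_id = NA_character_) {
  stopifnot(is.character(raw_tokens))
  n <- length(raw_tokens)
  protected <- rep(FALSE, n)
  if (n > 0L) {
    men <- find_mentions(raw_tokens, lexicons$supplements)
    if (nrow(men)) {
      for (r in seq_len(nrow(men))) protected[men$start[r]:men$end[r]] <- TRUE
    }
  }
  keep <- logical(n); cleaned <- character(n)
  for (i in seq_len(n)) {
    tok <- raw_tokens[i]
    if (protected[i]) {
      cleaned[i] <- variant_key(tok)   # strip apostrophes/periods only
      keep[i] <- nzchar(cleaned[i])
    } else {
      if (tok %in% lexicons$stopwords) { keep[i] <- FALSE; next }
      if (grepl("^[0-9[:punct:]]*$", tok)) { keep[i] <- FALSE; next }
      ct <- gsub("[^a-z]", "", tok)
      cleaned[i] <- ct
      keep[i] <- nzchar(ct) && !(ct %in% lexicons$stopwords)
    }
  }
  idx <- which(keep)
  clean <- cleaned[idx]
  prot <- protected[idx]
  norm <- clean
  if (any(!prot)) norm[!prot] <- lemmatize(clean[!prot], lexicons)
  ## a lemma that collapses onto a stop word is dropped too
  drop <- !prot & (norm %in% lexicons$stopwords)
  idx <- idx[!drop]; clean <- clean[!drop]; norm <- norm[!drop]; prot <- prot[!drop]
  structure(
    list(sentence_id = sentence_id, raw_tokens = raw_tokens,
         clean_tokens = clean, norm_tokens = norm,
         alignment = idx, protected = prot),
    class = "tokenized_sentence")
}

#' @export
print.tokenized_sentence <- function(x, ...) {
  cat("<tokenized_sentence>", if (!is.na(x$sentence_id)) x$sentence_id else "", "\n")
  cat("  raw :", paste(x$raw_tokens, collapse = " "), "\n")
  cat("  norm:", paste(x$norm_tokens, collapse = " "), "\n")
  invisible(x)
}

#' Full preprocessing pipeline for one sentence
#'
#' Abbreviation expansion, tokenization and normalization in the order
#' the classifiers consume them.
#'
#' @inheritParams normalize_tokens
#' @param text raw sentence text
#' @return a `tokenized_sentence`
#' @export
preprocess_sentence <- function(text, lexicons = default_lexicons(),
                                sentence_id = NA_character_) {
  normalize_tokens(tokenize(expand_abbreviations(text, lexicons$abbreviations)),
                   lexicons, sentence_id)
}

## Map a raw-token span (start, end inclusive) onto the normalized layer.
## Returns c(start, end) in norm-token indices, or NULL if nothing survived.
norm_span <- function(ts, start, end) {
  hit <- which(ts$alignment >= start & ts$alignment <= end)
  if (!length(hit)) return(NULL)
  c(min(hit), max(hit))
}

## Locate the target supplement's mention in a tokenized sentence.
## Returns the first raw-layer mention row for `supplement`, or NULL.
locate_target <- function(ts, supplement, lexicons) {
  men <- find_mentions(ts$raw_tokens, lexicons$supplements)
  men <- men[men$canonical == supplement, , drop = FALSE]
  if (!nrow(men)) return(NULL)
  men[1L, ]
}
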