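## Corpus container and line-delimited JSON I/O.
##
## A corpus is a plain data frame with one row per annotated sentence:
## columns `id`, `text`, `supplement`, `label` (NA for unlabeled), plus
## optional provenance columns from the synthetic generator that all other
## modules ignore.

#' Construct a corpus data frame
#'
#' Validates the corpus contract: non-empty unique ids, non-empty text,
#' supplements restricted to canonical lexicon entries, labels (when
#' present) within the four status classes.
#'
#' @param id,text,supplement character vectors of equal length
#' @param label optional character vector of class labels (C/D/S/U or NA)
#' @param lexicons lexicon bundle used to validate supplement names
#' @param ... additional provenance columns (recycled by `data.frame`)
#' @return a `data.frame` of class `sup_corpus`
#' @export
sup_corpus <- function(id, text, supplement, label = NA_character_,
                       lexicons = default_lexicons(), ...) {
  stopifnot(length(id) == length(text), length(text) == length(supplement))
  if (anyDuplicated(id)) stop("sentence ids must be unique", call. = FALSE)
  if (any(!nzchar(text))) stop("sentence text must be non-empty", call. = FALSE)
  bad <- setdiff(unique(supplement), names(lexicons$supplements$entries))
  if (length(bad)) {
    stop(sprintf("supplement(s) not in lexicon: %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  }
  lab <- as.character(label)
  ok <- is.na(lab) | lab %in% STATUS_CLASSES
  if (!all(ok)) stop("labels must be C, D, S, U or NA", call. = FALSE)
  out <- data.frame(id = as.character(id), text = as.character(text),
                    supplement = as.character(supplement),
                    label = lab, ..., stringsAsFactors = FALSE)
  class(out) <- c("sup_corpus", "data.frame")
  out
}

#' Read / write a corpus as line-delimited JSON
#'
#' One JSON object per line with fields `id`, `text`, `supplement` and
#' optionally `label` plus provenance fields; the pair round-trips
#' exactly.
#'
#' @param path file path
#' @param lexicons lexicon bundle for validation on read
#' @return `read_corpus`: a `sup_corpus`; `write_corpus`: `path` invisibly
#' @rdname corpus_io
#' @export
read_corpus <- function(path, lexicons = default_lexicons()) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop(sprintf("%s: empty corpus", basename(path)), call. = FALSE)
  recs <- lapply(seq_along(lines), function(i) {
    rec <- tryCatch(jsonlite::fromJSON(lines[i]),
                    error = function(e) stop(sprintf("%s, line %d: %s",
                                                     basename(path), i,
                                                     conditionMessage(e)),
                                             call. = FALSE))
    if (is.null(rec$id) || is.null(rec$text) || is.null(rec$supplement)) {
      stop(sprintf("%s, line %d: record needs id, text, supplement",
                   basename(path), i), call. = FALSE)
    }
    rec
  })
  fields <- unique(unlist(lapply(recs, names)))
  cols <- lapply(fields, function(f) {
    vapply(recs, function(r) {
      v <- r[[f]]
      if (is.null(v)) NA_character_ else as.character(v)
    }, character(1))
  })
  names(cols) <- fields
  extra <- setdiff(fields, c("id", "text", "supplement", "label"))
  do.call(sup_corpus, c(list(id = cols$id, text = cols$text,
                             supplement = cols$supplement,
                             label = cols$label %||% NA_character_,
                             lexicons = lexicons),
                        cols[extra]))
}

#' @rdname corpus_io
#' @param corpus a `sup_corpus` data frame
#' @export
write_corpus <- function(corpus, path) {
  lines <- vapply(seq_len(nrow(corpus)), function(i) {
    rec <- as.list(corpus[i, , drop = FALSE])
    rec <- rec[!vapply(rec, function(v) is.na(v), logical(1))]
    as.character(jsonlite::toJSON(rec, auto_unbox = TRUE))
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Preprocess a whole corpus
#'
#' Runs the preprocessing pipeline over every sentence and locates each
#' sentence's target supplement mention; the result feeds both the rule
#' engine and the feature extractors so the (comparatively expensive)
#' tokenization is done once.
#'
#' @param corpus a `sup_corpus`
#' @param lexicons lexicon bundle
#' @return a `prepared_corpus`: list with the corpus and, per sentence,
#'   its `tokenized_sentence` and target mention (or NULL when the
#'   supplement does not surface in the text)
#' @export
prepare_corpus <- function(corpus, lexicons = default_lexicons()) {
  sents <- lapply(seq_len(nrow(corpus)), function(i) {
    ts <- preprocess_sentence(corpus$text[i], lexicons, corpus$id[i])
    list(ts = ts, mention = locate_target(ts, corpus$supplement[i], lexicons))
  })
  structure(list(corpus = corpus, sentences = sents, lexicon_dir = lexicons$dir),
            class = "prepared_corpus")
}

#' @export
print.prepared_corpus <- function(x, ...) {
  cat(sprintf("<prepared_corpus> %d sentences (%d with located target mention)\n",
              nrow(x$corpus),
              sum(!vapply(x$sentences, function(s) is.null(s$mention), logical(1)))))
  invisible(x)
}
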