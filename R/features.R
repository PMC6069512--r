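## The nine feature-set types: bag-of-words n-grams over the raw or
## normalized token layer, TF-IDF weighting, and window-limited binary
## indicator features around the target mention.

#' Feature-set specification
#'
#' The nine standard configurations:
#' \tabular{ll}{
#'   1 \tab raw unigrams (cleaned but unlemmatized tokens) \cr
#'   2 \tab unigrams (normalized) \cr
#'   3 \tab TF-IDF weighted normalized unigrams \cr
#'   4 \tab bigrams \cr
#'   5 \tab unigrams + bigrams \cr
#'   6 \tab unigrams + bigrams + trigrams \cr
#'   7 \tab indicator features only (no distance cut-off) \cr
#'   8 \tab unigrams + bigrams + indicator features with window \cr
#'   9 \tab unigrams + bigrams + trigrams + indicator features with window
#' }
#'
#' @param type_id integer 1-9
#' @param indicator_window token window for indicator features of types 8
#'   and 9 (default 6); type 7 always uses the whole sentence
#' @param distance_buckets if TRUE, indicator features additionally encode
#'   a bucketed indicator-mention distance instead of bare presence
#' @return a `feature_spec` object
#' @export
feature_spec <- function(type_id, indicator_window = 6L,
                         distance_buckets = FALSE) {
  stopifnot(length(type_id) == 1L, type_id %in% 1:9, indicator_window >= 0)
  ngrams <- switch(type_id, `1` = 1L, `2` = 1L, `3` = 1L, `4` = 2L,
                   `5` = c(1L, 2L), `6` = 1:3, `7` = integer(0),
                   `8` = c(1L, 2L), `9` = 1:3)
  structure(
    list(type_id = as.integer(type_id),
         use_normalized = type_id != 1L,
         ngram_orders = ngrams,
         tfidf = type_id == 3L,
         indicator_features = type_id %in% c(7L, 8L, 9L),
         indicator_window = if (type_id == 7L) Inf else as.integer(indicator_window),
         distance_buckets = isTRUE(distance_buckets)),
    class = "feature_spec")
}

#' @export
print.feature_spec <- function(x, ...) {
  cat(sprintf("<feature_spec> type %d: layer=%s ngrams={%s}%s%s\n",
              x$type_id, if (x$use_normalized) "normalized" else "raw",
              paste(x$ngram_orders, collapse = ","),
              if (x$tfidf) " tf-idf" else "",
              if (x$indicator_features)
                sprintf(" indicators(window=%s)", format(x$indicator_window))
              else ""))
  invisible(x)
}

#' Extract n-gram counts from one sentence
#'
#' Contiguous n-grams over the selected token layer (raw-cleaned for type
#' 1, normalized otherwise), joined with underscores.
#'
#' @param ts a `tokenized_sentence`
#' @param spec a [feature_spec()] with non-empty `ngram_orders`
#' @return named integer vector of n-gram counts (possibly empty)
#' @examples
#' lex <- load_lexicons()
#' extract_ngrams(normalize_tokens(c("stop", "vitamin", "e"), lex),
#'                feature_spec(4))
#' @export
extract_ngrams <- function(ts, spec) {
  stopifnot(inherits(spec, "feature_spec"), length(spec$ngram_orders) > 0)
  toks <- if (spec$use_normalized) ts$norm_tokens else ts$clean_tokens
  out <- character(0)
  for (k in spec$ngram_orders) {
    n <- length(toks)
    if (n < k) next
    if (k == 1L) out <- c(out, toks)
    else {
      idx <- seq_len(n - k + 1L)
      grams <- toks[idx]
      for (j in seq_len(k - 1L)) grams <- paste(grams, toks[idx + j], sep = "_")
      out <- c(out, grams)
    }
  }
  if (!length(out)) return(stats::setNames(integer(0), character(0)))
  tab <- table(out)
  stats::setNames(as.integer(tab), names(tab))
}

#' Extract indicator features around the target mention
#'
#' One binary feature per indicator lemma occurring within
#' `spec$indicator_window` tokens of the mention (either side, normalized
#' layer). With `distance_buckets = TRUE` the feature name also encodes
#' the bucketed distance of the nearest occurrence (buckets 0, 1, 2, 3,
#' 4-6, 7+), covering the reading where the distance value itself is a
#' feature.
#'
#' @inheritParams extract_ngrams
#' @param mention one row from [find_mentions()] on the raw tokens
#' @param lex an `indicator_lexicon`
#' @return character vector of feature names present (binary features)
#' @export
extract_indicator_features <- function(ts, mention, lex, spec) {
  stopifnot(inherits(spec, "feature_spec"), spec$indicator_features)
  if (is.null(mention)) stop("mention is NULL", call. = FALSE)
  occ <- mention_matches(ts, mention, lex, rule_config())
  occ <- occ[occ$distance <= spec$indicator_window, , drop = FALSE]
  if (!nrow(occ)) return(character(0))
  if (!spec$distance_buckets) return(unique(paste0("IND_", occ$indicator)))
  nearest <- stats::aggregate(distance ~ indicator, data = occ, FUN = min)
  bucket <- cut(nearest$distance, breaks = c(-0.5, 0.5, 1.5, 2.5, 3.5, 6.5, Inf),
                labels = c("0", "1", "2", "3", "4-6", "7+"))
  unique(paste0("IND_", nearest$indicator, "_d", as.character(bucket)))
}

## Feature multiset for one prepared sentence under a spec.
sentence_features <- function(s, spec, lex) {
  feats <- integer(0)
  if (length(spec$ngram_orders)) feats <- extract_ngrams(s$ts, spec)
  if (spec$indicator_features && !is.null(s$mention)) {
    ind <- extract_indicator_features(s$ts, s$mention, lex, spec)
    if (length(ind)) {
      feats <- c(feats, stats::setNames(rep(1L, length(ind)), ind))
    }
  }
  feats
}

## Per-sentence feature multisets for a whole prepared corpus; computed
## once and shareable between fit_vectorizer and transform_features.
corpus_features <- function(prep, spec, lexicons) {
  lapply(prep$sentences, sentence_features, spec = spec,
         lex = lexicons$indicators)
}

#' Fit a vectorizer on a training corpus
#'
#' Fixes the vocabulary (sorted lexicographically, so the result is
#' independent of corpus ordering) and, for TF-IDF specs, the document
#' frequencies and corpus size from the training corpus only. Features
#' unseen in training are ignored at transform time.
#'
#' @param prep a [prepare_corpus()] result for the training split
#' @param spec a [feature_spec()]
#' @param lexicons lexicon bundle (indicator features)
#' @param featsets optional precomputed per-sentence feature multisets
#'   (internal use, to share work with the transform)
#' @return a `sup_vectorizer`
#' @export
fit_vectorizer <- function(prep, spec, lexicons = default_lexicons(),
                           featsets = NULL) {
  stopifnot(inherits(prep, "prepared_corpus"))
  if (!nrow(prep$corpus)) stop("empty training corpus", call. = FALSE)
  featsets <- featsets %||% corpus_features(prep, spec, lexicons)
  vocab <- sort(unique(unlist(lapply(featsets, names))))
  df <- NULL
  if (spec$tfidf) {
    df_tab <- table(unlist(lapply(featsets, function(f) unique(names(f)))))
    df <- stats::setNames(as.integer(df_tab[vocab]), vocab)
    df[is.na(df)] <- 0L
  }
  structure(list(spec = spec, vocabulary = vocab, df = df,
                 n_docs = nrow(prep$corpus)),
            class = "sup_vectorizer")
}

#' @export
print.sup_vectorizer <- function(x, ...) {
  cat(sprintf("<sup_vectorizer> type %d, %d features, fitted on %d documents%s\n",
              x$spec$type_id, length(x$vocabulary), x$n_docs,
              if (x$spec$tfidf) " (tf-idf)" else ""))
  invisible(x)
}

#' Transform a corpus into a feature matrix
#'
#' Counts (or TF-IDF weights) per training-vocabulary feature; rows are
#' sentences, in corpus order, with sentence ids as row names.
#' TF-IDF uses the smoothed formula
#' `tf * (ln((1 + N) / (1 + df)) + 1)` with L2 row normalization, so
#' ubiquitous terms keep a floor weight and unseen divisions cannot occur.
#'
#' @param vectorizer a fitted `sup_vectorizer`
#' @param prep a [prepare_corpus()] result
#' @param lexicons lexicon bundle
#' @param featsets optional precomputed per-sentence feature multisets
#' @return a sparse `dgCMatrix` (sentences x features)
#' @export
transform_features <- function(vectorizer, prep, lexicons = default_lexicons(),
                               featsets = NULL) {
  stopifnot(inherits(vectorizer, "sup_vectorizer"))
  spec <- vectorizer$spec
  vocab <- vectorizer$vocabulary
  featsets <- featsets %||% corpus_features(prep, spec, lexicons)
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  for (r in seq_along(prep$sentences)) {
    feats <- featsets[[r]]
    if (!length(feats)) next
    j <- match(names(feats), vocab)
    keep <- !is.na(j)
    if (!any(keep)) next
    ii <- c(ii, rep.int(r, sum(keep)))
    jj <- c(jj, j[keep])
    xx <- c(xx, as.numeric(feats[keep]))
  }
  m <- Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                            dims = c(length(prep$sentences), length(vocab)),
                            dimnames = list(prep$corpus$id, vocab))
  if (spec$tfidf) {
    idf <- log((1 + vectorizer$n_docs) / (1 + vectorizer$df)) + 1
    m <- m %*% Matrix::Diagonal(x = idf)
    rn <- sqrt(Matrix::rowSums(m^2))
    rn[rn == 0] <- 1
    m <- Matrix::Diagonal(x = 1 / rn) %*% m
    dimnames(m) <- list(prep$corpus$id, vocab)
  }
  methods::as(m, "CsparseMatrix")
}

#' Export a feature matrix as plain text
#'
#' Writes sparse coordinate triplets (`row<TAB>col<TAB>value`, 1-based)
#' and a companion vocabulary file, one feature name per line.
#'
#' @param m matrix from [transform_features()]
#' @param prefix output path prefix; writes `<prefix>.coo` and
#'   `<prefix>.vocab`
#' @return the two paths, invisibly
#' @export
write_feature_matrix <- function(m, prefix) {
  tm <- methods::as(m, "TsparseMatrix")
  coo <- sprintf("%d\t%d\t%.10g", tm@i + 1L, tm@j + 1L, tm@x)
  writeLines(coo, paste0(prefix, ".coo"), useBytes = TRUE)
  writeLines(colnames(m), paste0(prefix, ".vocab"), useBytes = TRUE)
  invisible(c(paste0(prefix, ".coo"), paste0(prefix, ".vocab")))
}
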