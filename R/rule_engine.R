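## Rule-based classifier: bidirectional window-limited indicator matching
## around the target supplement mention, with negation handling, a
## weak-indicator governing rule, distance-based resolution, and the
## window-size sweep.

#' Rule engine configuration
#'
#' @param window maximum number of tokens allowed between an indicator and
#'   the mention for a rule to fire (default 7)
#' @param sweep_range inclusive window range explored by [sweep_window()]
#' @param negation_window maximum tokens between a negator and the
#'   indicator it negates (negator before indicator; default 2)
#' @param govern_window maximum tokens between a governing indicator and a
#'   weak intake verb after it ("stop taking", "recommend taking";
#'   default 2)
#' @return a `rule_config` object
#' @export
rule_config <- function(window = 7L, sweep_range = 0:11,
                        negation_window = 2L, govern_window = 2L) {
  stopifnot(window >= 0, all(sweep_range >= 0), all(sweep_range <= 20),
            negation_window >= 0, govern_window >= 0)
  structure(list(window = as.integer(window),
                 sweep_range = as.integer(sweep_range),
                 negation_window = as.integer(negation_window),
                 govern_window = as.integer(govern_window)),
            class = "rule_config")
}

## Scan the normalized layer for indicator occurrences and resolve each
## occurrence's *effective* class:
##   - a negator within negation_window tokens before an indicator negates
##     it: negated D -> C ("never stopped" = still taking), negated C/S -> U;
##   - a weak intake verb (take/use/try) within govern_window tokens after
##     another indicator adopts that indicator's effective class
##     ("recommend taking" -> U, "stop taking" -> D).
## Returns a data frame over all occurrences, position included.
indicator_occurrences <- function(norm_tokens, protected, lex, cfg) {
  cls_map <- lex$classes
  is_ind <- (norm_tokens %in% names(cls_map)) & !protected
  pos <- which(is_ind)
  if (!length(pos)) {
    return(data.frame(pos = integer(0), indicator = character(0),
                      indicator_class = character(0),
                      effective_class = character(0),
                      negated = logical(0), stringsAsFactors = FALSE))
  }
  neg_pos <- which(norm_tokens %in% lex$negators & !protected)
  lemma <- norm_tokens[pos]
  base_cls <- unname(cls_map[lemma])
  negated <- vapply(pos, function(i) {
    any(neg_pos < i & (i - neg_pos - 1L) <= cfg$negation_window)
  }, logical(1))
  eff <- base_cls
  eff[negated & base_cls == "D"] <- "C"
  eff[negated & base_cls %in% c("C", "S")] <- "U"
  ## governing pass, left to right so chains resolve on settled classes;
  ## a governor overrides the weak verb's own negation flag, because in
  ## "never stopped taking" the negator attaches to the governor
  weak <- lemma %in% lex$weak
  for (k in seq_along(pos)) {
    if (!weak[k]) next
    gov <- which(pos < pos[k] & (pos[k] - pos - 1L) <= cfg$govern_window)
    if (length(gov)) eff[k] <- eff[max(gov)]
  }
  data.frame(pos = pos, indicator = lemma, indicator_class = base_cls,
             effective_class = eff, negated = negated, stringsAsFactors = FALSE)
}

## All indicator occurrences with their distance/direction relative to a
## mention span on the normalized layer (no window cut).
mention_matches <- function(ts, mention, lex, cfg) {
  if (is.null(mention)) stop("mention is NULL", call. = FALSE)
  n_raw <- length(ts$raw_tokens)
  if (mention$start < 1L || mention$end > n_raw || mention$start > mention$end) {
    stop("mention span outside sentence", call. = FALSE)
  }
  sp <- norm_span(ts, mention$start, mention$end)
  if (is.null(sp)) stop("mention did not survive normalization", call. = FALSE)
  occ <- indicator_occurrences(ts$norm_tokens, ts$protected, lex, cfg)
  if (!nrow(occ)) {
    occ$distance <- integer(0); occ$direction <- character(0)
    return(occ)
  }
  occ$distance <- ifelse(occ$pos < sp[1], sp[1] - occ$pos - 1L,
                         occ$pos - sp[2] - 1L)
  occ$direction <- ifelse(occ$pos < sp[1], "before", "after")
  occ <- occ[occ$distance >= 0L, , drop = FALSE]   # inside-span cannot occur
  occ[order(occ$distance, occ$direction != "before"), , drop = FALSE]
}

#' Match status-indicator rules around a mention
#'
#' Finds every indicator occurrence whose token distance to the target
#' mention is at most `cfg$window`, on either side, on the normalized
#' token layer. Distance counts the tokens strictly between indicator and
#' mention. Matches are sorted by (distance, before-first).
#'
#' @param ts a `tokenized_sentence`
#' @param mention one row from [find_mentions()] on the raw tokens
#' @param lex an `indicator_lexicon`
#' @param cfg a [rule_config()]
#' @return data frame with columns `indicator`, `indicator_class`,
#'   `effective_class`, `distance`, `direction`, `negated`
#' @examples
#' lexs <- load_lexicons()
#' ts <- preprocess_sentence("continue fish oil to reduce inflammation", lexs)
#' m <- find_mentions(ts$raw_tokens, lexs$supplements)[1, ]
#' match_rules(ts, m, lexs$indicators, rule_config())
#' @export
match_rules <- function(ts, mention, lex, cfg = rule_config()) {
  occ <- mention_matches(ts, mention, lex, cfg)
  occ <- occ[occ$distance <= cfg$window, , drop = FALSE]
  rownames(occ) <- NULL
  occ[, c("indicator", "indicator_class", "effective_class",
          "distance", "direction", "negated")]
}

## Resolution policy over a (window-filtered) match set:
## smallest distance, then indicator-before-mention, then the class
## precedence U > D > S > C; default class U when nothing fires.
resolve_matches <- function(matches) {
  if (!nrow(matches)) return("U")
  prec <- match(matches$effective_class, c("U", "D", "S", "C"))
  ord <- order(matches$distance, matches$direction != "before", prec)
  matches$effective_class[ord[1L]]
}

#' Classify one sentence with the rule engine
#'
#' Applies [match_rules()] and resolves multiple hits by smallest
#' distance, then indicator-before-mention, then the fixed class
#' precedence U > D > S > C; a sentence with no match defaults to
#' Unclassified.
#'
#' @inheritParams match_rules
#' @return a single class label in `{C, D, S, U}`
#' @export
classify_sentence <- function(ts, mention, lex, cfg = rule_config()) {
  resolve_matches(match_rules(ts, mention, lex, cfg))
}

#' Rule-classify a whole corpus
#'
#' @param prep a [prepare_corpus()] result (or a `sup_corpus`, which is
#'   prepared on the fly)
#' @param lexicons lexicon bundle
#' @param cfg a [rule_config()]
#' @param diagnostics if TRUE, attach per-sentence match tables (both
#'   window-limited and unbounded) used by [categorize_errors()]
#' @return character vector of predicted classes, named by sentence id;
#'   with `diagnostics = TRUE`, a list with `predicted` and `diagnostics`
#' @export
classify_corpus <- function(prep, lexicons = default_lexicons(),
                            cfg = rule_config(), diagnostics = FALSE) {
  if (inherits(prep, "sup_corpus")) prep <- prepare_corpus(prep, lexicons)
  lex <- lexicons$indicators
  n <- nrow(prep$corpus)
  pred <- character(n)
  diag <- if (diagnostics) vector("list", n)
  for (i in seq_len(n)) {
    s <- prep$sentences[[i]]
    if (is.null(s$mention)) {
      ## target never surfaces: nothing to anchor a window on
      pred[i] <- "U"
      if (diagnostics) {
        diag[[i]] <- list(all = NULL, windowed = NULL, no_mention = TRUE)
      }
      next
    }
    all_m <- mention_matches(s$ts, s$mention, lex, cfg)
    win_m <- all_m[all_m$distance <= cfg$window, , drop = FALSE]
    pred[i] <- resolve_matches(win_m)
    if (diagnostics) {
      diag[[i]] <- list(all = all_m, windowed = win_m, no_mention = FALSE)
    }
  }
  names(pred) <- prep$corpus$id
  if (diagnostics) {
    names(diag) <- prep$corpus$id
    list(predicted = pred, diagnostics = diag)
  } else pred
}

#' Window-size sweep
#'
#' Re-runs the rule classifier at every window size in `cfg$sweep_range`
#' over a labeled corpus and reports the support-weighted F-measure per
#' window. Matches are computed once at the maximum window and filtered,
#' so the sweep costs little more than a single run.
#'
#' @inheritParams classify_corpus
#' @return data frame with columns `window` and `weighted_f`
#' @export
sweep_window <- function(prep, lexicons = default_lexicons(),
                         cfg = rule_config()) {
  if (inherits(prep, "sup_corpus")) prep <- prepare_corpus(prep, lexicons)
  if (!nrow(prep$corpus)) stop("empty corpus", call. = FALSE)
  if (any(is.na(prep$corpus$label))) {
    stop("sweep_window requires a fully labeled corpus", call. = FALSE)
  }
  lex <- lexicons$indicators
  all_matches <- lapply(prep$sentences, function(s) {
    if (is.null(s$mention)) NULL else mention_matches(s$ts, s$mention, lex, cfg)
  })
  gold <- prep$corpus$label
  wf <- vapply(cfg$sweep_range, function(w) {
    pred <- vapply(all_matches, function(m) {
      if (is.null(m)) "U"
      else resolve_matches(m[m$distance <= w, , drop = FALSE])
    }, character(1))
    score(gold, pred)$weighted["f_measure"]
  }, numeric(1))
  data.frame(window = cfg$sweep_range, weighted_f = unname(wf))
}
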