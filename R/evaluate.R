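## Evaluation: per-class and weighted precision/recall/F, per-supplement
## breakdown, inter-annotator agreement, pairwise classifier comparison,
## and automated error categorization for the rule engine.

#' Score predictions against gold labels
#'
#' Computes the 4x4 confusion matrix (gold rows x predicted columns),
#' per-class precision/recall/F and the support-weighted totals
#' (weighted metric = sum over classes of support_c * metric_c / N).
#' F is the harmonic mean 2PR/(P+R), defined as 0 when P + R = 0.
#'
#' @param gold,predicted equal-length vectors of labels in `{C, D, S, U}`
#' @return an `evaluation_report`: list with `confusion`, `per_class`
#'   (data frame: class, support, precision, recall, f_measure),
#'   `weighted` (named numeric) and `n`
#' @examples
#' score(c("C", "D", "S"), c("C", "D", "U"))
#' @export
score <- function(gold, predicted) {
  if (length(gold) != length(predicted)) {
    stop("gold and predicted must have equal length", call. = FALSE)
  }
  g <- as_status(gold, "gold"); p <- as_status(predicted, "predicted")
  if (anyNA(g) || anyNA(p)) stop("labels must not be NA", call. = FALSE)
  conf <- table(gold = g, predicted = p)
  support <- rowSums(conf)
  tp <- diag(conf)
  prec <- ifelse(colSums(conf) > 0, tp / colSums(conf), 0)
  rec <- ifelse(support > 0, tp / support, 0)
  f <- ifelse(prec + rec > 0, 2 * prec * rec / (prec + rec), 0)
  per_class <- data.frame(class = STATUS_CLASSES, support = as.integer(support),
                          precision = as.numeric(prec), recall = as.numeric(rec),
                          f_measure = as.numeric(f), stringsAsFactors = FALSE)
  structure(
    list(confusion = unclass(conf), per_class = per_class,
         weighted = weighted_metrics(per_class), n = length(g)),
    class = "evaluation_report")
}

#' Support-weighted totals from per-class metrics
#'
#' The "Total (weighted)" row: each per-class metric averaged with the
#' class supports as weights.
#'
#' @param per_class data frame with columns `support`, `precision`,
#'   `recall`, `f_measure` (one row per class)
#' @return named numeric vector `precision`, `recall`, `f_measure`
#' @export
weighted_metrics <- function(per_class) {
  w <- per_class$support / sum(per_class$support)
  c(precision = sum(w * per_class$precision),
    recall = sum(w * per_class$recall),
    f_measure = sum(w * per_class$f_measure))
}

#' @export
print.evaluation_report <- function(x, digits = 2, ...) {
  cat(sprintf("<evaluation_report> n = %d\n", x$n))
  tab <- x$per_class
  tab[, 3:5] <- lapply(tab[, 3:5], round_half_up, digits = digits)
  print(tab, row.names = FALSE)
  w <- round_half_up(x$weighted, digits)
  cat(sprintf("Total (weighted): P %.*f  R %.*f  F %.*f\n",
              digits, w["precision"], digits, w["recall"], digits, w["f_measure"]))
  invisible(x)
}

#' Per-supplement evaluation breakdown
#'
#' Scores each supplement's sentences separately, mirroring the
#' supplement-level generalizability table.
#'
#' @param corpus a labeled `sup_corpus`
#' @param predicted predictions aligned with `corpus` rows
#' @return list with `reports` (named list of `evaluation_report`) and
#'   `summary` (data frame: supplement, n, precision, recall, f_measure —
#'   weighted metrics per supplement)
#' @export
score_by_supplement <- function(corpus, predicted) {
  if (is.null(corpus$supplement)) stop("corpus lacks a supplement field", call. = FALSE)
  if (nrow(corpus) != length(predicted)) {
    stop("predicted must align with corpus rows", call. = FALSE)
  }
  sups <- sort(unique(corpus$supplement))
  reports <- lapply(sups, function(s) {
    i <- corpus$supplement == s
    score(corpus$label[i], predicted[i])
  })
  names(reports) <- sups
  summary <- data.frame(
    supplement = sups,
    n = vapply(reports, function(r) r$n, integer(1)),
    precision = vapply(reports, function(r) r$weighted["precision"], numeric(1)),
    recall = vapply(reports, function(r) r$weighted["recall"], numeric(1)),
    f_measure = vapply(reports, function(r) r$weighted["f_measure"], numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE)
  list(reports = reports, summary = summary)
}

#' Inter-annotator agreement (Cohen's kappa)
#'
#' Observed agreement p_o, chance agreement p_e from the product of the
#' two raters' label marginals, and kappa = (p_o - p_e) / (1 - p_e);
#' kappa is 1 when the raters agree everywhere (p_e = 1 included, by
#' convention).
#'
#' @param rater1,rater2 equal-length label vectors
#' @return an `agreement_result`: list with `p_o`, `p_e`, `kappa`,
#'   `percent_agreement` and `n`
#' @examples
#' agreement(rep(c("C", "D"), c(50, 50)),
#'           rep(c("C", "D", "C", "D"), c(45, 5, 5, 45)))
#' @export
agreement <- function(rater1, rater2) {
  if (length(rater1) != length(rater2)) {
    stop("rater vectors must have equal length", call. = FALSE)
  }
  n <- length(rater1)
  if (n < 1L) stop("need at least one rated item", call. = FALSE)
  r1 <- as_status(rater1, "rater1"); r2 <- as_status(rater2, "rater2")
  p_o <- mean(r1 == r2)
  p_e <- sum((table(r1) / n) * (table(r2) / n))
  kappa <- if (p_e >= 1) 1 else (p_o - p_e) / (1 - p_e)
  structure(list(p_o = p_o, p_e = p_e, kappa = kappa,
                 percent_agreement = 100 * p_o, n = n),
            class = "agreement_result")
}

#' @export
print.agreement_result <- function(x, ...) {
  cat(sprintf("<agreement_result> n = %d: kappa %.3f (p_o %.3f, p_e %.3f), %.1f%% agreement\n",
              x$n, x$kappa, x$p_o, x$p_e, x$percent_agreement))
  invisible(x)
}

#' Pairwise classifier comparison
#'
#' For each gold class, counts the sentences both classifiers got right,
#' only A got right, only B got right, and both got wrong; per-classifier
#' true positives follow as TP_A = both + A-only (and likewise for B).
#'
#' @param gold gold labels
#' @param pred_a,pred_b predictions from the two classifiers
#' @return a `comparison_result` data frame with one row per class:
#'   `class`, `support`, `both_correct`, `a_only`, `b_only`,
#'   `both_wrong`, `tp_a`, `tp_b`
#' @export
compare_classifiers <- function(gold, pred_a, pred_b) {
  if (length(gold) != length(pred_a) || length(gold) != length(pred_b)) {
    stop("gold, pred_a and pred_b must have equal length", call. = FALSE)
  }
  g <- as_status(gold, "gold")
  a_ok <- as_status(pred_a, "pred_a") == g
  b_ok <- as_status(pred_b, "pred_b") == g
  rows <- lapply(STATUS_CLASSES, function(cl) {
    i <- g == cl
    data.frame(class = cl, support = sum(i),
               both_correct = sum(a_ok[i] & b_ok[i]),
               a_only = sum(a_ok[i] & !b_ok[i]),
               b_only = sum(!a_ok[i] & b_ok[i]),
               both_wrong = sum(!a_ok[i] & !b_ok[i]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$tp_a <- out$both_correct + out$a_only
  out$tp_b <- out$both_correct + out$b_only
  stopifnot(all(out$both_correct + out$a_only + out$b_only + out$both_wrong
                == out$support))
  class(out) <- c("comparison_result", "data.frame")
  out
}

#' Categorize rule-engine errors
#'
#' Deterministic re-implementation of the manual error review, applied to
#' every misclassified sentence, in this order:
#' \enumerate{
#'   \item no indicator anywhere in the sentence and gold is not U:
#'     \emph{missing-pattern} (the rule inventory lacks the construction);
#'   \item two or more indicators of different effective classes matched
#'     within the window: \emph{indicator-issue};
#'   \item an indicator of the gold class exists but only beyond the
#'     window: \emph{distance-issue};
#'   \item anything else: \emph{missing-pattern}.
#' }
#'
#' @param corpus the (labeled) evaluated corpus
#' @param predicted rule-engine predictions aligned with `corpus`
#' @param diagnostics per-sentence diagnostics from
#'   `classify_corpus(..., diagnostics = TRUE)`
#' @param cfg the [rule_config()] used for classification
#' @param denominator size used for the percentage column of the summary
#'   (defaults to the corpus size)
#' @return list with `errors` (data frame: id, gold, predicted, category,
#'   note) and `summary` (data frame: category, n, percent — percent of
#'   `denominator`, half-up rounded to one decimal)
#' @export
categorize_errors <- function(corpus, predicted, diagnostics,
                              cfg = rule_config(),
                              denominator = nrow(corpus)) {
  stopifnot(nrow(corpus) == length(predicted))
  mis <- which(!is.na(corpus$label) & corpus$label != predicted)
  rows <- lapply(mis, function(i) {
    d <- diagnostics[[corpus$id[i]]]
    if (is.null(d)) stop(sprintf("no diagnostics for sentence %s", corpus$id[i]),
                         call. = FALSE)
    gold <- corpus$label[i]
    has_any <- !is.null(d$all) && nrow(d$all) > 0
    win <- d$windowed
    cat_ <- if (!has_any && gold != "U") {
      "missing-pattern"
    } else if (!is.null(win) && nrow(win) >= 2 &&
               length(unique(win$effective_class)) >= 2) {
      "indicator-issue"
    } else if (has_any &&
               any(d$all$effective_class == gold & d$all$distance > cfg$window) &&
               !(gold %in% (win$effective_class %||% character(0)))) {
      "distance-issue"
    } else {
      "missing-pattern"
    }
    note <- switch(cat_,
      "missing-pattern" = "no rule captured the gold-class construction",
      "indicator-issue" = sprintf("competing indicators in window: %s",
                                  paste(unique(win$indicator), collapse = ", ")),
      "distance-issue" = sprintf("gold-class indicator beyond window %d",
                                 cfg$window))
    data.frame(id = corpus$id[i], gold = gold, predicted = predicted[i],
               category = cat_, note = note, stringsAsFactors = FALSE)
  })
  errors <- if (length(rows)) do.call(rbind, rows)
    else data.frame(id = character(0), gold = character(0),
                    predicted = character(0), category = character(0),
                    note = character(0), stringsAsFactors = FALSE)
  cats <- c("missing-pattern", "indicator-issue", "distance-issue")
  n_cat <- vapply(cats, function(cc) sum(errors$category == cc), integer(1))
  summary <- data.frame(
    category = c(cats, "total"),
    n = c(n_cat, nrow(errors)),
    percent = round_half_up(100 * c(n_cat, nrow(errors)) / denominator, 1),
    row.names = NULL, stringsAsFactors = FALSE)
  list(errors = errors, summary = summary)
}
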