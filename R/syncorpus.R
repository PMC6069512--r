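## Seeded synthetic-corpus generator emulating the annotated study corpus
## (class mix, indicator placement, abbreviations, misspellings, negations,
## distractors), plus the per-supplement 70/30 splitter. Sentences are
## assembled from a template bank so that each sentence's stored label is
## recoverable by the rule engine at unbounded window: the construction is
## rule-consistent by design, which is what makes end-to-end pipeline
## tests meaningful.

## Inflection table for the indicator lemmas the templates draw on.
IND_FORMS <- list(
  continue = c(base = "continue", past = "continued", gerund = "continuing", third = "continues"),
  increase = c(base = "increase", past = "increased", gerund = "increasing", third = "increases"),
  take = c(base = "take", past = "took", gerund = "taking", third = "takes"),
  use = c(base = "use", past = "used", gerund = "using", third = "uses"),
  remain = c(base = "remain", past = "remained", gerund = "remaining", third = "remains"),
  start = c(base = "start", past = "started", gerund = "starting", third = "starts"),
  restart = c(base = "restart", past = "restarted", gerund = "restarting", third = "restarts"),
  begin = c(base = "begin", past = "began", gerund = "beginning", third = "begins"),
  initiate = c(base = "initiate", past = "initiated", gerund = "initiating", third = "initiates"),
  add = c(base = "add", past = "added", gerund = "adding", third = "adds"),
  resume = c(base = "resume", past = "resumed", gerund = "resuming", third = "resumes"),
  stop = c(base = "stop", past = "stopped", gerund = "stopping", third = "stops"),
  discontinue = c(base = "discontinue", past = "discontinued", gerund = "discontinuing", third = "discontinues"),
  hold = c(base = "hold", past = "held", gerund = "holding", third = "holds"),
  off = c(base = "off", past = "off", gerund = "off", third = "off"),
  quit = c(base = "quit", past = "quit", gerund = "quitting", third = "quits"),
  cease = c(base = "cease", past = "ceased", gerund = "ceasing", third = "ceases"),
  withhold = c(base = "withhold", past = "withheld", gerund = "withholding", third = "withholds"),
  recommend = c(base = "recommend", past = "recommended", gerund = "recommending", third = "recommends"),
  advise = c(base = "advise", past = "advised", gerund = "advising", third = "advises"),
  suggest = c(base = "suggest", past = "suggested", gerund = "suggesting", third = "suggests"),
  consider = c(base = "consider", past = "considered", gerund = "considering", third = "considers"),
  avoid = c(base = "avoid", past = "avoided", gerund = "avoiding", third = "avoids"),
  inquire = c(base = "inquire", past = "inquired", gerund = "inquiring", third = "inquires"),
  discuss = c(base = "discuss", past = "discussed", gerund = "discussing", third = "discusses"),
  counsel = c(base = "counsel", past = "counseled", gerund = "counseling", third = "counsels"))

## Filler vocabulary for the {gap} slot: content words that survive
## normalization as exactly one token each, so gap length equals the
## token distance it contributes.
GAP_FILLER <- c("daily", "oral", "dose", "mg", "tablet", "capsule",
                "supplement", "regimen", "liquid", "chewable", "generic",
                "herbal", "standard", "strength", "extract", "maintenance",
                "routine", "nightly", "weekly", "low", "high", "otc")
GAP_GLUE <- c("the", "her", "his", "a", "of")

## Co-mentioned distractor substances: deliberately outside the
## supplement lexicon so they can never become target mentions.
DISTRACTOR_SUBSTANCES <- c("aspirin", "estrogen", "tylenol", "ibuprofen",
                           "lisinopril", "metformin", "prednisone",
                           "warfarin", "levothyroxine", "omeprazole")
DISTRACTOR_INDICATORS <- list(C = c("continue", "increase"),
                              D = c("stop", "discontinue"),
                              S = c("start", "add"),
                              U = c("recommend", "avoid"))

## Reverse abbreviation table for the abbreviation perturbation.
ABBREV_SURFACES <- list(continue = "cont", continued = "cont",
                        discontinue = c("dc", "d/c"),
                        discontinued = c("d/ced", "d/cd"),
                        patient = "pt")

#' Load the sentence template bank
#'
#' Parses the packaged template file (or a user-supplied one) and
#' precomputes, per template: indicator/mention/gap slot positions, the
#' fixed content-token count between indicator and mention, and whether
#' the gap slot lies between them (only then does gap length add to the
#' indicator distance).
#'
#' @param path template TSV (default: packaged bank)
#' @return data frame of templates with parsed slot metadata
#' @export
load_templates <- function(path = sup_extdata("templates", "templates.tsv")) {
  lx <- read_lexicon_lines(path)
  stopw <- default_lexicons()$stopwords
  rows <- lapply(seq_along(lx$lines), function(i) {
    parts <- strsplit(lx$lines[i], "\t", fixed = TRUE)[[1]]
    if (length(parts) != 6L) {
      parse_error(path, lx$lineno[i], "expected class, id, source, form, indicators, template")
    }
    cls <- parts[1]; form <- parts[4]
    if (!cls %in% STATUS_CLASSES) parse_error(path, lx$lineno[i], "bad class")
    inds <- if (parts[5] == "-") character(0)
      else trimws(strsplit(parts[5], ",", fixed = TRUE)[[1]])
    bad <- setdiff(inds, names(IND_FORMS))
    if (length(bad)) parse_error(path, lx$lineno[i],
                                 sprintf("unknown indicator(s): %s", paste(bad, collapse = ", ")))
    words <- strsplit(parts[6], " +")[[1]]
    ip <- grep("\\{ind\\}", words); sp <- grep("\\{sup\\}", words)
    gp <- grep("\\{gap\\}", words)
    if (length(sp) != 1L) parse_error(path, lx$lineno[i], "need exactly one {sup}")
    if (form == "none" && length(ip)) parse_error(path, lx$lineno[i], "form 'none' with {ind}")
    if (form != "none" && length(ip) != 1L) parse_error(path, lx$lineno[i], "need exactly one {ind}")
    fb <- 0L; gap_between <- FALSE
    if (length(ip)) {
      lo <- min(ip, sp); hi <- max(ip, sp)
      between <- if (hi - lo > 1L) words[(lo + 1L):(hi - 1L)] else character(0)
      between <- between[!grepl("\\{gap\\}", between)]
      core <- gsub("[^a-z0-9']", "", tolower(between))
      fb <- sum(nzchar(core) & !(core %in% stopw) & !grepl("^[0-9]+$", core))
      gap_between <- length(gp) == 1L && gp > lo && gp < hi
    }
    data.frame(class = cls, id = parts[2], source = parts[3], form = form,
               indicators = I(list(inds)), template = parts[6],
               fixed_between = as.integer(fb), has_gap = length(gp) == 1L,
               gap_between = gap_between, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Generator configuration
#'
#' Defaults emulate the study corpus: 25 supplements x 100 sentences with
#' the pooled class mix C .3348 / D .1956 / S .2412 / U .2284, indicator
#' placed at a geometric-tailed distance of at most
#' `max_indicator_distance` tokens, and perturbations (clinical
#' abbreviations, misspelled supplement variants, negations, distractor
#' co-mentions) applied at fixed rates.
#'
#' @param supplements canonical supplement names (default: the packaged 25)
#' @param sentences_per_supplement sentences generated per supplement
#' @param class_proportions named probabilities over C, D, S, U (must sum
#'   to 1)
#' @param max_indicator_distance cap on the indicator-mention token
#'   distance
#' @param abbreviation_rate,misspelling_rate,negation_rate,distractor_rate
#'   per-sentence perturbation probabilities
#' @param seed integer RNG seed; the whole corpus is a deterministic
#'   function of the configuration
#' @return a `generator_config` object
#' @export
generator_config <- function(supplements = NULL,
                             sentences_per_supplement = 100L,
                             class_proportions = c(C = 837, D = 489, S = 603,
                                                   U = 571) / 2500,
                             max_indicator_distance = 10L,
                             abbreviation_rate = 0.15,
                             misspelling_rate = 0.15,
                             negation_rate = 0.05,
                             distractor_rate = 0.10,
                             seed = 1L) {
  if (is.null(supplements)) {
    supplements <- names(default_lexicons()$supplements$entries)
  }
  stopifnot(sentences_per_supplement >= 1,
            abs(sum(class_proportions) - 1) < 1e-9,
            all(sort(names(class_proportions)) == STATUS_CLASSES),
            max_indicator_distance >= 0)
  rates <- c(abbreviation_rate, misspelling_rate, negation_rate, distractor_rate)
  stopifnot(all(rates >= 0), all(rates <= 1))
  structure(list(supplements = supplements,
                 sentences_per_supplement = as.integer(sentences_per_supplement),
                 class_proportions = class_proportions[STATUS_CLASSES],
                 max_indicator_distance = as.integer(max_indicator_distance),
                 abbreviation_rate = abbreviation_rate,
                 misspelling_rate = misspelling_rate,
                 negation_rate = negation_rate,
                 distractor_rate = distractor_rate,
                 seed = as.integer(seed)),
            class = "generator_config")
}

## Sample a gap length with geometrically decaying weights.
sample_gap <- function(gmax, decay = 0.6) {
  if (gmax <= 0L) return(0L)
  g <- 0:gmax
  sample(g, 1L, prob = decay^g)
}

render_gap <- function(g) {
  if (g == 0L) return("")
  words <- sample(GAP_FILLER, g, replace = g > length(GAP_FILLER))
  if (stats::runif(1) < 0.4) paste(c(sample(GAP_GLUE, 1L), words), collapse = " ")
  else paste(words, collapse = " ")
}

finish_text <- function(x) {
  x <- gsub(" +", " ", trimws(x))
  x <- gsub(" ([.,])", "\\1", x)
  sub("^([a-z])", "\\U\\1", x, perl = TRUE)
}

## Count content tokens (the ones the normalized layer keeps) after the
## target surface in a sentence, used to pad distractor clauses.
content_after <- function(text, surface, stopw) {
  toks <- tokenize(text)
  stoks <- tokenize(surface)
  n <- length(toks); k <- length(stoks)
  pos <- NA_integer_
  for (i in seq_len(n - k + 1L)) {
    if (identical(variant_key(toks[i:(i + k - 1L)]), variant_key(stoks))) {
      pos <- i + k - 1L; break
    }
  }
  if (is.na(pos) || pos >= n) return(0L)
  rest <- toks[(pos + 1L):n]
  sum(!(rest %in% stopw) & !grepl("^[0-9]+$", rest))
}

negation_relabel <- function(indicator_class) {
  switch(indicator_class, D = "C", C = "U", S = "U", U = "U")
}

#' Generate a synthetic annotated corpus
#'
#' Deterministic given the seed: each sentence is assembled from a
#' class-specific template, with its label's indicator placed at a sampled
#' token distance from the supplement mention, then perturbed
#' (abbreviation, misspelled variant, negation with relabeling, distractor
#' clause) at the configured rates. Every sentence carries a construction
#' trace (`template`, `distance`, `perturbations`). By construction the
#' stored label is what the rule engine recovers at unbounded window.
#'
#' @param cfg a [generator_config()]
#' @param lexicons lexicon bundle (supplement variants, abbreviations)
#' @param templates template bank from [load_templates()]
#' @return a labeled `sup_corpus` with provenance columns
#' @export
generate_corpus <- function(cfg = generator_config(),
                            lexicons = default_lexicons(),
                            templates = load_templates()) {
  stopifnot(inherits(cfg, "generator_config"))
  stopw <- lexicons$stopwords
  by_class <- split(seq_len(nrow(templates)), templates$class)
  n_total <- length(cfg$supplements) * cfg$sentences_per_supplement
  rows <- vector("list", n_total)
  with_local_seed(cfg$seed, {
    r <- 0L
    for (sup in cfg$supplements) {
      for (j in seq_len(cfg$sentences_per_supplement)) {
        r <- r + 1L
        label <- sample(STATUS_CLASSES, 1L, prob = cfg$class_proportions)
        ## a negated construction realizes the sampled (final) label from
        ## a source-class indicator: "never stopped X" is C, "not taking
        ## X" / "not started X" is U; D and S cannot arise by negation.
        ## Sampling the final label keeps the class mix at the configured
        ## proportions regardless of the negation rate.
        negated <- label %in% c("C", "U") &&
          stats::runif(1) < cfg$negation_rate
        src_class <- if (!negated) label
          else if (label == "C") "D" else sample(c("C", "S"), 1L)
        cand <- by_class[[src_class]]
        if (negated) cand <- cand[templates$form[cand] != "none"]
        ti <- cand[sample.int(length(cand), 1L)]
        tpl <- templates[ti, ]
        perturbs <- character(0)
        ind_lemma <- NA_character_; ind_surface <- NA_character_
        distance <- NA_integer_
        if (tpl$form != "none") {
          ind_lemma <- sample(tpl$indicators[[1]], 1L)
          ind_surface <- unname(IND_FORMS[[ind_lemma]][tpl$form])
          g <- 0L
          if (tpl$has_gap) {
            gmax <- if (tpl$gap_between)
              max(0L, cfg$max_indicator_distance - tpl$fixed_between) else 3L
            g <- sample_gap(gmax)
          }
          distance <- tpl$fixed_between + if (tpl$gap_between) g else 0L
          text <- tpl$template
          text <- sub("\\{ind\\}", ind_surface, text)
          text <- sub("\\{gap\\}", render_gap(g), text)
        } else {
          text <- tpl$template
          if (tpl$has_gap) text <- sub("\\{gap\\}", "", text)
        }
        sup_surface <- sup
        text <- sub("\\{sup\\}", sup_surface, text)
        final_label <- label

        if (negated) {
          neg <- if (src_class == "D") sample(c("never", "not"), 1L) else "not"
          text <- sub(paste0("\\b", ind_surface, "\\b"),
                      paste(neg, ind_surface), text)
          perturbs <- c(perturbs, "negation")
        }

        ## distractor: co-mentioned substance with a different-status
        ## indicator, strictly farther from the target mention
        if (!is.na(distance) && stats::runif(1) < cfg$distractor_rate) {
          dcls <- sample(setdiff(STATUS_CLASSES, final_label), 1L)
          dlemma <- sample(DISTRACTOR_INDICATORS[[dcls]], 1L)
          dsurf <- unname(IND_FORMS[[dlemma]]["past"])
          subst <- sample(DISTRACTOR_SUBSTANCES, 1L)
          after <- content_after(text, sup_surface, stopw)
          pad <- max(0L, distance + 1L - after)
          padtxt <- if (pad > 0L)
            paste(sample(GAP_FILLER, pad, replace = pad > length(GAP_FILLER)),
                  collapse = " ") else ""
          text <- sub("\\.$", "", text)
          text <- paste0(text, " and ", if (nzchar(padtxt)) paste0(padtxt, " ") else "",
                         dsurf, " ", subst, ".")
          perturbs <- c(perturbs, "distractor")
        }

        ## abbreviation: swap a full word for its clinical short form
        if (stats::runif(1) < cfg$abbreviation_rate) {
          toks <- strsplit(text, " ", fixed = TRUE)[[1]]
          core <- tolower(gsub("[.,]$", "", toks))
          hit <- which(core %in% names(ABBREV_SURFACES))
          if (length(hit)) {
            h <- hit[sample.int(length(hit), 1L)]
            ab <- ABBREV_SURFACES[[core[h]]]
            ab <- ab[sample.int(length(ab), 1L)]
            tm <- regexpr("[.,]$", toks[h])
            trail <- if (tm > 0L) substring(toks[h], tm) else ""
            toks[h] <- paste0(ab, trail)
            text <- paste(toks, collapse = " ")   # stays lowercase until the end
            perturbs <- c(perturbs, "abbreviation")
          }
        }

        ## misspelling: swap the supplement surface for a lexical variant
        if (stats::runif(1) < cfg$misspelling_rate) {
          variants <- setdiff(lexicons$supplements$entries[[sup]], sup_surface)
          if (length(variants)) {
            v <- variants[sample.int(length(variants), 1L)]
            text <- sub(sup_surface, v, text, fixed = TRUE)
            sup_surface <- v
            perturbs <- c(perturbs, "misspelling")
          }
        }

        rows[[r]] <- data.frame(
          id = sprintf("s%05d", r), text = finish_text(text),
          supplement = sup, label = final_label, template = tpl$id,
          distance = distance,
          perturbations = if (length(perturbs)) paste(perturbs, collapse = ",")
                          else NA_character_,
          stringsAsFactors = FALSE)
      }
    }
  })
  out <- do.call(rbind, rows)
  sup_corpus(out$id, out$text, out$supplement, out$label, lexicons,
             template = out$template, distance = out$distance,
             perturbations = out$perturbations)
}

#' Apply one perturbation to a generated sentence record
#'
#' Standalone access to the generator's noise model: `abbreviation`
#' replaces a full word with its clinical short form, `misspelling` swaps
#' the supplement surface for a non-canonical lexical variant, `negation`
#' inserts a negator before the status indicator and relabels the record
#' (D becomes C, C/S become U), and `distractor` appends a clause with a
#' different substance and a different-status indicator placed farther
#' from the target mention than the target's own indicator. An
#' inapplicable kind returns the record unchanged with a `warning` flag.
#'
#' @param record a one-row corpus data frame (needs `text`, `supplement`,
#'   `label`; `distance` for distractor)
#' @param kind one of "abbreviation", "misspelling", "negation",
#'   "distractor"
#' @param lexicons lexicon bundle
#' @param seed RNG seed for the sampled choices
#' @return the modified record, with `perturbations` updated and a
#'   logical `warning` column when the kind was inapplicable
#' @export
perturb <- function(record, kind = c("abbreviation", "misspelling",
                                     "negation", "distractor"),
                    lexicons = default_lexicons(), seed = 1L) {
  kind <- match.arg(kind)
  stopifnot(is.data.frame(record), nrow(record) == 1L)
  with_local_seed(seed, perturb_impl(record, kind, lexicons))
}

perturb_impl <- function(record, kind, lexicons) {
  out <- record
  out$warning <- FALSE
  no_op <- function() { out$warning <- TRUE; out }
  text <- record$text
  toks <- tokenize(text)
  lemmas <- lemmatize(toks, lexicons)
  ind_i <- which(lemmas %in% names(lexicons$indicators$classes))
  if (kind == "abbreviation") {
    words <- strsplit(text, " ", fixed = TRUE)[[1]]
    core <- tolower(gsub("[.,]$", "", words))
    hit <- which(core %in% names(ABBREV_SURFACES))
    if (!length(hit)) return(no_op())
    h <- hit[1L]
    ab <- ABBREV_SURFACES[[core[h]]][1L]
    tm <- regexpr("[.,]$", words[h])
    trail <- if (tm > 0L) substring(words[h], tm) else ""
    words[h] <- paste0(ab, trail)
    out$text <- finish_text(paste(words, collapse = " "))
  } else if (kind == "misspelling") {
    men <- find_mentions(toks, lexicons$supplements)
    men <- men[men$canonical == record$supplement, , drop = FALSE]
    if (!nrow(men)) return(no_op())
    cur <- men$surface[1L]
    variants <- setdiff(lexicons$supplements$entries[[record$supplement]], cur)
    if (!length(variants)) return(no_op())
    out$text <- finish_text(sub(cur, sample(variants, 1L), tolower(text),
                                fixed = TRUE))
  } else if (kind == "negation") {
    if (!length(ind_i)) return(no_op())
    i <- ind_i[1L]
    ind_class <- unname(lexicons$indicators$classes[lemmas[i]])
    neg <- if (ind_class == "D") "never" else "not"
    out$text <- finish_text(sub(paste0("\\b", toks[i], "\\b"),
                                paste(neg, toks[i]), tolower(text)))
    out$label <- negation_relabel(ind_class)
  } else {  # distractor
    if (!length(ind_i) || is.null(record$distance) || is.na(record$distance)) {
      return(no_op())
    }
    dcls <- sample(setdiff(STATUS_CLASSES, record$label), 1L)
    dlemma <- sample(DISTRACTOR_INDICATORS[[dcls]], 1L)
    dsurf <- unname(IND_FORMS[[dlemma]]["past"])
    subst <- sample(DISTRACTOR_SUBSTANCES, 1L)
    men <- find_mentions(toks, lexicons$supplements)
    men <- men[men$canonical == record$supplement, , drop = FALSE]
    if (!nrow(men)) return(no_op())
    after <- content_after(text, men$surface[1L], lexicons$stopwords)
    pad <- max(0L, as.integer(record$distance) + 1L - after)
    padtxt <- if (pad > 0L)
      paste(sample(GAP_FILLER, pad, replace = pad > length(GAP_FILLER)),
            collapse = " ") else ""
    body <- sub("\\.$", "", text)
    out$text <- finish_text(paste0(body, " and ",
                                   if (nzchar(padtxt)) paste0(padtxt, " ") else "",
                                   dsurf, " ", subst, "."))
  }
  prev <- record$perturbations
  out$perturbations <- if (is.null(prev) || is.na(prev)) kind
                       else paste(prev, kind, sep = ",")
  out
}

#' Split a corpus at the supplement level
#'
#' For each supplement independently, a seeded random
#' `round(train_fraction * n)` of its sentences go to training and the
#' rest to test, so both splits cover every supplement.
#'
#' @param corpus a `sup_corpus`
#' @param train_fraction fraction per supplement assigned to training
#'   (default 0.7); fractions leaving an empty split are rejected
#' @param seed RNG seed
#' @return a `split_result`: list with `training`, `test` and a
#'   `counts` data frame (per-supplement training/test sizes)
#' @export
split_corpus <- function(corpus, train_fraction = 0.7, seed = 1L) {
  if (is.null(corpus$supplement)) stop("corpus lacks a supplement field", call. = FALSE)
  tab <- table(corpus$supplement)
  if (any(tab < 2L)) {
    stop(sprintf("supplement(s) with fewer than 2 sentences: %s",
                 paste(names(tab)[tab < 2], collapse = ", ")), call. = FALSE)
  }
  n_tr <- round(train_fraction * as.integer(tab))
  if (any(n_tr < 1L) || any(n_tr >= as.integer(tab))) {
    stop("train_fraction would leave an empty training or test split",
         call. = FALSE)
  }
  train_idx <- integer(0)
  with_local_seed(seed, {
    for (k in seq_along(tab)) {
      idx <- which(corpus$supplement == names(tab)[k])
      train_idx <- c(train_idx, sample(idx, n_tr[k]))
    }
  })
  train_idx <- sort(train_idx)
  training <- corpus[train_idx, , drop = FALSE]
  test <- corpus[-train_idx, , drop = FALSE]
  counts <- data.frame(supplement = names(tab), n = as.integer(tab),
                       training = n_tr, test = as.integer(tab) - n_tr,
                       row.names = NULL, stringsAsFactors = FALSE)
  structure(list(training = training, test = test, counts = counts,
                 train_fraction = train_fraction, seed = seed),
            class = "split_result")
}

#' @export
print.split_result <- function(x, ...) {
  cat(sprintf("<split_result> %d training / %d test sentences over %d supplements\n",
              nrow(x$training), nrow(x$test), nrow(x$counts)))
  invisible(x)
}
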