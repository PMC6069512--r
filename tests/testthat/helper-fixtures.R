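# Shared fixtures, built once per test run and memoised.

fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(fixture_env[[name]])) fixture_env[[name]] <- builder()
  fixture_env[[name]]
}

lexs <- function() fixture("lexs", load_lexicons)

# The full-size default synthetic corpus (25 supplements x 100 sentences)
# and its preprocessed form, shared across test files.
big_corpus <- function() {
  fixture("big_corpus", function() generate_corpus(generator_config(seed = 42)))
}
big_prep <- function() {
  fixture("big_prep", function() prepare_corpus(big_corpus(), lexs()))
}
big_split <- function() {
  fixture("big_split", function() split_corpus(big_corpus(), seed = 7))
}
big_prep_split <- function() {
  fixture("big_prep_split", function() {
    sp <- big_split()
    list(train = prepare_corpus(sp$training, lexs()),
         test = prepare_corpus(sp$test, lexs()))
  })
}

# A small corpus for cheap unit tests.
small_corpus <- function() {
  fixture("small_corpus", function() {
    generate_corpus(generator_config(sentences_per_supplement = 10, seed = 5))
  })
}
small_prep <- function() {
  fixture("small_prep", function() prepare_corpus(small_corpus(), lexs()))
}

# Preprocess a single sentence and locate its target mention.
prep_one <- function(text, supplement) {
  ts <- preprocess_sentence(text, lexs())
  list(ts = ts, mention = supstatus:::locate_target(ts, supplement, lexs()))
}

# A linearly separable labeled corpus: each class draws on a disjoint
# indicator-free vocabulary, so any reasonable learner can fit it exactly.
separable_corpus <- function(n_per_class = 20) {
  vocab <- list(C = c("alpha", "bravo", "charlie"),
                D = c("delta", "echo", "foxtrot"),
                S = c("golf", "hotel", "india"),
                U = c("juliet", "kilo", "lima"))
  rows <- list()
  k <- 0
  for (cl in names(vocab)) {
    for (i in seq_len(n_per_class)) {
      k <- k + 1
      w <- vocab[[cl]][1 + (i %% 3)]
      rows[[k]] <- c(sprintf("x%03d", k),
                     sprintf("%s %s ginkgo noted", w, vocab[[cl]][1]),
                     "ginkgo", cl)
    }
  }
  sup_corpus(id = vapply(rows, `[`, character(1), 1),
             text = vapply(rows, `[`, character(1), 2),
             supplement = vapply(rows, `[`, character(1), 3),
             label = vapply(rows, `[`, character(1), 4))
}
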