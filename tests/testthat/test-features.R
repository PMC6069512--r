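test_that("feature specs encode the nine standard configurations", {
  expect_false(feature_spec(1)$use_normalized)
  expect_true(feature_spec(3)$tfidf)
  expect_equal(feature_spec(3)$ngram_orders, 1L)
  expect_equal(feature_spec(5)$ngram_orders, c(1L, 2L))
  expect_equal(feature_spec(6)$ngram_orders, 1:3)
  expect_true(feature_spec(7)$indicator_features)
  expect_equal(feature_spec(7)$indicator_window, Inf)
  s8 <- feature_spec(8)
  expect_true(s8$indicator_features)
  expect_equal(s8$indicator_window, 6L)
  expect_equal(s8$ngram_orders, c(1L, 2L))
  expect_error(feature_spec(10))
})

test_that("extract_ngrams enumerates contiguous n-grams with counts", {
  lex <- lexs()
  ts <- normalize_tokens(c("stop", "vitamin", "e"), lex)
  uni <- extract_ngrams(ts, feature_spec(2))
  expect_mapequal(as.list(uni), list(stop = 1L, vitamin = 1L, e = 1L))
  bi <- extract_ngrams(ts, feature_spec(4))
  expect_mapequal(as.list(bi), list(stop_vitamin = 1L, vitamin_e = 1L))
  short <- normalize_tokens("ginkgo", lex)
  expect_length(extract_ngrams(short, feature_spec(4)), 0)
  expect_length(extract_ngrams(short, feature_spec(6)), 1)  # unigram only
})

test_that("type 1 uses unlemmatized tokens while type 2 lemmatizes", {
  lex <- lexs()
  ts <- preprocess_sentence("she started taking ginkgo", lex)
  raw <- names(extract_ngrams(ts, feature_spec(1)))
  norm <- names(extract_ngrams(ts, feature_spec(2)))
  expect_true("started" %in% raw)
  expect_true("start" %in% norm)
  expect_false("started" %in% norm)
})

test_that("indicator features respect the distance window", {
  lex <- lexs()
  p <- prep_one("continue fish oil to reduce inflammation", "fish oil")
  expect_equal(extract_indicator_features(p$ts, p$mention, lex$indicators,
                                          feature_spec(8)),
               "IND_continue")
  gap <- paste(rep("dose", 7), collapse = " ")
  p2 <- prep_one(paste("stop", gap, "ginkgo"), "ginkgo")
  expect_length(extract_indicator_features(p2$ts, p2$mention, lex$indicators,
                                           feature_spec(8)), 0)
  # type 7 has no cut-off
  expect_equal(extract_indicator_features(p2$ts, p2$mention, lex$indicators,
                                          feature_spec(7)),
               "IND_stop")
  p3 <- prep_one("stop the ginkgo and restart it later", "ginkgo")
  expect_setequal(extract_indicator_features(p3$ts, p3$mention, lex$indicators,
                                             feature_spec(8)),
                  c("IND_stop", "IND_restart"))
})

test_that("type 5 vocabulary is the union of type 2 and type 4 vocabularies", {
  prep <- small_prep()
  v2 <- fit_vectorizer(prep, feature_spec(2), lexs())$vocabulary
  v4 <- fit_vectorizer(prep, feature_spec(4), lexs())$vocabulary
  v5 <- fit_vectorizer(prep, feature_spec(5), lexs())$vocabulary
  expect_setequal(v5, union(v2, v4))
})

test_that("type 8 columns are type 5 columns plus indicator features", {
  prep <- small_prep()
  v5 <- fit_vectorizer(prep, feature_spec(5), lexs())$vocabulary
  v8 <- fit_vectorizer(prep, feature_spec(8), lexs())$vocabulary
  ind_cols <- setdiff(v8, v5)
  expect_true(all(startsWith(ind_cols, "IND_")))
  expect_setequal(v8, union(v5, ind_cols))
  X5 <- transform_features(fit_vectorizer(prep, feature_spec(5), lexs()),
                           prep, lexs())
  X8 <- transform_features(fit_vectorizer(prep, feature_spec(8), lexs()),
                           prep, lexs())
  expect_equal(as.matrix(X8[, colnames(X5)]), as.matrix(X5))
})

test_that("tf-idf weights match the hand-computed smooth-idf formula", {
  lex <- lexs()
  corp <- sup_corpus(c("a", "b", "c"),
                     c("continue ginkgo daily", "stop ginkgo", "daily dose ginkgo"),
                     rep("ginkgo", 3), c("C", "D", "U"))
  prep <- prepare_corpus(corp, lex)
  vec <- fit_vectorizer(prep, feature_spec(3), lex)
  X <- transform_features(vec, prep, lex)
  # document frequencies: ginkgo 3, daily 2, others 1; N = 3
  idf <- function(df) log((1 + 3) / (1 + df)) + 1
  # "ginkgo" appears in every document: its raw weight is tf * idf floor 1
  expect_equal(vec$df[["ginkgo"]], 3L)
  expect_equal(idf(3), 1)
  # row a: continue (df 1), ginkgo (df 3), daily (df 2), each tf 1
  raw <- c(continue = idf(1), daily = idf(2), ginkgo = idf(3))
  expected <- raw / sqrt(sum(raw^2))
  got <- as.matrix(X)["a", names(raw)]
  expect_equal(unname(got), unname(expected), tolerance = 1e-12)
})

test_that("tf-idf rows have unit L2 norm unless all-zero", {
  prep <- small_prep()
  vec <- fit_vectorizer(prep, feature_spec(3), lexs())
  X <- transform_features(vec, prep, lexs())
  norms <- sqrt(Matrix::rowSums(X^2))
  expect_true(all(abs(norms[norms > 0] - 1) < 1e-12))
})

test_that("transform ignores out-of-vocabulary features", {
  lex <- lexs()
  train <- sup_corpus(c("a", "b"), c("continue ginkgo", "stop ginkgo"),
                      rep("ginkgo", 2), c("C", "D"))
  test <- sup_corpus("z", "zzzunseen wordzz ginkgo plus novel tokens",
                     "ginkgo", "C")
  vec <- fit_vectorizer(prepare_corpus(train, lex), feature_spec(2), lex)
  Xz <- transform_features(vec, prepare_corpus(test, lex), lex)
  expect_equal(colnames(Xz), vec$vocabulary)
  expect_equal(sum(Xz["z", setdiff(colnames(Xz), "ginkgo")]), 0)
})

test_that("vectorizer vocabulary is independent of corpus ordering", {
  corp <- small_corpus()[1:40, ]
  lex <- lexs()
  v1 <- fit_vectorizer(prepare_corpus(corp, lex), feature_spec(5), lex)$vocabulary
  shuffled <- corp[rev(seq_len(nrow(corp))), ]
  v2 <- fit_vectorizer(prepare_corpus(shuffled, lex), feature_spec(5), lex)$vocabulary
  expect_identical(v1, v2)
  expect_identical(v1, sort(v1))
})

test_that("feature matrices export as coordinate text plus vocabulary", {
  prep <- small_prep()
  vec <- fit_vectorizer(prep, feature_spec(2), lexs())
  X <- transform_features(vec, prep, lexs())
  d <- withr::local_tempdir()
  write_feature_matrix(X, file.path(d, "fm"))
  vocab <- readLines(file.path(d, "fm.vocab"))
  expect_identical(vocab, colnames(X))
  coo <- read.table(file.path(d, "fm.coo"), sep = "\t")
  expect_equal(nrow(coo), Matrix::nnzero(X))
  expect_equal(sum(coo$V3), sum(X))
})
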