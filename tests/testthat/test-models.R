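test_that("maximum entropy fits a separable corpus perfectly", {
  corp <- separable_corpus(20)
  cfg <- train_config("maximum-entropy", feature_spec(2), folds = 4, seed = 3)
  mod <- train_model(corp, cfg, lexs())
  pred <- predict(mod, corp, lexs())
  expect_equal(unname(pred), corp$label)
})

test_that("training is deterministic given corpus, config and seed", {
  corp <- separable_corpus(12)
  for (algo in c("maximum-entropy", "random-forest")) {
    cfg <- train_config(algo, feature_spec(2), folds = 4, seed = 17)
    m1 <- train_model(corp, cfg, lexs())
    m2 <- train_model(corp, cfg, lexs())
    expect_identical(m1$selected, m2$selected)
    expect_identical(m1$cv_table, m2$cv_table)
    expect_identical(unname(predict(m1, corp, lexs())),
                     unname(predict(m2, corp, lexs())))
  }
})

test_that("class-probability vectors are normalized", {
  corp <- separable_corpus(12)
  cfg <- train_config("maximum-entropy", feature_spec(2), folds = 4, seed = 3)
  mod <- train_model(corp, cfg, lexs())
  prob <- predict(mod, corp, lexs(), type = "prob")
  expect_equal(dim(prob), c(nrow(corp), 4))
  expect_true(all(abs(rowSums(prob) - 1) < 1e-9))
})

test_that("predict handles empty input and the SVM declines probabilities", {
  corp <- separable_corpus(12)
  cfg <- train_config("svm", feature_spec(2), folds = 4, seed = 3)
  mod <- train_model(corp, cfg, lexs())
  expect_length(predict(mod, corp[0, ], lexs()), 0)
  expect_error(predict(mod, corp, lexs(), type = "prob"), "labels only")
  expect_true(all(predict(mod, corp, lexs()) %in% c("C", "D", "S", "U")))
})

test_that("naive Bayes backs off to the prior-majority class out of vocabulary", {
  # skewed class priors: C dominates
  corp <- separable_corpus(10)
  corp <- rbind(corp, within(separable_corpus(15)[1:15, ],
                             id <- paste0(id, "x")))  # 15 extra C rows
  cfg <- train_config("naive-bayes", feature_spec(2), folds = 5, seed = 3)
  mod <- train_model(corp, cfg, lexs())
  prior_major <- names(which.max(table(corp$label)))
  oov <- sup_corpus("q", "wholly unseen vocabulary here ginkgo",
                    "ginkgo", NA_character_)
  # "ginkgo" occurs in every training sentence, so only the priors and
  # near-uniform likelihoods separate the classes
  pred <- predict(mod, oov, lexs())
  expect_equal(unname(pred), prior_major)
})

test_that("maximum entropy matches a closed-form logistic fit on a toy problem", {
  withr::with_seed(8, {
    n <- 400
    x1 <- rnorm(n); x2 <- rnorm(n)
    p <- plogis(0.7 + 1.3 * x1 - 2 * x2)
    yb <- rbinom(n, 1, p)
  })
  X <- Matrix::Matrix(cbind(f1 = x1, f2 = x2), sparse = TRUE)
  glm_fit <- glm(yb ~ x1 + x2, family = binomial())
  gl <- glmnet::glmnet(X, factor(yb), family = "binomial", alpha = 0,
                       lambda = c(0.01, 1e-6), standardize = FALSE)
  co <- as.numeric(predict(gl, s = 1e-6, type = "coefficients"))
  expect_equal(co, unname(coef(glm_fit)), tolerance = 0.02)
})

test_that("fitted models never touch the test split", {
  sp <- split_corpus(small_corpus(), seed = 4)
  cfg <- train_config("maximum-entropy", feature_spec(2), folds = 5, seed = 9)
  m_with <- train_model(sp$training, cfg, lexs())
  # retrain after "deleting" the test split entirely
  m_without <- train_model(sp$training[seq_len(nrow(sp$training)), ], cfg, lexs())
  expect_identical(serialize(m_with$fit$beta, NULL),
                   serialize(m_without$fit$beta, NULL))
  expect_identical(m_with$selected, m_without$selected)
})

test_that("stratified folds reject classes smaller than the fold count", {
  corp <- separable_corpus(4)  # 4 per class < 10 folds
  cfg <- train_config("naive-bayes", feature_spec(2), folds = 10, seed = 1)
  expect_error(train_model(corp, cfg, lexs()), "stratification")
})

test_that("grid_report lays out one scored cell per algorithm and type", {
  corp <- separable_corpus(12)
  sp <- split_corpus(corp, seed = 2)
  lex <- lexs()
  rep <- grid_report(prepare_corpus(sp$training, lex),
                     prepare_corpus(sp$test, lex), lex,
                     algorithms = c("naive-bayes", "maximum-entropy"),
                     types = c(2, 7), folds = 4, seed = 5)
  expect_equal(nrow(rep), 4)
  expect_setequal(rep$algorithm, c("naive-bayes", "maximum-entropy"))
  expect_equal(sum(rep$best), 1)
  expect_equal(which(rep$best), which.max(rep$f_measure))
  expect_true(all(rep$f_measure >= 0 & rep$f_measure <= 1))
})

test_that("lemma-level features beat raw inflected features on lemma-driven labels", {
  # labels depend only on the indicator lemma; inflection is pure noise,
  # so normalized unigrams (type 2) cannot do worse than raw ones (type 1)
  lex <- lexs()
  withr::with_seed(21, {
    inds <- list(C = c("continue", "continued", "continues", "continuing"),
                 D = c("stop", "stopped", "stops", "stopping"),
                 S = c("start", "started", "starts", "starting"),
                 U = c("recommend", "recommended", "recommends", "recommending"))
    rows <- list()
    k <- 0
    for (cl in names(inds)) {
      for (i in 1:24) {
        k <- k + 1
        rows[[k]] <- c(sprintf("m%03d", k),
                       paste(sample(inds[[cl]], 1), "the daily ginkgo"),
                       "ginkgo", cl)
      }
    }
  })
  corp <- sup_corpus(vapply(rows, `[`, character(1), 1),
                     vapply(rows, `[`, character(1), 2),
                     vapply(rows, `[`, character(1), 3),
                     label = vapply(rows, `[`, character(1), 4))
  sp <- split_corpus(corp, seed = 3)
  rep <- grid_report(prepare_corpus(sp$training, lex),
                     prepare_corpus(sp$test, lex), lex,
                     algorithms = "naive-bayes", types = c(1, 2),
                     folds = 3, seed = 6)
  f1 <- rep$f_measure[rep$type == 1]
  f2 <- rep$f_measure[rep$type == 2]
  expect_gte(f2, f1)
})
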