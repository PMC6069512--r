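test_that("score computes confusion-derived per-class metrics", {
  perfect <- score(c("C", "D", "S", "U"), c("C", "D", "S", "U"))
  expect_true(all(perfect$per_class[, c("precision", "recall", "f_measure")] == 1))
  expect_true(all(perfect$weighted == 1))
  expect_equal(sum(perfect$confusion), 4)

  # hand-counted two-class confusion [[2,1],[0,3]] embedded in C/D labels
  gold <- c("C", "C", "C", "D", "D", "D")
  pred <- c("C", "C", "D", "D", "D", "D")
  r <- score(gold, pred)
  expect_equal(r$confusion["C", "C"], 2)
  expect_equal(r$confusion["C", "D"], 1)
  expect_equal(r$confusion["D", "D"], 3)
  pc <- r$per_class
  expect_equal(pc$precision[pc$class == "C"], 2 / 2)
  expect_equal(pc$precision[pc$class == "D"], 3 / 4)
  expect_equal(pc$recall[pc$class == "C"], 2 / 3)
  expect_equal(pc$recall[pc$class == "D"], 3 / 3)

  expect_error(score(c("C", "D"), "C"), "equal length")
  expect_error(score(c("C", "X"), c("C", "D")), "outside")
})

test_that("per-class supports equal confusion row sums and weighted recall is accuracy", {
  sp <- big_split()
  pred <- classify_corpus(sp$test, lexs())
  r <- score(sp$test$label, pred)
  expect_equal(unname(rowSums(r$confusion)), r$per_class$support)
  expect_equal(sum(r$confusion), r$n)
  # micro recall = accuracy for single-label multiclass
  expect_equal(unname(r$weighted["recall"]), mean(sp$test$label == pred))
  expect_gte(min(r$per_class$f_measure), 0)
  w <- r$weighted["f_measure"]
  expect_true(w >= min(r$per_class$f_measure) - 1e-12 &&
              w <= max(r$per_class$f_measure) + 1e-12)
})

test_that("support-weighted totals reproduce printed table arithmetic", {
  # rule-based classifier table: per-class (P, R, F) and supports
  t2 <- data.frame(support = c(233, 166, 178, 173),
                   precision = c(0.90, 0.92, 0.97, 0.78),
                   recall = c(0.91, 0.80, 0.84, 0.97),
                   f_measure = c(0.90, 0.85, 0.90, 0.86))
  w2 <- round_half_up(weighted_metrics(t2), 2)
  expect_equal(unname(w2), c(0.89, 0.88, 0.88))
})

test_that("score_by_supplement partitions the corpus", {
  sp <- big_split()
  pred <- classify_corpus(sp$test, lexs())
  by_sup <- score_by_supplement(sp$test, pred)
  expect_length(by_sup$reports, 25)
  expect_true(all(by_sup$summary$n == 30))
  expect_equal(sum(by_sup$summary$n), score(sp$test$label, pred)$n)

  one <- sp$test[sp$test$supplement == "ginkgo", ]
  pone <- pred[sp$test$supplement == "ginkgo"]
  solo <- score_by_supplement(one, pone)
  expect_equal(solo$reports$ginkgo$weighted,
               score(one$label, pone)$weighted)
})

test_that("kappa agreement matches closed-form cases", {
  ident <- agreement(rep(c("C", "D"), 50), rep(c("C", "D"), 50))
  expect_equal(ident$kappa, 1)
  expect_equal(ident$percent_agreement, 100)

  # diagonal 45/45, off-diagonal 5/5: p_o = .9, p_e = .5, kappa = .8
  r1 <- rep(c("C", "D"), c(50, 50))
  r2 <- c(rep("C", 45), rep("D", 5), rep("C", 5), rep("D", 45))
  a <- agreement(r1, r2)
  expect_equal(a$p_o, 0.9)
  expect_equal(a$p_e, 0.5)
  expect_equal(a$kappa, 0.8)
  expect_equal(a$p_o, a$percent_agreement / 100)

  # one rater constant while the other is balanced: chance-level agreement
  b <- agreement(rep(c("C", "D"), 20), rep("C", 40))
  expect_equal(b$kappa, 0)

  expect_error(agreement("C", c("C", "D")), "equal length")
})

test_that("agreement is symmetric in its raters", {
  withr::with_seed(14, {
    for (i in 1:5) {
      r1 <- sample(c("C", "D", "S", "U"), 60, replace = TRUE)
      r2 <- sample(c("C", "D", "S", "U"), 60, replace = TRUE)
      a <- agreement(r1, r2); b <- agreement(r2, r1)
      expect_equal(a$kappa, b$kappa)
      expect_equal(a$p_e, b$p_e)
    }
  })
})

test_that("pairwise comparison cells are internally consistent", {
  gold <- rep("C", 10)
  same <- rep(c("C", "D"), 5)
  cmp0 <- compare_classifiers(gold, same, same)
  expect_true(all(cmp0$a_only == 0) && all(cmp0$b_only == 0))

  # constructed class-C row with cells 209 / 3 / 13 / 8
  gold <- rep("C", 233)
  pa <- c(rep("C", 209), rep("C", 3), rep("D", 13), rep("D", 8))
  pb <- c(rep("C", 209), rep("D", 3), rep("C", 13), rep("D", 8))
  cmp <- compare_classifiers(gold, pa, pb)
  rowC <- cmp[cmp$class == "C", ]
  expect_equal(rowC$both_correct, 209)
  expect_equal(rowC$a_only, 3)
  expect_equal(rowC$b_only, 13)
  expect_equal(rowC$both_wrong, 8)
  expect_equal(rowC$tp_a, 212)
  expect_equal(rowC$tp_b, 222)
  expect_equal(rowC$both_correct + rowC$a_only + rowC$b_only + rowC$both_wrong,
               rowC$support)
})

test_that("comparison cells match a brute-force per-sentence tally", {
  withr::with_seed(23, {
    gold <- sample(c("C", "D", "S", "U"), 200, replace = TRUE)
    pa <- sample(c("C", "D", "S", "U"), 200, replace = TRUE)
    pb <- sample(c("C", "D", "S", "U"), 200, replace = TRUE)
  })
  cmp <- compare_classifiers(gold, pa, pb)
  for (cl in c("C", "D", "S", "U")) {
    bc <- ao <- bo <- bw <- 0
    for (i in seq_along(gold)) {
      if (gold[i] != cl) next
      a_ok <- pa[i] == cl; b_ok <- pb[i] == cl
      if (a_ok && b_ok) bc <- bc + 1
      else if (a_ok) ao <- ao + 1
      else if (b_ok) bo <- bo + 1
      else bw <- bw + 1
    }
    row <- cmp[cmp$class == cl, ]
    expect_equal(c(row$both_correct, row$a_only, row$b_only, row$both_wrong),
                 c(bc, ao, bo, bw))
  }
})

test_that("comparison true positives equal the scorer's confusion diagonal", {
  sp <- big_split()
  rule_pred <- classify_corpus(sp$test, lexs())
  alt_pred <- rev(rule_pred)
  cmp <- compare_classifiers(sp$test$label, rule_pred, alt_pred)
  conf <- score(sp$test$label, rule_pred)$confusion
  expect_equal(cmp$tp_a, unname(diag(conf)))
})

test_that("error categorization follows the documented precedence", {
  lex <- lexs()
  cfg <- rule_config()
  corp <- sup_corpus(
    c("e1", "e2", "e3"),
    c("was taking milk thistle when he was living at home, but is no longer doing so",
      "pt quit taking turmeric – restarted less than a week ago",
      paste("stopped", paste(rep("daily", 9), collapse = " "), "ginkgo")),
    c("milk thistle", "turmeric", "ginkgo"),
    c("D", "S", "D"))
  res <- classify_corpus(corp, lex, cfg, diagnostics = TRUE)
  expect_true(all(res$predicted != corp$label))  # all three misclassified
  ec <- categorize_errors(corp, res$predicted, res$diagnostics, cfg)
  expect_equal(ec$errors$category,
               c("missing-pattern", "indicator-issue", "distance-issue"))
  expect_equal(ec$summary$n[ec$summary$category == "total"], 3)
})

test_that("error categories are exhaustive and exclusive over real errors", {
  sp <- big_split()
  res <- classify_corpus(sp$test, lexs(), rule_config(), diagnostics = TRUE)
  ec <- categorize_errors(sp$test, res$predicted, res$diagnostics, rule_config())
  n_err <- sum(sp$test$label != res$predicted)
  expect_equal(nrow(ec$errors), n_err)
  expect_true(all(ec$errors$category %in%
                  c("missing-pattern", "indicator-issue", "distance-issue")))
  expect_equal(sum(ec$summary$n[ec$summary$category != "total"]), n_err)
  expect_error(categorize_errors(sp$test, res$predicted,
                                 res$diagnostics[1], rule_config()),
               "no diagnostics")
})
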