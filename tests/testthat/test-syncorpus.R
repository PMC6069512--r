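test_that("the default configuration emulates the study corpus shape", {
  corp <- big_corpus()
  expect_equal(nrow(corp), 2500)
  expect_true(all(table(corp$supplement) == 100))
  expect_length(unique(corp$supplement), 25)
  expect_true(all(corp$label %in% c("C", "D", "S", "U")))
  expect_true(all(nzchar(corp$text)))
})

test_that("generation is byte-identical for identical seeds", {
  cfg <- generator_config(sentences_per_supplement = 8, seed = 123)
  a <- generate_corpus(cfg)
  b <- generate_corpus(cfg)
  fa <- withr::local_tempfile(); fb <- withr::local_tempfile()
  write_corpus(a, fa); write_corpus(b, fb)
  expect_identical(readLines(fa), readLines(fb))
  c2 <- generate_corpus(generator_config(sentences_per_supplement = 8, seed = 124))
  expect_false(identical(a$text, c2$text))
})

test_that("class frequencies match the configured proportions within 3 SE", {
  corp <- big_corpus()
  props <- generator_config()$class_proportions
  freq <- table(factor(corp$label, levels = names(props))) / nrow(corp)
  se <- sqrt(props * (1 - props) / nrow(corp))
  expect_true(all(abs(freq - props) <= 3 * se))
})

test_that("every stored label is recovered by the rule engine at unbounded window", {
  prep <- big_prep()
  pred <- classify_corpus(prep, lexs(), rule_config(window = 999L))
  expect_equal(unname(pred), big_corpus()$label)
})

test_that("misspelling at rate 1 always draws a lexicon variant surface", {
  lex <- lexs()
  cfg <- generator_config(supplements = c("ginkgo", "ginseng"),
                          sentences_per_supplement = 30,
                          misspelling_rate = 1, abbreviation_rate = 0,
                          negation_rate = 0, distractor_rate = 0, seed = 9)
  corp <- generate_corpus(cfg, lex)
  for (i in seq_len(nrow(corp))) {
    toks <- tokenize(corp$text[i])
    men <- find_mentions(toks, lex$supplements)
    men <- men[men$canonical == corp$supplement[i], , drop = FALSE]
    expect_gte(nrow(men), 1)
    expect_true(nzchar(men$surface[1]))
    expect_true(men$surface[1] %in%
                lex$supplements$entries[[corp$supplement[i]]])
  }
  # at rate 1 the canonical surface is replaced whenever a variant exists
  surfaces <- vapply(seq_len(nrow(corp)), function(i) {
    men <- find_mentions(tokenize(corp$text[i]), lex$supplements)
    men$surface[men$canonical == corp$supplement[i]][1]
  }, character(1))
  expect_true(mean(surfaces != corp$supplement) > 0.9)
})

test_that("the 70/30 supplement-level split reproduces the study sizes", {
  sp <- big_split()
  expect_equal(nrow(sp$training), 1750)
  expect_equal(nrow(sp$test), 750)
  expect_true(all(sp$counts$training == 70))
  expect_true(all(sp$counts$test == 30))
  # partition: every id exactly once across the two splits
  expect_length(intersect(sp$training$id, sp$test$id), 0)
  expect_setequal(c(sp$training$id, sp$test$id), big_corpus()$id)
})

test_that("degenerate split requests are rejected", {
  corp <- small_corpus()
  expect_error(split_corpus(corpus = corp, train_fraction = 1.0), "empty")
  expect_error(split_corpus(corpus = corp, train_fraction = 0), "empty")
  tiny <- corp[1, ]
  expect_error(split_corpus(tiny), "fewer than 2")
})

test_that("perturb applies each noise kind and flags inapplicable ones", {
  lex <- lexs()
  rec <- data.frame(id = "p1", text = "discontinue ginkgo", supplement = "ginkgo",
                    label = "D", distance = 0L, perturbations = NA_character_,
                    stringsAsFactors = FALSE)
  ab <- perturb(rec, "abbreviation", lex, seed = 2)
  expect_false(ab$warning)
  expect_true(tokenize(ab$text)[1] %in% c("dc", "d/c"))
  expect_equal(ab$perturbations, "abbreviation")

  ms <- perturb(rec, "misspelling", lex, seed = 2)
  expect_false(ms$warning)
  men <- find_mentions(tokenize(ms$text), lex$supplements)
  expect_equal(men$canonical, "ginkgo")
  expect_false(men$surface == "ginkgo")

  ng <- data.frame(id = "p2", text = "stopped ginseng", supplement = "ginseng",
                   label = "D", distance = 0L, perturbations = NA_character_,
                   stringsAsFactors = FALSE)
  ng2 <- perturb(ng, "negation", lex, seed = 2)
  expect_equal(ng2$label, "C")
  expect_match(ng2$text, "^Never stopped")
  # negated sentence still classifies to its new label
  expect_equal(unname(classify_corpus(sup_corpus(ng2$id, ng2$text,
                                                 ng2$supplement, ng2$label),
                                      lex)), "C")

  st <- data.frame(id = "p3", text = "started black cohosh", supplement = "black cohosh",
                   label = "S", distance = 0L, perturbations = NA_character_,
                   stringsAsFactors = FALSE)
  dt <- perturb(st, "distractor", lex, seed = 2)
  expect_false(dt$warning)
  expect_equal(dt$label, "S")  # label unchanged
  expect_gt(length(tokenize(dt$text)), length(tokenize(st$text)))
  expect_equal(unname(classify_corpus(sup_corpus(dt$id, dt$text,
                                                 dt$supplement, dt$label),
                                      lex, rule_config(window = 999L))), "S")

  # inapplicable: no indicator to negate
  bare <- data.frame(id = "p4", text = "patient has questions about garlic",
                     supplement = "garlic", label = "U", distance = NA_integer_,
                     perturbations = NA_character_, stringsAsFactors = FALSE)
  ng3 <- perturb(bare, "negation", lex, seed = 2)
  expect_true(ng3$warning)
  expect_equal(ng3$text, bare$text)
})

test_that("construction traces record template, distance and perturbations", {
  corp <- big_corpus()
  expect_true(all(c("template", "distance", "perturbations") %in% names(corp)))
  tpl <- load_templates()
  expect_true(all(corp$template %in% tpl$id))
  d <- corp$distance[!is.na(corp$distance)]
  expect_true(all(d >= 0 & d <= generator_config()$max_indicator_distance))
  expect_gt(sum(grepl("abbreviation", corp$perturbations), na.rm = TRUE), 0)
  expect_gt(sum(grepl("negation", corp$perturbations), na.rm = TRUE), 0)
})
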