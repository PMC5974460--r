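# Small separable corpus: category banks are exclusive, so word features
# should support near-perfect one-vs-rest classification.
classify_fixture <- function(seed = 5, n_conversations = 12) {
  generate_corpus(mc_profile(seed = seed, n_conversations = n_conversations))
}

test_that("cross-validation on separable synthetic data reaches high F", {
  corp <- classify_fixture()
  for (learner in c("naive_bayes", "random_forest")) {
    ev <- cross_validate(corp, "medical", learner, feature_spec(), k = 5, seed = 1)
    expect_gte(ev$f, 0.95)
    expect_true(all(c(ev$precision, ev$recall, ev$f) >= 0 &
                      c(ev$precision, ev$recall, ev$f) <= 1))
  }
  ev_svm <- cross_validate(corp, "medical", "linear_svm",
                           feature_spec(), k = 5, seed = 1)
  expect_gte(ev_svm$f, 0.9)
})

test_that("reported F is the harmonic mean of pooled precision and recall", {
  ev <- cross_validate(classify_fixture(), "physical", "naive_bayes",
                       feature_spec(), k = 5, seed = 2)
  expect_equal(ev$f, 2 * ev$precision * ev$recall / (ev$precision + ev$recall),
               tolerance = 1e-12)
  expect_equal(ev$precision, ev$counts$tp / (ev$counts$tp + ev$counts$fp))
})

test_that("cross-validation is deterministic under a fixed seed", {
  corp <- classify_fixture(seed = 11, n_conversations = 8)
  a <- cross_validate(corp, "medical", "random_forest", feature_spec(),
                      k = 5, seed = 3)
  b <- cross_validate(corp, "medical", "random_forest", feature_spec(),
                      k = 5, seed = 3)
  expect_identical(a$counts, b$counts)
})

test_that("categories with too few positives are refused by name", {
  corp <- make_corpus(c("a b", "c d", "e f"),
                      c("medical", "other", "other"),
                      c(FALSE, FALSE, FALSE))
  expect_error(cross_validate(corp, "medical", k = 10), "medical")
})

test_that("shuffled labels drive F towards the positive-class rate", {
  corp <- classify_fixture(seed = 19, n_conversations = 10)
  s <- corpus_sentences(corp)
  rate <- mean(vapply(s$categories, function(cc) "medical" %in% cc, TRUE))
  fs <- vapply(1:5, function(sd) {
    set.seed(100 + sd)
    shuffled <- s
    shuffled$categories <- sample(shuffled$categories)
    cv <- cross_validate(new_corpus(shuffled, "MC", "shuffled"),
                         "medical", "naive_bayes", feature_spec(),
                         k = 5, seed = sd)
    cv$f
  }, 0)
  # no signal: mean F far below the separable-case level, near chance
  expect_lt(mean(fs), rate + 0.25)
})

test_that("cross-forum transfer with train = test equals resubstitution", {
  corp <- classify_fixture(seed = 23, n_conversations = 6)
  ev <- cross_forum_eval(corp, corp, "medical", "naive_bayes",
                         feature_spec(), seed = 1)
  s <- corpus_sentences(corp)
  s <- s[!vapply(s$categories, function(cc) "multiple" %in% cc, TRUE), ]
  fm <- fit_features(s, feature_spec(), dialect = "MC", seed = 1)
  x <- featurize(fm, s)
  y <- vapply(s$categories, function(cc) "medical" %in% cc, TRUE)
  mod <- fit_learner(x, y, "naive_bayes", seed = 1)
  resub <- evaluate_binary(predict_learner(mod, x), y)
  expect_equal(ev$counts, resub[c("tp", "fp", "fn", "tn")])
})

test_that("shared-vocabulary categories transfer better than divergent ones", {
  banks_a <- default_vocab_banks()
  banks_b <- banks_a
  # second forum talks about different non-medical things entirely
  banks_b$other <- c("visa", "passport", "airline", "luggage", "hotel",
                     "rental", "cruise", "booking", "itinerary", "customs",
                     "currency", "tipping")
  mix <- c(medical = 0.4, other = 0.4, social = 0.2)
  rates <- c(medical = 0, other = 0, social = 0)
  mk <- function(seed, banks) generate_corpus(forum_config(
    seed = seed, n_conversations = 12, category_mixture = mix,
    hasn_rate_by_category = rates, vocab_banks = banks, dialect = "MC"))
  train <- mk(1, banks_a); test <- mk(2, banks_b)
  f_med <- cross_forum_eval(train, test, "medical", "naive_bayes",
                            feature_spec(), seed = 1)$f
  f_other <- cross_forum_eval(train, test, "other", "naive_bayes",
                              feature_spec(), seed = 1)$f
  expect_gt(f_med, f_other)
})

test_that("the need classifier beats the induced rules on held-out data", {
  train <- generate_corpus(mc_profile(seed = 31, n_conversations = 40))
  test <- generate_corpus(mc_profile(seed = 57, n_conversations = 15))
  model <- train_hasn_classifier(train, learner = "random_forest", seed = 1)
  stat_eval <- evaluate_hasn(model, test)
  expect_gte(stat_eval$f, 0.8)

  tr <- corpus_sentences(train)
  rs <- induce_patterns(tr[tr$hasn, ], tr[!tr$hasn, ])
  rule_eval <- evaluate_binary(match_all(rs, test),
                               corpus_sentences(test)$hasn)
  expect_gte(stat_eval$f, rule_eval$f)
})

test_that("an all-negative held-out set flags undefined precision", {
  corp <- make_corpus(c("how do i sleep now", "went home today fine"),
                      c("other", "other"), c(TRUE, FALSE))
  model <- train_hasn_classifier(corp, learner = "naive_bayes",
                                 spec = feature_spec(min_term_count = 1),
                                 seed = 1)
  neg <- make_corpus(c("went home again", "all fine here"),
                     c("other", "other"), c(FALSE, FALSE), conv = "c9")
  ev <- evaluate_hasn(model, neg)
  expect_equal(ev$recall, 0)
  expect_true("recall" %in% ev$undefined)
})

test_that("pooled corpora with duplicate sentence ids are rejected", {
  corp <- classify_fixture(seed = 2, n_conversations = 2)
  expect_error(train_hasn_classifier(list(corp, corp)), "disjoint")
})

test_that("sequential decoding reproduces batch predictions for gold-context specs", {
  corp <- classify_fixture(seed = 40, n_conversations = 4)
  mods <- lapply(c("medical", "social"), function(cat)
    train_category_classifier(corp, cat, "naive_bayes", feature_spec(), seed = 1))
  out <- classify_sequential(mods, corp)
  s <- corpus_sentences(corp)
  expect_identical(out$sentence_id, s$sentence_id)
  fm <- mods[[1]]$features
  batch <- predict_learner(mods[[1]]$model, featurize(fm, s, context_corpus = s))
  seq_med <- vapply(out$predicted, function(p) "medical" %in% p, TRUE)
  expect_identical(seq_med, unname(batch))
})
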