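test_that("generation is byte-identical under a fixed seed", {
  cfg <- mc_profile(seed = 42, n_conversations = 5)
  a <- withr::local_tempfile(fileext = ".jsonl")
  b <- withr::local_tempfile(fileext = ".jsonl")
  write_corpus(generate_corpus(cfg), a)
  write_corpus(generate_corpus(cfg), b)
  expect_identical(readLines(a), readLines(b))
})

test_that("degenerate mixtures and zero need rates behave as stated", {
  cfg <- forum_config(seed = 1, n_conversations = 4,
                      category_mixture = c(social = 1),
                      hasn_rate_by_category = c(social = 0))
  corp <- generate_corpus(cfg)
  expect_true(all(vapply(corp$sentences$categories,
                         function(cc) identical(cc, "social"), TRUE)))
  expect_equal(corpus_stats(corp)$hasn_fraction, 0)
})

test_that("config validation rejects bad mixtures and probabilities", {
  expect_error(forum_config(category_mixture = c(social = 0.5)), "sum to 1")
  expect_error(forum_config(category_mixture = c(social = 1),
                            hasn_rate_by_category = c(social = 1.5)), "\\[0, 1\\]")
  expect_error(forum_config(category_mixture = c(romance = 1)), "romance")
})

test_that("referential sentences carry a referring cue and no bank word", {
  corp <- generate_corpus(mc_profile(seed = 3, n_conversations = 20))
  s <- corpus_sentences(corp)
  prev <- vapply(s$categories, function(cc) "previous" %in% cc, TRUE)
  bank_words <- unlist(default_vocab_banks(), use.names = FALSE)
  cues <- c("this", "that", "it")
  for (toks in s$tokens[prev]) {
    expect_true(any(toks %in% cues))
    expect_false(any(toks %in% bank_words))
  }
})

test_that("need sentences open with question or indirect-statement cues", {
  corp <- generate_corpus(mc_profile(seed = 8, n_conversations = 20))
  s <- corpus_sentences(corp)
  need <- s[s$hasn, ]
  expect_gt(nrow(need), 20)
  # every need sentence is either a question or starts with a first-person
  # indirect cue
  is_q <- grepl("\\?$", need$text)
  starts_i <- startsWith(need$text, "I ")
  expect_true(all(is_q | starts_i))
  expect_gt(sum(is_q), 0)
  expect_gt(sum(starts_i & !is_q), 0)
})

test_that("generated category frequencies converge to the mixture", {
  cfg <- mc_profile(seed = 17, n_conversations = 160)  # ~5000 sentences
  s <- corpus_sentences(generate_corpus(cfg))
  expect_gt(nrow(s), 4500)
  primary <- vapply(s$categories, `[`, "", 1L)
  obs <- table(factor(primary, levels = names(cfg$category_mixture)))
  gof <- suppressWarnings(
    stats::chisq.test(obs, p = cfg$category_mixture / sum(cfg$category_mixture)))
  expect_gt(gof$p.value, 0.01)
})

test_that("label autocorrelation creates topical runs without changing the mixture", {
  cfg0 <- balanced_config(seed = 9, n_conversations = 60)
  cfg1 <- balanced_config(seed = 9, n_conversations = 60,
                          label_autocorrelation = 0.8)
  run_rate <- function(cfg) {
    s <- corpus_sentences(generate_corpus(cfg))
    primary <- vapply(s$categories, `[`, "", 1L)
    same_post <- s$conversation_id[-1] == s$conversation_id[-nrow(s)] &
      s$post_id[-1] == s$post_id[-nrow(s)]
    mean((primary[-1] == primary[-nrow(s)])[same_post])
  }
  expect_lt(run_rate(cfg0), 0.3)
  expect_gt(run_rate(cfg1), 0.6)
  s1 <- corpus_sentences(generate_corpus(cfg1))
  primary <- vapply(s1$categories, `[`, "", 1L)
  obs <- table(factor(primary, levels = names(cfg1$category_mixture)))
  # marginal still near uniform
  expect_lt(max(abs(as.numeric(obs) / sum(obs) - 1 / 9)), 0.05)
})

test_that("education pages cover exactly the configured fraction of topics", {
  banks <- default_vocab_banks()
  n_topics <- length(banks)
  for (cf in c(0, 0.5, 1)) {
    edu <- generate_education_pages(
      education_config(seed = 2, coverage_fraction = cf), banks)
    expect_length(edu$covered_topics, round(cf * n_topics))
    expect_identical(sort(names(edu$gold_coverage)), edu$covered_topics)
    page_tokens <- tokenize_all(edu$pages$text)
    names(page_tokens) <- edu$pages$page_id
    for (topic in edu$topics) {
      hits <- vapply(page_tokens, function(t) sum(t %in% banks[[topic]]), 0)
      if (topic %in% edu$covered_topics) {
        expect_true(all(hits[edu$gold_coverage[[topic]]] >= 3))
      } else {
        expect_true(all(hits == 0))
      }
    }
  }
  expect_error(education_config(coverage_fraction = 1.2), "\\[0, 1\\]")
  expect_error(generate_education_pages(
    education_config(n_pages = 2, coverage_fraction = 1), banks), "smaller")
})

test_that("perfect raters reproduce gold coverage; noisy raters match binomial expectation", {
  results <- tibble::tibble(query_id = rep(paste0("q", 1:500), each = 2),
                            page_id = rep(c("pa", "pb"), 500))
  queries <- tibble::tibble(query_id = paste0("q", 1:500),
                            topic = rep(c("medical", "other"), 250))
  gold <- list(medical = "pa")  # only medical queries' page pa truly covers
  perfect <- simulate_raters(results, queries, gold, rater_config(seed = 1))
  truth <- results$query_id %in% queries$query_id[queries$topic == "medical"] &
    results$page_id == "pa"
  expect_identical(perfect$relevant, rep(truth, 2))

  none <- simulate_raters(results, queries, gold,
                          rater_config(seed = 1, sensitivity = 0))
  expect_false(any(none$relevant))

  noisy <- simulate_raters(results, queries, gold,
                           rater_config(seed = 5, sensitivity = 0.9,
                                        false_positive_rate = 0.05))
  n_true <- sum(truth); n_false <- sum(!truth)
  expected <- 0.9 * n_true + 0.05 * n_false
  se <- sqrt(0.9 * 0.1 * n_true + 0.05 * 0.95 * n_false)
  per_rater <- tapply(noisy$relevant, noisy$rater_id, sum)
  for (x in per_rater) expect_lt(abs(x - expected), 3 * se)
})

test_that("study profiles reproduce their descriptive calibration", {
  mc <- corpus_stats(generate_corpus(mc_profile(seed = 21)))
  expect_lt(abs(mc$mean_words_per_sentence - 14.04), 0.5)
  expect_lt(abs(mc$mean_sentences_per_post - 6.35), 0.75)
  expect_lt(abs(mc$hasn_fraction - 0.057), 0.015)
  csn <- corpus_stats(generate_corpus(csn_profile(seed = 21)))
  expect_lt(abs(csn$mean_words_per_sentence - 13.97), 0.5)
  expect_lt(abs(csn$mean_sentences_per_post - 11.52), 1.0)
  expect_lt(abs(csn$hasn_fraction - 0.087), 0.02)
  # CSN carries two-label sentences, MC never does
  expect_gt(sum(lengths(corpus_sentences(
    generate_corpus(csn_profile(seed = 3, n_conversations = 20)))$categories) == 2), 0)
})
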