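test_that("duplicate need restatements are removed, others retained", {
  corp <- make_corpus(
    c("I am concerned about whether insurance covers this like taxol.",
      "Any answers out there?",
      "Any ideas about that?",
      "We went walking today."),
    c("medical", "previous", "previous", "wellness"),
    c(TRUE, TRUE, TRUE, FALSE))
  need <- select_need_sentences(corp)
  # the restatement directly after a need sentence is dropped; the
  # "previous" need sentence after it (following a previous+need sentence
  # that was itself a duplicate) is kept only if its predecessor is a need
  # sentence -- here the predecessor IS a need sentence, so it is dropped too
  expect_identical(need$index_in_post, 0L)

  corp2 <- make_corpus(
    c("We went walking today.", "Any answers out there?"),
    c("wellness", "previous"), c(FALSE, TRUE))
  expect_equal(nrow(select_need_sentences(corp2)), 1)  # not after a need

  corp3 <- make_corpus("All calm here.", "social", FALSE)
  expect_equal(nrow(select_need_sentences(corp3)), 0)
})

test_that("duplicates require same-post adjacency", {
  corp <- make_corpus(
    c("How do I handle chemo?", "Any answers out there?"),
    c("medical", "previous"), c(TRUE, TRUE),
    post = c("p1", "p2"))
  expect_equal(nrow(select_need_sentences(corp)), 2)
})

test_that("referential resolution picks the nearest non-social sentence", {
  corp <- make_corpus(
    c("Chemo starts monday for me.",   # medical, distance 2
      "Thanks so much everyone.",      # social, distance 1
      "Any ideas about that?"),        # previous (to resolve)
    c("medical", "social", "previous"), c(FALSE, FALSE, TRUE))
  sid <- corpus_sentences(corp)$sentence_id
  expect_identical(resolve_reference(sid[3], corp)$sentence_id, sid[1])

  corp2 <- make_corpus(
    c("Chemo starts monday for me.", "Any ideas about that?"),
    c("medical", "previous"), c(FALSE, TRUE))
  sid2 <- corpus_sentences(corp2)$sentence_id
  expect_identical(resolve_reference(sid2[2], corp2)$sentence_id, sid2[1])

  only_social <- make_corpus(
    c("Thanks all.", "Any ideas about that?"),
    c("social", "previous"), c(FALSE, TRUE))
  sid3 <- corpus_sentences(only_social)$sentence_id
  expect_warning(res <- resolve_reference(sid3[2], only_social), "antecedent")
  expect_identical(res$sentence_id, sid3[2])
})

test_that("resolution ties favour the preceding sentence", {
  corp <- make_corpus(
    c("Chemo starts monday.", "Any ideas about that?", "Radiation was fine."),
    c("medical", "previous", "medical"), c(FALSE, TRUE, FALSE))
  sid <- corpus_sentences(corp)$sentence_id
  expect_identical(resolve_reference(sid[2], corp)$sentence_id, sid[1])
})

test_that("page indexing matches hand counts", {
  pages <- tibble::tibble(page_id = c("a", "b", "c"),
                          text = c("chemo pain chemo", "pain sleep", "diet"))
  idx <- index_pages(pages)
  expect_equal(idx$n_pages, 3)
  expect_equal(idx$avgdl, (3 + 2 + 1) / 3)
  expect_equal(unname(idx$df[c("chemo", "pain", "sleep", "diet")]),
               c(1, 2, 1, 1))
  expect_equal(idx$tf[[1]][["chemo"]], 2)

  dup <- index_pages(tibble::tibble(page_id = c("x", "y"),
                                    text = c("chemo pain", "chemo pain")))
  expect_equal(unname(dup$df["chemo"]), 2)
  expect_equal(dup$length, c(2L, 2L))

  expect_warning(punct <- index_pages(tibble::tibble(
    page_id = c("ok", "bad"), text = c("chemo", "!!! ..."))), "no tokens")
  expect_equal(punct$n_pages, 1)
  expect_error(index_pages(withr::local_tempdir()), "no .txt")
})

test_that("query construction scores tf-idf with the stated smoothing", {
  pages <- tibble::tibble(
    page_id = paste0("p", 1:4),
    text = c("chemo a", "chemo b", "chemo c", "fatigue d"))
  idx <- index_pages(pages)
  corp <- make_corpus("Chemo chemo fatigue hit hard today.",
                      "physical", TRUE)
  q <- build_query(corpus_sentences(corp)$sentence_id[1], corp, idx)
  terms <- q$terms[[1]]
  # hand computation: tf(chemo)=2, idf=ln(5/4)+1; tf(fatigue)=1, idf=ln(5/2)+1
  expect_equal(terms$weight[terms$term == "chemo"], 2 * (log(5 / 4) + 1))
  expect_equal(terms$weight[terms$term == "fatigue"], 1 * (log(5 / 2) + 1))
  expect_gt(terms$weight[terms$term == "chemo"],
            terms$weight[terms$term == "fatigue"])
  expect_true(all(diff(terms$weight) <= 0))
  expect_false(any(terms$term %in% default_stopwords()))
})

test_that("queries cap at ten terms and reject all-stop-word sentences", {
  idx <- index_pages(tibble::tibble(page_id = "p", text = "chemo"))
  many <- paste(paste0("term", 1:12, "x"), collapse = " ")
  corp <- make_corpus(paste0(many, "."), "medical", TRUE)
  q <- build_query(corpus_sentences(corp)$sentence_id[1], corp, idx)
  expect_equal(nrow(q$terms[[1]]), 10)

  stopc <- make_corpus("And so it was.", "other", TRUE)
  expect_error(build_query(corpus_sentences(stopc)$sentence_id[1], stopc, idx),
               "no non-stop-word")
})

test_that("referential queries draw terms only from the antecedent", {
  idx <- index_pages(tibble::tibble(page_id = "p", text = "chemo radiation"))
  corp <- make_corpus(
    c("Radiation burns were awful.", "Thanks friends.", "Any ideas about that one?"),
    c("physical", "social", "previous"), c(FALSE, FALSE, TRUE))
  sid <- corpus_sentences(corp)$sentence_id
  q <- build_query(sid[3], corp, idx)
  expect_identical(q$resolved_sentence_id, sid[1])
  expect_true("radiation" %in% q$terms[[1]]$term)
  expect_false(any(c("ideas", "one") %in% q$terms[[1]]$term))
  expect_identical(q$topic, "physical")
})

test_that("BM25 ranking equals a brute-force evaluation of the formula", {
  vocab <- c("chemo", "pain", "sleep", "diet", "hair", "taxol")
  set.seed(404)
  for (trial in 1:25) {
    n_pages <- sample(2:5, 1)
    texts <- vapply(seq_len(n_pages), function(i)
      paste(sample(vocab, sample(3:12, 1), replace = TRUE), collapse = " "), "")
    idx <- index_pages(tibble::tibble(page_id = paste0("p", seq_len(n_pages)),
                                      text = texts))
    terms <- sample(vocab, sample(1:5, 1))
    got <- bm25_rank(terms, idx, top_k = n_pages)
    want <- brute_force_bm25(terms, texts)
    expect_equal(got$score, sort(want, decreasing = TRUE), tolerance = 1e-12)
    expect_true(all(diff(got$score) <= 0))
  }
})

test_that("BM25 edge cases: absent terms score zero, ties break by page id", {
  idx <- index_pages(tibble::tibble(page_id = c("b", "a"),
                                    text = c("chemo pain", "chemo pain")))
  none <- bm25_rank("zzz", idx, top_k = 2)
  expect_equal(none$score, c(0, 0))
  tie <- bm25_rank("chemo", idx, top_k = 2)
  expect_identical(tie$page_id, c("a", "b"))  # equal scores, id order
  single <- index_pages(tibble::tibble(page_id = "only", text = "chemo"))
  expect_identical(bm25_rank("chemo", single)$page_id[1], "only")
})

test_that("percent agreement and per-rater fractions match hand counts", {
  ratings <- dplyr::bind_rows(
    tibble::tibble(query_id = "q1", page_id = c("a", "b"),
                   rater_id = "r1", relevant = c(TRUE, FALSE)),
    tibble::tibble(query_id = "q1", page_id = c("a", "b"),
                   rater_id = "r2", relevant = c(TRUE, TRUE)))
  pa <- percent_agreement(ratings)
  expect_equal(pa$agreement, 0.5)
  expect_equal(unname(pa$per_rater), c(0.5, 1))
  expect_false(pa$pairwise)

  same <- ratings; same$relevant <- TRUE
  expect_equal(percent_agreement(same)$agreement, 1)
  flip <- ratings
  flip$relevant <- rep(c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(percent_agreement(flip)$agreement, 0)

  missing <- ratings[-1, ]
  expect_error(percent_agreement(missing), "missing verdict")
})

test_that("three raters fall back to mean pairwise agreement with a flag", {
  ratings <- dplyr::bind_rows(lapply(1:3, function(r) tibble::tibble(
    query_id = "q1", page_id = c("a", "b"),
    rater_id = paste0("r", r),
    relevant = c(r < 3, FALSE))))
  pa <- percent_agreement(ratings)
  expect_true(pa$pairwise)
  # pairs: r1r2 agree on both; r1r3 and r2r3 agree on 1 of 2
  expect_equal(pa$agreement, mean(c(1, 0.5, 0.5)))
})

test_that("coverage distinguishes any-rater from all-rater relevance", {
  mk <- function(q, p, r1, r2) dplyr::bind_rows(
    tibble::tibble(query_id = q, page_id = p, rater_id = "r1", relevant = r1),
    tibble::tibble(query_id = q, page_id = p, rater_id = "r2", relevant = r2))
  ratings <- dplyr::bind_rows(
    mk("q1", "a", TRUE, TRUE),    # covered by all
    mk("q2", "b", TRUE, FALSE),   # covered by one
    mk("q3", "c", FALSE, FALSE))  # uncovered
  cv <- coverage(ratings)
  expect_equal(cv$coverage_any, 2 / 3)
  expect_equal(cv$coverage_all, 1 / 3)

  all_rel <- ratings; all_rel$relevant <- TRUE
  expect_equal(coverage(all_rel)[c("coverage_any", "coverage_all")],
               list(coverage_any = 1, coverage_all = 1))
  none_rel <- ratings; none_rel$relevant <- FALSE
  expect_equal(coverage(none_rel)$coverage_any, 0)
})

test_that("coverage_all never exceeds coverage_any on random rating tables", {
  set.seed(808)
  for (trial in 1:30) {
    rt <- random_rating_table(n_queries = sample(3:12, 1),
                              n_raters = sample(2:3, 1),
                              p_relevant = runif(1))
    cv <- coverage(rt)
    expect_lte(cv$coverage_all, cv$coverage_any)
    expect_lte(cv$coverage_any, 1)
  }
})

test_that("gap artifacts are written: queries, report, review markdown", {
  fc <- balanced_config(seed = 61, n_conversations = 8)
  corp <- generate_corpus(fc)
  edu <- generate_education_pages(
    education_config(seed = 62, coverage_fraction = 1), fc$vocab_banks)
  idx <- index_pages(edu$pages)
  qs <- suppressWarnings(build_queries(corp, idx))
  res <- retrieve_all(qs, idx)
  rt <- simulate_raters(res, qs, edu$gold_coverage, rater_config(seed = 63))
  gr <- gap_report(qs, rt)

  qpath <- withr::local_tempfile(fileext = ".csv")
  write_queries(qs, qpath)
  qtab <- utils::read.csv(qpath)
  expect_equal(nrow(qtab), nrow(qs))
  expect_true(all(grepl(":", qtab$terms)))

  gpath <- withr::local_tempfile(fileext = ".csv")
  tpath <- withr::local_tempfile(fileext = ".txt")
  write_gap_report(gr, gpath, tpath)
  row <- utils::read.csv(gpath)
  expect_equal(row$coverage_any, gr$coverage_any)
  expect_true(any(grepl("knowledge gap", readLines(tpath))))

  rpath <- withr::local_tempfile(fileext = ".md")
  write_review_file(qs[1:2, ], res, corp, edu$pages, rpath)
  md <- readLines(rpath)
  expect_true(any(startsWith(md, "## q:")))
  expect_true(any(grepl("\\*\\*", md)))
})
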