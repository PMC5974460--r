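# Independent oracles, implemented from the definitions rather than by the
# package's code paths.

# Brute-force minimal separating subset: enumerate every subset of the
# candidate bigrams via bitmasks, sort by (size, lexicographic position
# order), return the first subset contained in no negative bigram set.
brute_force_separating_subset <- function(cand, neg_bigram_sets, max_size = 4) {
  n <- length(cand)
  if (n == 0) return(NULL)
  masks <- seq_len(2^n - 1)
  sizes <- vapply(masks, function(m) sum(bitwAnd(m, 2^(0:(n - 1))) > 0), 0)
  keep <- sizes <= max_size
  masks <- masks[keep]; sizes <- sizes[keep]
  # lexicographic over member index vectors within a size
  keyord <- order(sizes, vapply(masks, function(m) {
    idx <- which(bitwAnd(m, 2^(0:(n - 1))) > 0)
    paste(sprintf("%03d", idx), collapse = "")
  }, ""))
  for (m in masks[keyord]) {
    s <- cand[bitwAnd(m, 2^(0:(n - 1))) > 0]
    separates <- !any(vapply(neg_bigram_sets, function(nb) all(s %in% nb), TRUE))
    if (separates) return(s)
  }
  NULL
}

# Full rule-induction oracle following the loop definition directly.
brute_force_induce <- function(pos_tokens, neg_tokens, v, max_size = 4) {
  neg_sets <- lapply(neg_tokens, function(t) unique(bigrams(t)))
  patterns <- list()
  unseparable <- integer(0)
  for (i in seq_along(pos_tokens)) {
    sent_bg <- unique(bigrams(pos_tokens[[i]]))
    if (any(vapply(patterns, function(p) all(p %in% sent_bg), TRUE))) next
    cand <- candidate_bigrams(pos_tokens[[i]], v)
    s <- brute_force_separating_subset(cand, neg_sets, max_size)
    if (is.null(s)) unseparable <- c(unseparable, i)
    else patterns[[length(patterns) + 1]] <- s
  }
  list(patterns = patterns, unseparable = unseparable)
}

# Okapi BM25 evaluated directly from raw page texts (no shared code with
# index_pages / bm25_rank beyond the tokenizer definition, re-stated here).
brute_force_bm25 <- function(query_terms, page_texts, k1 = 1.2, b = 0.75) {
  toks <- lapply(page_texts, function(x) {
    t <- strsplit(tolower(x), "\\s+")[[1]]
    t <- gsub("^[^a-z0-9]+|[^a-z0-9]+$", "", t)
    t[nzchar(t)]
  })
  N <- length(toks)
  avgdl <- mean(vapply(toks, length, 0))
  query_terms <- unique(query_terms)
  vapply(seq_len(N), function(d) {
    score <- 0
    for (t in query_terms) {
      df <- sum(vapply(toks, function(x) t %in% x, TRUE))
      f <- sum(toks[[d]] == t)
      idf <- log(1 + (N - df + 0.5) / (df + 0.5))
      score <- score + idf * f * (k1 + 1) /
        (f + k1 * (1 - b + b * length(toks[[d]]) / avgdl))
    }
    score
  }, 0)
}

# Random rating table (complete: every rater rates every document).
random_rating_table <- function(n_queries, docs_per_query = 2, n_raters = 2,
                                p_relevant = 0.3) {
  rows <- list()
  for (q in seq_len(n_queries)) {
    for (d in seq_len(docs_per_query)) {
      for (r in seq_len(n_raters)) {
        rows[[length(rows) + 1]] <- tibble::tibble(
          query_id = paste0("q", q), page_id = paste0("d", q, "_", d),
          rater_id = paste0("r", r),
          relevant = stats::runif(1) < p_relevant)
      }
    }
  }
  dplyr::bind_rows(rows)
}
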