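#' Default stop-word list
#'
#' A standard English stop-word list (~180 words) extended with forum
#' artifacts (greetings, thanks) that carry no retrieval value.
#'
#' @return Character vector of lowercased stop-words.
#' @export
default_stopwords <- function() {
  path <- system.file("extdata", "stopwords.txt", package = "needgap")
  read_word_list(path)
}

#' Select need sentences for query construction
#'
#' Returns the sentences flagged as expressing an information need, minus
#' duplicates: a sentence is a duplicate if it is labelled "previous" and
#' immediately follows (same post, next index) another need sentence — the
#' restatement pattern ("... Any answers out there?").
#'
#' @param corpus A labelled `needgap_corpus`.
#' @return Tibble of retained need sentences in corpus order.
#' @export
select_need_sentences <- function(corpus) {
  s <- corpus_sentences(corpus)
  is_prev <- vapply(s$categories, function(cc) "previous" %in% cc, TRUE)
  dup <- logical(nrow(s))
  if (nrow(s) > 1L) {
    same_post <- s$conversation_id[-1] == s$conversation_id[-nrow(s)] &
      s$post_id[-1] == s$post_id[-nrow(s)] &
      s$index_in_post[-1] == s$index_in_post[-nrow(s)] + 1L
    dup[-1] <- s$hasn[-1] & is_prev[-1] & same_post & s$hasn[-nrow(s)]
  }
  s[s$hasn & !dup, ]
}

#' Resolve the antecedent of a referential sentence
#'
#' For a sentence labelled "previous", finds the nearest sentence in the
#' same conversation (by absolute sentence distance in conversation order;
#' ties favour the preceding sentence) whose categories include at least
#' one category other than social/previous. If no such sentence exists the
#' sentence itself is returned with a warning. Non-referential sentences
#' resolve to themselves.
#'
#' @param sentence_id Id of the sentence to resolve.
#' @param corpus A labelled `needgap_corpus`.
#' @return The resolved sentence as a one-row tibble.
#' @export
resolve_reference <- function(sentence_id, corpus) {
  s <- corpus_sentences(corpus)
  i <- match(sentence_id, s$sentence_id)
  if (is.na(i)) stop("unknown sentence_id: ", sentence_id)
  if (!"previous" %in% s$categories[[i]]) return(s[i, ])
  conv <- which(s$conversation_id == s$conversation_id[i])
  informative <- vapply(s$categories[conv], function(cc)
    length(setdiff(cc, c("social", "previous"))) > 0, TRUE)
  cand <- conv[informative & conv != i]
  if (length(cand) == 0L) {
    warning("no non-social antecedent in conversation for ", sentence_id,
            "; using the sentence itself")
    return(s[i, ])
  }
  d <- abs(cand - i)
  best <- cand[d == min(d)]
  j <- if (length(best) > 1L) min(best) else best  # tie -> preceding
  s[j, ]
}

#' Index education pages for retrieval
#'
#' Tokenization is identical to the corpus tokenizer so query and page
#' vocabularies align. Pages with no tokens are excluded with a warning.
#'
#' @param x Directory containing one `.txt` file per page, or a tibble with
#'   `page_id` and `text` columns.
#' @param k1,b Okapi BM25 parameters (defaults 1.2 and 0.75).
#' @return A `needgap_page_index`: per-page token counts and lengths,
#'   document frequencies, average page length, and the BM25 parameters.
#' @export
index_pages <- function(x, k1 = 1.2, b = 0.75) {
  if (is.character(x) && length(x) == 1L) {
    if (!dir.exists(x)) stop("pages directory does not exist: ", x)
    files <- sort(list.files(x, pattern = "\\.txt$", full.names = TRUE))
    if (length(files) == 0L) stop("no .txt pages found in ", x)
    pages <- tibble::tibble(
      page_id = tools::file_path_sans_ext(basename(files)),
      text = vapply(files, function(f)
        paste(readLines(f, warn = FALSE, encoding = "UTF-8"), collapse = " "), ""))
  } else {
    pages <- tibble::as_tibble(x)
    stopifnot(all(c("page_id", "text") %in% names(pages)))
  }
  toks <- tokenize_all(pages$text)
  empty <- lengths(toks) == 0L
  if (any(empty)) {
    warning("excluding ", sum(empty), " page(s) with no tokens: ",
            paste(pages$page_id[empty], collapse = ", "))
    pages <- pages[!empty, ]
    toks <- toks[!empty]
  }
  if (nrow(pages) == 0L) stop("no non-empty pages to index")
  tf <- lapply(toks, function(t) {
    tab <- table(t)
    stats::setNames(as.integer(tab), names(tab))
  })
  df_tab <- table(unlist(lapply(tf, names)))
  structure(list(
    page_id = pages$page_id,
    tf = tf,
    length = lengths(toks),
    df = stats::setNames(as.integer(df_tab), names(df_tab)),
    n_pages = nrow(pages),
    avgdl = mean(lengths(toks)),
    k1 = k1, b = b),
    class = "needgap_page_index")
}

#' @export
print.needgap_page_index <- function(x, ...) {
  cat("<needgap_page_index>", x$n_pages, "pages, avg length",
      round(x$avgdl, 1), "tokens,", length(x$df), "terms\n")
  invisible(x)
}

# smoothed tf-idf idf used for query-term scoring
#' @noRd
tfidf_idf <- function(df, n_docs) log((n_docs + 1) / (df + 1)) + 1

#' Build a retrieval query from a need sentence
#'
#' Referential ("previous") sentences first resolve to their nearest
#' non-social antecedent, and the query terms come only from that antecedent.
#' Stop-words are removed, each remaining content term is scored tf * idf
#' (raw within-sentence count; smoothed idf `ln((N+1)/(df+1)) + 1` over the
#' page index by default, or over the corpus sentences with
#' `idf_source = "corpus"`), and up to `k` of the highest-scoring terms are
#' kept, ties broken alphabetically.
#'
#' @param sentence_id Need sentence id (from [select_need_sentences()]).
#' @param corpus A labelled `needgap_corpus`.
#' @param index A `needgap_page_index` (idf collection by default).
#' @param stoplist Character stop-word vector.
#' @param k Maximum number of query terms (default 10).
#' @param idf_source `"pages"` or `"corpus"`.
#' @return One-row tibble: `query_id`, `source_sentence_id`,
#'   `resolved_sentence_id`, `topic` (first non-social gold category of the
#'   resolved sentence), `terms` (list of tibbles `term`, `weight`, weight
#'   descending).
#' @export
build_query <- function(sentence_id, corpus, index, stoplist = default_stopwords(),
                        k = 10L, idf_source = c("pages", "corpus")) {
  idf_source <- match.arg(idf_source)
  resolved <- resolve_reference(sentence_id, corpus)
  toks <- resolved$tokens[[1]]
  content <- toks[!toks %in% stoplist]
  if (length(content) == 0L) {
    stop("sentence ", sentence_id, " (resolved to ", resolved$sentence_id,
         ") has no non-stop-word tokens")
  }
  tf <- table(content)
  if (idf_source == "pages") {
    df <- index$df[names(tf)]
    df[is.na(df)] <- 0L
    n_docs <- index$n_pages
  } else {
    s <- corpus_sentences(corpus)
    df <- vapply(names(tf), function(t)
      sum(vapply(s$tokens, function(x) t %in% x, TRUE)), 0L)
    n_docs <- nrow(s)
  }
  score <- as.numeric(tf) * tfidf_idf(as.numeric(df), n_docs)
  ord <- order(-score, names(tf))
  top <- utils::head(ord, k)
  topic_cats <- setdiff(resolved$categories[[1]], c("social", "previous"))
  tibble::tibble(
    query_id = paste0("q:", sentence_id),
    source_sentence_id = sentence_id,
    resolved_sentence_id = resolved$sentence_id,
    topic = if (length(topic_cats) > 0) topic_cats[1] else resolved$categories[[1]][1],
    terms = list(tibble::tibble(term = names(tf)[top],
                                weight = score[top])))
}

#' Build queries for every retained need sentence
#'
#' Sentences whose resolved text is all stop-words are skipped with a
#' warning naming them.
#'
#' @inheritParams build_query
#' @param corpus A labelled `needgap_corpus`.
#' @return Tibble of queries (see [build_query()]).
#' @export
build_queries <- function(corpus, index, stoplist = default_stopwords(),
                          k = 10L, idf_source = "pages") {
  need <- select_need_sentences(corpus)
  out <- list()
  skipped <- character(0)
  for (sid in need$sentence_id) {
    q <- tryCatch(
      build_query(sid, corpus, index, stoplist, k, idf_source),
      error = function(e) NULL)
    if (is.null(q)) skipped <- c(skipped, sid) else out[[length(out) + 1L]] <- q
  }
  if (length(skipped) > 0) {
    warning("skipped ", length(skipped),
            " need sentence(s) with no content terms: ",
            paste(utils::head(skipped, 5), collapse = ", "))
  }
  dplyr::bind_rows(out)
}

# BM25 idf with the usual +1 smoothing inside the log
#' @noRd
bm25_idf <- function(df, n_pages) log(1 + (n_pages - df + 0.5) / (df + 0.5))

#' Rank pages for a query with Okapi BM25
#'
#' score(q, d) = sum over query terms t of
#' idf(t) * f(t,d) * (k1 + 1) / (f(t,d) + k1 * (1 - b + b * |d| / avgdl)),
#' with idf(t) = ln(1 + (N - df + 0.5) / (df + 0.5)). Each distinct query
#' term contributes once (tf-idf weights select the terms; they do not enter
#' the BM25 score). Ties are broken by page id.
#'
#' @param query One-row query tibble from [build_query()], or a character
#'   vector of terms.
#' @param index A `needgap_page_index`.
#' @param top_k Number of pages returned (default 2).
#' @return Tibble `query_id`, `rank`, `page_id`, `score` (scores
#'   non-increasing).
#' @export
bm25_rank <- function(query, index, top_k = 2L) {
  stopifnot(inherits(index, "needgap_page_index"))
  if (is.character(query)) {
    terms <- unique(query)
    qid <- "q:adhoc"
  } else {
    terms <- unique(query$terms[[1]]$term)
    qid <- query$query_id[1]
  }
  df <- index$df[terms]
  df[is.na(df)] <- 0L
  idf <- bm25_idf(as.numeric(df), index$n_pages)
  scores <- vapply(seq_len(index$n_pages), function(d) {
    f <- index$tf[[d]][terms]
    f[is.na(f)] <- 0L
    norm <- index$k1 * (1 - index$b + index$b * index$length[d] / index$avgdl)
    sum(idf * as.numeric(f) * (index$k1 + 1) / (as.numeric(f) + norm))
  }, 0)
  ord <- order(-scores, index$page_id)
  top <- utils::head(ord, top_k)
  tibble::tibble(query_id = qid, rank = seq_along(top),
                 page_id = index$page_id[top], score = scores[top])
}

#' @rdname bm25_rank
#' @param queries Query tibble from [build_queries()].
#' @return `retrieve_all()`: row-bound rankings for every query.
#' @export
retrieve_all <- function(queries, index, top_k = 2L) {
  dplyr::bind_rows(lapply(seq_len(nrow(queries)), function(i)
    bm25_rank(queries[i, ], index, top_k)))
}

#' Percent agreement over rated documents
#'
#' Simple agreement, unadjusted for chance: the fraction of rated documents
#' (query-page pairs) on which the raters give identical verdicts. With more
#' than two raters the mean over rater pairs is reported and flagged.
#'
#' @param ratings Rating table: `query_id`, `page_id`, `rater_id`,
#'   `relevant`; every rater must rate every document (missing verdicts
#'   raise an error listing them).
#' @return List: `agreement`, `n_documents`, `per_rater` (named relevant
#'   fractions), `pairwise` (flag, TRUE when > 2 raters were averaged).
#' @export
percent_agreement <- function(ratings) {
  wide <- ratings_wide(ratings)
  raters <- attr(wide, "raters")
  if (length(raters) < 2L) stop("percent agreement needs at least 2 raters")
  pairs <- utils::combn(raters, 2L, simplify = FALSE)
  agree <- vapply(pairs, function(p) mean(wide[, p[1]] == wide[, p[2]]), 0)
  list(agreement = mean(agree),
       n_documents = nrow(wide),
       per_rater = colMeans(wide[, raters, drop = FALSE]),
       pairwise = length(raters) > 2L)
}

# one row per (query, page), one logical column per rater
#' @noRd
ratings_wide <- function(ratings) {
  ratings <- tibble::as_tibble(ratings)
  raters <- sort(unique(ratings$rater_id))
  key <- paste(ratings$query_id, ratings$page_id, sep = "\r")
  docs <- unique(key)
  wide <- matrix(NA, length(docs), length(raters),
                 dimnames = list(docs, raters))
  wide[cbind(match(key, docs), match(ratings$rater_id, raters))] <- ratings$relevant
  if (anyNA(wide)) {
    miss <- which(is.na(wide), arr.ind = TRUE)
    labels <- paste0("(", gsub("\r", ", ", docs[miss[, 1]]), ", ",
                     raters[miss[, 2]], ")")
    stop("missing verdict(s): ", paste(utils::head(labels, 5), collapse = "; "))
  }
  qp <- do.call(rbind, strsplit(docs, "\r", fixed = TRUE))
  out <- wide
  attr(out, "raters") <- raters
  attr(out, "query_id") <- qp[, 1]
  out
}

#' Any-rater and all-rater coverage of need queries
#'
#' `coverage_any` is the fraction of queries with at least one retrieved
#' document judged relevant by at least one rater; `coverage_all` is the
#' fraction with at least one document judged relevant by every rater. The
#' complement of coverage estimates the knowledge gap.
#'
#' @param ratings Rating table (see [percent_agreement()]).
#' @return List: `coverage_any`, `coverage_all`, `n_queries`.
#' @export
coverage <- function(ratings) {
  wide <- ratings_wide(ratings)
  qid <- attr(wide, "query_id")
  any_doc <- rowSums(wide) > 0
  all_doc <- rowSums(wide) == ncol(wide)
  qs <- unique(qid)
  cov_any <- vapply(qs, function(q) any(any_doc[qid == q]), TRUE)
  cov_all <- vapply(qs, function(q) any(all_doc[qid == q]), TRUE)
  list(coverage_any = mean(cov_any), coverage_all = mean(cov_all),
       n_queries = length(qs))
}

#' Assemble a gap report
#'
#' @param queries Query tibble (used for the query count).
#' @param ratings Rating table covering the retrieved documents.
#' @return A `needgap_gap_report`: query/document counts, percent
#'   agreement, per-rater relevant fractions, any/all-rater coverage.
#' @export
gap_report <- function(queries, ratings) {
  pa <- percent_agreement(ratings)
  cv <- coverage(ratings)
  structure(list(n_queries = nrow(queries),
                 n_documents_rated = pa$n_documents,
                 percent_agreement = pa$agreement,
                 per_rater = pa$per_rater,
                 coverage_any = cv$coverage_any,
                 coverage_all = cv$coverage_all),
            class = "needgap_gap_report")
}

#' @export
print.needgap_gap_report <- function(x, ...) {
  cat(sprintf("Queries: %d; documents rated: %d\n",
              x$n_queries, x$n_documents_rated))
  cat(sprintf("Agreement over documents: %.1f%%\n", 100 * x$percent_agreement))
  for (r in names(x$per_rater)) {
    cat(sprintf("  %s marked %.1f%% of documents relevant\n",
                r, 100 * x$per_rater[[r]]))
  }
  cat(sprintf("Coverage by >=1 rater: %.1f%%; by all raters: %.1f%%\n",
              100 * x$coverage_any, 100 * x$coverage_all))
  cat(sprintf("Estimated knowledge gap: %.1f%% - %.1f%% of needs unaddressed\n",
              100 * (1 - x$coverage_any), 100 * (1 - x$coverage_all)))
  invisible(x)
}

#' Write gap-assessment artifacts
#'
#' `write_queries()` writes the query table (terms pipe-delimited with
#' weights); `write_gap_report()` writes a one-row CSV plus an optional
#' plain-text summary; `write_review_file()` renders a markdown review file
#' showing, for each query, its full posting with the query sentence
#' highlighted and the retrieved pages with matched terms marked — the
#' hand-off format for human relevance raters.
#'
#' @param queries Query tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_queries <- function(queries, path) {
  terms <- vapply(queries$terms, function(t)
    paste(sprintf("%s:%.4f", t$term, t$weight), collapse = "|"), "")
  out <- data.frame(query_id = queries$query_id,
                    source_sentence_id = queries$source_sentence_id,
                    resolved_sentence_id = queries$resolved_sentence_id,
                    topic = queries$topic,
                    terms = terms, stringsAsFactors = FALSE)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_queries
#' @param report A `needgap_gap_report`.
#' @param txt_path Optional text summary path.
#' @export
write_gap_report <- function(report, path, txt_path = NULL) {
  stopifnot(inherits(report, "needgap_gap_report"))
  row <- data.frame(n_queries = report$n_queries,
                    n_documents_rated = report$n_documents_rated,
                    percent_agreement = report$percent_agreement,
                    coverage_any = report$coverage_any,
                    coverage_all = report$coverage_all)
  for (r in names(report$per_rater)) {
    row[[paste0("relevant_frac_", r)]] <- report$per_rater[[r]]
  }
  utils::write.csv(row, path, row.names = FALSE)
  if (!is.null(txt_path)) {
    writeLines(utils::capture.output(print(report)), txt_path)
  }
  invisible(path)
}

#' @rdname write_queries
#' @param results Retrieval results from [retrieve_all()].
#' @param corpus The source corpus.
#' @param pages Page tibble (`page_id`, `text`).
#' @export
write_review_file <- function(queries, results, corpus, pages, path) {
  s <- corpus_sentences(corpus)
  lines <- c("# Relevance review", "")
  for (i in seq_len(nrow(queries))) {
    q <- queries[i, ]
    src <- s[s$sentence_id == q$source_sentence_id, ]
    post <- s[s$conversation_id == src$conversation_id &
                s$post_id == src$post_id, ]
    lines <- c(lines, sprintf("## %s", q$query_id), "", "Posting:", "")
    for (j in seq_len(nrow(post))) {
      mark <- if (post$sentence_id[j] == q$source_sentence_id) "**" else ""
      lines <- c(lines, sprintf("> %s%s%s", mark, post$text[j], mark))
    }
    terms <- q$terms[[1]]$term
    lines <- c(lines, "", sprintf("Query terms: %s", paste(terms, collapse = ", ")), "")
    hits <- results[results$query_id == q$query_id, ]
    for (j in seq_len(nrow(hits))) {
      txt <- pages$text[pages$page_id == hits$page_id[j]]
      for (t in terms) {
        txt <- gsub(paste0("\\b(", t, ")\\b"), "**\\1**", txt, ignore.case = TRUE)
      }
      lines <- c(lines,
                 sprintf("### Rank %d: %s (score %.3f)", hits$rank[j],
                         hits$page_id[j], hits$score[j]),
                 "", txt, "")
    }
  }
  writeLines(lines, path)
  invisible(path)
}
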