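#' Default category vocabulary banks
#'
#' One word bank per content category, used by the synthetic-forum generator
#' and by the education-page generator. Words are category-exclusive (no word
#' appears in two banks) and disjoint from the shared filler vocabulary, so
#' a category's bank is an unambiguous topical signature: classifiers can be
#' validated for separability and education-page coverage can be defined as
#' presence of bank words. "previous" has no bank: referential sentences are
#' realised from referring cues and fillers only.
#'
#' @return Named list of character vectors.
#' @export
default_vocab_banks <- function() {
  list(
    medical = c("chemo", "radiation", "taxol", "mastectomy", "lumpectomy",
                "tumor", "biopsy", "mammogram", "oncologist", "diagnosis",
                "herceptin", "tamoxifen", "surgery", "recurrence", "reconstruction"),
    resource = c("website", "book", "brochure", "pamphlet", "article",
                 "research", "library", "video", "podcast", "newsletter",
                 "guide", "handbook"),
    social = c("hugs", "congratulations", "greetings", "blessings", "wishes",
               "warmly", "cheers", "dearest", "lovely", "kindly",
               "prayers", "strength"),
    psychological = c("scared", "anxious", "depressed", "crying", "fear",
                      "overwhelmed", "panic", "worry", "sadness", "grief",
                      "mood", "nerves"),
    background = c("retired", "teacher", "hometown", "grandchildren", "married",
                   "birthday", "anniversary", "career", "garden", "church",
                   "cousin", "neighbor"),
    wellness = c("exercise", "diet", "vitamins", "nutrition", "yoga",
                 "walking", "hydration", "supplements", "smoothie", "fiber",
                 "stretching", "mindfulness"),
    physical = c("pain", "swelling", "fatigue", "numbness", "soreness",
                 "rash", "nausea", "tingling", "headache", "lymphedema",
                 "hair", "dizziness"),
    other = c("insurance", "travel", "weather", "recipe", "taxes", "vacation",
              "parking", "traffic", "holiday", "shopping", "paperwork",
              "landlord")
  )
}

# Shared filler vocabulary: topic-neutral words that appear in sentences of
# every category and in education pages. Deliberately includes a few cue-like
# function words (i, it, this, that, was) so rule induction sees realistic
# near-miss negatives.
#' @noRd
filler_words <- function() {
  c("the", "and", "a", "to", "of", "in", "for", "on", "with", "at", "so",
    "but", "i", "my", "me", "it", "was", "this", "that", "really", "very",
    "today", "again", "still", "maybe", "little", "found", "started", "told",
    "went", "came", "took", "long", "short", "new", "old", "good", "time",
    "day", "week", "month", "year", "thing", "things", "way", "bit", "lot",
    "sure", "soon", "later", "around", "home", "place", "people",
    "everything", "something", "always", "never", "often", "sometimes",
    "last", "first", "next", "since", "after", "before", "because", "about")
}

#' @noRd
referring_cues <- function() c("this", "that", "it")

#' @noRd
hasn_templates <- function() {
  list(
    wh = list(c("how", "do", "i"),
              c("what", "should", "i", "do", "about"),
              c("does", "anyone", "know", "about"),
              c("can", "anyone", "tell", "me", "about"),
              c("where", "can", "i", "find"),
              c("how", "long", "does"),
              c("what", "is", "the", "best")),
    indirect = list(c("i", "was", "wondering", "about"),
                    c("i", "am", "concerned", "about"),
                    c("i", "was", "wanting", "to", "know", "about"),
                    c("i", "wonder", "if"),
                    c("i", "am", "having", "trouble", "with")),
    previous = list(c("any", "answers", "out", "there"),
                    c("anyone", "else", "have", "this"),
                    c("does", "anyone", "know", "about", "this"),
                    c("what", "about", "that"),
                    c("has", "anyone", "tried", "it"))
  )
}

#' Synthetic-forum generator configuration
#'
#' Length distributions are truncated rounded normals (minimum 1).
#' `category_mixture` must sum to 1; each generated sentence draws its
#' primary category from it. `hasn_rate_by_category` gives the probability
#' that a sentence of each category expresses an information need.
#' `previous_follow_rate` is the probability that a "previous"-category
#' sentence immediately following a need sentence is itself a need
#' restatement (the duplicate pattern removed during query construction).
#' In the CSN dialect a sentence gains a second category label with
#' probability `second_label_rate`.
#'
#' @param seed Integer RNG seed.
#' @param n_conversations Number of conversations.
#' @param posts_per_conversation,sentences_per_post,words_per_sentence
#'   Numeric `c(mean, sd)` pairs for the truncated normal lengths.
#' @param category_mixture Named probability vector over categories.
#' @param hasn_rate_by_category Named probability vector over categories.
#' @param previous_follow_rate Probability in `[0, 1]`.
#' @param second_label_rate Probability in `[0, 1]` (CSN only).
#' @param label_autocorrelation Probability in `[0, 1]` that a sentence
#'   repeats the category of the preceding sentence in its post instead of
#'   drawing fresh from the mixture. The marginal category distribution is
#'   unchanged for any value; positive values create the topical runs that
#'   make neighbour-label context informative. Default 0 (independent
#'   draws), which keeps the mixture contract exact.
#' @param dialect `"MC"` or `"CSN"`.
#' @param vocab_banks Named list of category word banks.
#' @return A `needgap_forum_config` list.
#' @export
forum_config <- function(seed = 1L,
                         n_conversations = 65L,
                         posts_per_conversation = c(4.71, 2.5),
                         sentences_per_post = c(6.35, 4.42),
                         words_per_sentence = c(14.04, 6.30),
                         category_mixture = NULL,
                         hasn_rate_by_category = NULL,
                         previous_follow_rate = 0.3,
                         second_label_rate = 0,
                         label_autocorrelation = 0,
                         dialect = c("MC", "CSN"),
                         vocab_banks = default_vocab_banks()) {
  dialect <- match.arg(dialect)
  if (is.null(category_mixture)) {
    category_mixture <- mc_category_mixture()
  }
  if (is.null(hasn_rate_by_category)) {
    hasn_rate_by_category <- mc_hasn_rates()[names(category_mixture)]
    hasn_rate_by_category[is.na(hasn_rate_by_category)] <- 0
    names(hasn_rate_by_category) <- names(category_mixture)
  }
  if (abs(sum(category_mixture) - 1) > 1e-9) {
    stop("category_mixture must sum to 1 (got ", sum(category_mixture), ")")
  }
  probs <- c(category_mixture, hasn_rate_by_category, previous_follow_rate,
             second_label_rate, label_autocorrelation)
  if (any(probs < 0 | probs > 1)) stop("all probabilities must lie in [0, 1]")
  admissible <- category_levels(dialect)
  bad <- setdiff(names(category_mixture), admissible)
  if (length(bad) > 0) {
    stop("category_mixture names inadmissible for dialect ", dialect, ": ",
         paste(bad, collapse = ", "))
  }
  structure(list(seed = as.integer(seed),
                 n_conversations = as.integer(n_conversations),
                 posts_per_conversation = posts_per_conversation,
                 sentences_per_post = sentences_per_post,
                 words_per_sentence = words_per_sentence,
                 category_mixture = category_mixture,
                 hasn_rate_by_category = hasn_rate_by_category,
                 previous_follow_rate = previous_follow_rate,
                 second_label_rate = second_label_rate,
                 label_autocorrelation = label_autocorrelation,
                 dialect = dialect,
                 vocab_banks = vocab_banks),
            class = "needgap_forum_config")
}

# Category mixture and per-category need rates of the MC study corpus
# (counts per category over 1943 sentences; the printed per-category counts
# sum to 1942 through rounding, so the vector is renormalised).
#' @noRd
mc_category_mixture <- function() {
  counts <- c(medical = 597, resource = 87, social = 353, psychological = 61,
              background = 69, wellness = 88, physical = 167, previous = 147,
              other = 313, multiple = 60)
  counts / sum(counts)
}

#' @noRd
mc_hasn_rates <- function() {
  hasn <- c(medical = 34, resource = 9, social = 0, psychological = 0,
            background = 0, wellness = 3, physical = 18, previous = 38,
            other = 8, multiple = 0)
  counts <- c(medical = 597, resource = 87, social = 353, psychological = 61,
              background = 69, wellness = 88, physical = 167, previous = 147,
              other = 313, multiple = 60)
  hasn / counts
}

#' @noRd
csn_category_mixture <- function() {
  counts <- c(medical = 473, resource = 32, social = 443, psychological = 63,
              background = 38, wellness = 78, physical = 193, previous = 425,
              other = 728)
  counts / sum(counts)
}

#' @noRd
csn_hasn_rates <- function() {
  hasn <- c(medical = 48, resource = 9, social = 9, psychological = 5,
            background = 0, wellness = 5, physical = 15, previous = 81,
            other = 24)
  counts <- c(medical = 473, resource = 32, social = 443, psychological = 63,
              background = 38, wellness = 78, physical = 193, previous = 425,
              other = 728)
  hasn / counts
}

#' Study-profile generator configurations
#'
#' `mc_profile()` reproduces the descriptive profile of the MayoConnect
#' corpus: 65 conversations, 6.35 (SD 4.42) sentences per post, 14.04
#' (SD 6.30) words per sentence, the published category mixture, and
#' per-category need rates that combine to an overall need prevalence near
#' 5.7%. `csn_profile()` reproduces the Cancer Survivors Network profile:
#' 11.52 (SD 5.29) sentences per post, 13.97 (SD 5.30) words per sentence,
#' up to two labels per sentence, and an overall need prevalence near 8.7%.
#'
#' @param seed Integer RNG seed.
#' @param n_conversations Number of conversations to generate.
#' @return A `needgap_forum_config`.
#' @export
mc_profile <- function(seed = 1L, n_conversations = 65L) {
  forum_config(seed = seed,
               n_conversations = n_conversations,
               posts_per_conversation = c(4.71, 2.5),
               sentences_per_post = c(6.35, 4.42),
               words_per_sentence = c(14.04, 6.30),
               category_mixture = mc_category_mixture(),
               hasn_rate_by_category = mc_hasn_rates(),
               dialect = "MC")
}

#' @rdname mc_profile
#' @export
csn_profile <- function(seed = 1L, n_conversations = 92L) {
  forum_config(seed = seed,
               n_conversations = n_conversations,
               posts_per_conversation = c(2.0, 1.0),
               sentences_per_post = c(11.52, 5.29),
               words_per_sentence = c(13.97, 5.30),
               category_mixture = csn_category_mixture(),
               hasn_rate_by_category = csn_hasn_rates(),
               second_label_rate = 0.10,
               dialect = "CSN")
}

# truncated rounded normal draw, minimum 1
#' @noRd
rlen <- function(n, dist) pmax(1L, as.integer(round(stats::rnorm(n, dist[1], dist[2]))))

#' Generate a labelled synthetic forum corpus
#'
#' Sentences are realised from templates: a category draw from the mixture
#' selects a word bank; need sentences open with either a wh-question or an
#' indirect statement cue ("i was wondering about ...") with equal
#' probability; referential ("previous") sentences contain a referring cue
#' (this/that/it) and no category-exclusive word. Authors rotate round-robin
#' within a conversation. The same seed yields a byte-identical corpus.
#'
#' @param config A `needgap_forum_config`.
#' @return A `needgap_corpus` carrying gold `categories` and `hasn` labels.
#' @export
generate_corpus <- function(config) {
  stopifnot(inherits(config, "needgap_forum_config"))
  set.seed(config$seed)
  mix <- config$category_mixture
  rates <- config$hasn_rate_by_category
  banks <- config$vocab_banks
  fill <- filler_words()
  tpl <- hasn_templates()
  rows <- vector("list", 4096L)
  nrow_used <- 0L
  for (ci in seq_len(config$n_conversations)) {
    cid <- sprintf("c%03d", ci)
    n_posts <- rlen(1L, config$posts_per_conversation)
    authors <- sprintf("user%02d", seq_len(max(2L, min(4L, n_posts))))
    for (pi in seq_len(n_posts)) {
      pid <- sprintf("p%02d", pi)
      author <- authors[((pi - 1L) %% length(authors)) + 1L]
      n_sent <- rlen(1L, config$sentences_per_post)
      prev_hasn <- FALSE
      prev_category <- NULL
      for (si in seq_len(n_sent)) {
        len <- rlen(1L, config$words_per_sentence)
        if (config$label_autocorrelation > 0 && !is.null(prev_category) &&
            stats::runif(1) < config$label_autocorrelation) {
          category <- prev_category
        } else {
          category <- sample(names(mix), 1L, prob = mix)
        }
        if (category == "previous") {
          hasn <- if (prev_hasn) {
            stats::runif(1) < config$previous_follow_rate
          } else {
            stats::runif(1) < rates[["previous"]]
          }
        } else {
          hasn <- stats::runif(1) < rates[[category]]
        }
        cats <- category
        if (config$dialect == "CSN" && category != "previous" &&
            stats::runif(1) < config$second_label_rate) {
          second <- sample(setdiff(names(mix), c(category, "previous")), 1L)
          cats <- c(category, second)
        }
        toks <- realise_sentence(category, cats, hasn, len, banks, fill, tpl)
        text <- render_text(toks$tokens, toks$question)
        nrow_used <- nrow_used + 1L
        if (nrow_used > length(rows)) rows <- c(rows, vector("list", length(rows)))
        rows[[nrow_used]] <- list(conversation_id = cid, post_id = pid,
                                  author = author, post_order = pi - 1L,
                                  index_in_post = si - 1L, text = text,
                                  categories = cats, hasn = hasn)
        prev_hasn <- hasn
        prev_category <- category
      }
    }
  }
  rows <- rows[seq_len(nrow_used)]
  sentences <- tibble::tibble(
    conversation_id = vapply(rows, `[[`, "", "conversation_id"),
    post_id = vapply(rows, `[[`, "", "post_id"),
    author = vapply(rows, `[[`, "", "author"),
    post_order = vapply(rows, `[[`, 0L, "post_order"),
    index_in_post = vapply(rows, `[[`, 0L, "index_in_post"),
    text = vapply(rows, `[[`, "", "text"),
    categories = lapply(rows, `[[`, "categories"),
    hasn = vapply(rows, `[[`, TRUE, "hasn"))
  new_corpus(sentences, dialect = config$dialect,
             provenance = sprintf("synthetic (%s profile, seed %d)",
                                  config$dialect, config$seed))
}

# Assemble the token sequence of one sentence. Referential sentences draw no
# bank word and always carry a referring cue; all other sentences draw about
# a third of their tokens from the bank(s) of their label(s).
#' @noRd
realise_sentence <- function(category, cats, hasn, len, banks, fill, tpl) {
  question <- FALSE
  prefix <- character(0)
  if (hasn) {
    if (category == "previous") {
      prefix <- tpl$previous[[sample.int(length(tpl$previous), 1L)]]
      question <- TRUE
    } else if (stats::runif(1) < 0.5) {
      prefix <- tpl$wh[[sample.int(length(tpl$wh), 1L)]]
      question <- TRUE
    } else {
      prefix <- tpl$indirect[[sample.int(length(tpl$indirect), 1L)]]
    }
  }
  body_len <- max(len - length(prefix), 2L)
  if (category == "previous") {
    body <- sample(fill, body_len, replace = TRUE)
    if (!any(body %in% referring_cues()) && !any(prefix %in% referring_cues())) {
      body[sample.int(body_len, 1L)] <- sample(referring_cues(), 1L)
    }
  } else {
    pool_cats <- setdiff(cats, "previous")
    if (category == "multiple") {
      pool_cats <- sample(setdiff(names(banks), "social"), 2L)
    }
    bank <- unlist(banks[pool_cats], use.names = FALSE)
    n_bank <- max(1L, round(0.35 * body_len))
    n_bank <- min(n_bank, body_len)
    body <- c(sample(bank, n_bank, replace = TRUE),
              sample(fill, body_len - n_bank, replace = TRUE))
    body <- body[sample.int(body_len)]
  }
  list(tokens = c(prefix, body), question = question)
}

#' @noRd
render_text <- function(tokens, question) {
  text <- paste(tokens, collapse = " ")
  substring(text, 1, 1) <- toupper(substring(text, 1, 1))
  paste0(text, if (question) "?" else ".")
}

#' Education-page generator configuration
#'
#' @param seed Integer RNG seed.
#' @param n_pages Number of pages to generate.
#' @param words_per_page Tokens per page.
#' @param coverage_fraction Fraction `c` in `[0, 1]` of need topics planted in
#'   at least one page; exactly `round(c * n_topics)` topics are covered and
#'   the remaining topics appear in no page.
#' @return A `needgap_education_config` list.
#' @export
education_config <- function(seed = 1L, n_pages = 16L, words_per_page = 150L,
                             coverage_fraction = 1) {
  if (coverage_fraction < 0 || coverage_fraction > 1) {
    stop("coverage_fraction must lie in [0, 1]")
  }
  structure(list(seed = as.integer(seed), n_pages = as.integer(n_pages),
                 words_per_page = as.integer(words_per_page),
                 coverage_fraction = coverage_fraction),
            class = "needgap_education_config")
}

#' Generate synthetic education pages with controlled topic coverage
#'
#' Topics are the content categories of `vocab_banks`. A covered topic owns
#' one or more pages in which roughly a third of the tokens come from its
#' (category-exclusive) bank — at least 3 bank words per page — and the
#' remaining tokens are shared fillers; uncovered topics appear in no page.
#' The emitted `gold_coverage` maps each covered topic to its page ids.
#'
#' @param config A `needgap_education_config`.
#' @param vocab_banks Named list of category word banks (share these with the
#'   forum generator so coverage is meaningful).
#' @param dir Optional directory: pages written as `<page_id>.txt`, gold
#'   coverage as `gold_coverage.csv`.
#' @return List with `pages` (tibble `page_id`, `text`), `gold_coverage`
#'   (named list topic -> page ids), `topics`, `covered_topics`.
#' @export
generate_education_pages <- function(config, vocab_banks = default_vocab_banks(),
                                     dir = NULL) {
  stopifnot(inherits(config, "needgap_education_config"))
  set.seed(config$seed)
  topics <- names(vocab_banks)
  n_cov <- round(config$coverage_fraction * length(topics))
  covered <- sort(sample(topics, n_cov))
  if (config$n_pages < n_cov) {
    stop("n_pages (", config$n_pages, ") is smaller than the number of covered topics (",
         n_cov, ")")
  }
  fill <- filler_words()
  page_topic <- rep(NA_character_, config$n_pages)
  if (n_cov > 0) {
    page_topic[seq_len(n_cov)] <- covered
    extra <- which(is.na(page_topic))
    if (length(extra) > 0) {
      # half the remaining pages get a covered topic too, rest are filler-only
      n_extra <- floor(length(extra) / 2)
      if (n_extra > 0) {
        page_topic[extra[seq_len(n_extra)]] <- sample(covered, n_extra, replace = TRUE)
      }
    }
  }
  texts <- character(config$n_pages)
  for (i in seq_len(config$n_pages)) {
    L <- config$words_per_page
    if (is.na(page_topic[i])) {
      toks <- sample(fill, L, replace = TRUE)
    } else {
      bank <- vocab_banks[[page_topic[i]]]
      n_bank <- max(3L, round(0.3 * L))
      toks <- c(sample(bank, n_bank, replace = TRUE),
                sample(fill, L - n_bank, replace = TRUE))
      toks <- toks[sample.int(L)]
    }
    texts[i] <- paste(toks, collapse = " ")
  }
  page_id <- sprintf("page%03d", seq_len(config$n_pages))
  gold <- lapply(stats::setNames(covered, covered),
                 function(t) page_id[!is.na(page_topic) & page_topic == t])
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    for (i in seq_along(page_id)) {
      writeLines(texts[i], file.path(dir, paste0(page_id[i], ".txt")))
    }
    gold_df <- data.frame(
      topic = rep(names(gold), lengths(gold)),
      page_id = unlist(gold, use.names = FALSE))
    utils::write.csv(gold_df, file.path(dir, "gold_coverage.csv"), row.names = FALSE)
  }
  list(pages = tibble::tibble(page_id = page_id, text = texts),
       gold_coverage = gold, topics = topics, covered_topics = covered)
}

#' Simulated-rater configuration
#'
#' @param seed Integer RNG seed.
#' @param n_raters Number of independent raters (default 2).
#' @param sensitivity Probability a rater marks a truly covering page
#'   relevant.
#' @param false_positive_rate Probability a rater marks a non-covering page
#'   relevant.
#' @return A `needgap_rater_config` list.
#' @export
rater_config <- function(seed = 1L, n_raters = 2L, sensitivity = 1,
                         false_positive_rate = 0) {
  if (any(c(sensitivity, false_positive_rate) < 0) ||
      any(c(sensitivity, false_positive_rate) > 1)) {
    stop("sensitivity and false_positive_rate must lie in [0, 1]")
  }
  structure(list(seed = as.integer(seed), n_raters = as.integer(n_raters),
                 sensitivity = sensitivity,
                 false_positive_rate = false_positive_rate),
            class = "needgap_rater_config")
}

#' Simulate rater verdicts over retrieval results
#'
#' Each rater independently marks each retrieved (query, page) document
#' relevant with probability `sensitivity` if the page truly covers the
#' query's gold topic (per `gold_coverage`) and with probability
#' `false_positive_rate` otherwise.
#'
#' @param results Retrieval results tibble (`query_id`, `page_id`, ...).
#' @param queries Query tibble with `query_id` and gold `topic`.
#' @param gold_coverage Named list topic -> covering page ids, from
#'   [generate_education_pages()].
#' @param config A `needgap_rater_config`.
#' @return A rating table tibble: `query_id`, `page_id`, `rater_id`,
#'   `relevant`.
#' @export
simulate_raters <- function(results, queries, gold_coverage, config) {
  stopifnot(inherits(config, "needgap_rater_config"))
  set.seed(config$seed)
  topic_of <- stats::setNames(queries$topic, queries$query_id)
  unknown <- setdiff(results$query_id, queries$query_id)
  if (length(unknown) > 0) {
    stop("results reference unknown query id(s): ",
         paste(utils::head(unknown, 5), collapse = ", "))
  }
  truth <- mapply(function(q, p) {
    t <- topic_of[[q]]
    !is.na(t) && t %in% names(gold_coverage) && p %in% gold_coverage[[t]]
  }, results$query_id, results$page_id)
  out <- list()
  for (r in seq_len(config$n_raters)) {
    prob <- ifelse(truth, config$sensitivity, config$false_positive_rate)
    out[[r]] <- tibble::tibble(
      query_id = results$query_id,
      page_id = results$page_id,
      rater_id = sprintf("rater%d", r),
      relevant = unname(stats::runif(length(prob)) < prob))
  }
  dplyr::bind_rows(out)
}

# Derive independent sub-stream seeds (corpus, pages, raters) from one
# master seed, keeping results within 32-bit integer range.
#' @noRd
substream_seeds <- function(seed) {
  base <- as.integer(seed) %% 1000000L
  c(corpus = base * 3L + 1L, pages = base * 3L + 2L, raters = base * 3L + 3L)
}
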