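#' Question-cue vocabulary
#'
#' The cue vocabulary V from which need-detection bigram patterns are
#' induced: wh-words, auxiliary verbs, pronouns, and words associated with
#' direct or indirect requests for information (wondering, wanting, trouble,
#' anyone, similar, advice, ...). The packaged default has ~75 words; supply
#' `words` to override.
#'
#' @param words Optional character vector replacing the packaged default.
#' @return A `needgap_cue_vocabulary` (character vector, lowercased, unique).
#' @export
cue_vocabulary <- function(words = NULL) {
  if (is.null(words)) {
    path <- system.file("extdata", "cue_vocabulary.txt", package = "needgap")
    words <- read_word_list(path)
  }
  words <- unique(tolower(trimws(words)))
  words <- words[nzchar(words)]
  if (length(words) == 0L) stop("cue vocabulary must be non-empty")
  structure(words, class = c("needgap_cue_vocabulary", "character"))
}

#' Candidate cue bigrams of a sentence
#'
#' The adjacent token pairs whose both members are in the cue vocabulary,
#' ordered by first occurrence position in the sentence (duplicates removed).
#'
#' @param tokens Character token vector (or a list-corpus sentence's tokens).
#' @param v A cue vocabulary from [cue_vocabulary()].
#' @return Character vector of space-joined bigrams.
#' @export
candidate_bigrams <- function(tokens, v) {
  bg <- bigrams(tokens)
  if (length(bg) == 0L) return(character(0))
  n <- length(tokens)
  keep <- tokens[-n] %in% v & tokens[-1L] %in% v
  unique(bg[keep])
}

#' Induce minimal bigram-pattern rules for need detection
#'
#' Iterates positive examples in input order. A positive already matched by
#' an accepted pattern is skipped. For an unmatched positive, subsets of its
#' candidate cue bigrams are searched in order of increasing size (within a
#' size, lexicographically over bigrams ordered by sentence position, up to
#' `max_size`); the first subset contained in the positive but in no
#' negative example is accepted as a pattern. Positives for which no such
#' subset exists are recorded as unseparable. By construction no accepted
#' pattern matches any negative training example.
#'
#' @param positives,negatives Lists of token vectors, or tibbles with
#'   `tokens` (and optionally `sentence_id`) columns as in a corpus.
#' @param v A cue vocabulary.
#' @param max_size Maximum pattern cardinality (default 4; larger patterns
#'   overfit and explode the search).
#' @return A `needgap_ruleset`: `patterns` (list of `list(bigrams,
#'   source_example_id)`), `unseparable` (example ids), `vocabulary`.
#' @export
induce_patterns <- function(positives, negatives, v = cue_vocabulary(),
                            max_size = 4L) {
  pos <- as_token_examples(positives, "pos")
  neg <- as_token_examples(negatives, "neg")
  if (length(intersect(pos$ids, neg$ids)) > 0) {
    stop("positive and negative example ids overlap")
  }
  neg_sets <- lapply(neg$tokens, function(t) unique(bigrams(t)))
  patterns <- list()
  unseparable <- character(0)
  for (i in seq_along(pos$tokens)) {
    toks <- pos$tokens[[i]]
    sent_bg <- unique(bigrams(toks))
    if (any(vapply(patterns, function(p) all(p$bigrams %in% sent_bg), TRUE))) next
    cand <- candidate_bigrams(toks, v)
    found <- find_separating_subset(cand, neg_sets, max_size)
    if (is.null(found)) {
      unseparable <- c(unseparable, pos$ids[i])
    } else {
      patterns[[length(patterns) + 1L]] <-
        list(bigrams = found, source_example_id = pos$ids[i])
    }
  }
  structure(list(patterns = patterns, unseparable = unseparable,
                 vocabulary = as.character(v), max_size = as.integer(max_size)),
            class = "needgap_ruleset")
}

# Smallest subset of `cand` (position order preserved; increasing size, then
# lexicographic over position indices) contained in no negative bigram set.
#' @noRd
find_separating_subset <- function(cand, neg_sets, max_size) {
  n <- length(cand)
  if (n == 0L) return(NULL)
  for (size in seq_len(min(n, max_size))) {
    combs <- utils::combn(n, size)
    for (j in seq_len(ncol(combs))) {
      s <- cand[combs[, j]]
      hit <- any(vapply(neg_sets, function(nb) all(s %in% nb), TRUE))
      if (!hit) return(s)
    }
  }
  NULL
}

#' @noRd
as_token_examples <- function(x, prefix) {
  if (is.data.frame(x)) {
    ids <- if ("sentence_id" %in% names(x)) x$sentence_id
           else paste0(prefix, seq_len(nrow(x)))
    list(tokens = x$tokens, ids = ids)
  } else if (inherits(x, "needgap_corpus")) {
    s <- corpus_sentences(x)
    list(tokens = s$tokens, ids = s$sentence_id)
  } else {
    ids <- names(x)
    if (is.null(ids)) ids <- paste0(prefix, seq_along(x))
    list(tokens = x, ids = ids)
  }
}

#' Match a ruleset against a sentence
#'
#' @param ruleset A `needgap_ruleset`.
#' @param tokens Character token vector.
#' @return `TRUE` iff some pattern's every bigram occurs among the
#'   sentence's adjacent token pairs; an empty ruleset never matches.
#' @export
match_ruleset <- function(ruleset, tokens) {
  stopifnot(inherits(ruleset, "needgap_ruleset"))
  if (length(ruleset$patterns) == 0L) return(FALSE)
  sent_bg <- unique(bigrams(tokens))
  any(vapply(ruleset$patterns, function(p) all(p$bigrams %in% sent_bg), TRUE))
}

#' @rdname match_ruleset
#' @param corpus A `needgap_corpus` or tibble with a `tokens` column.
#' @return `match_all()`: logical vector over sentences in corpus order.
#' @export
match_all <- function(ruleset, corpus) {
  toks <- if (inherits(corpus, "needgap_corpus")) corpus_sentences(corpus)$tokens
          else corpus$tokens
  vapply(toks, function(t) match_ruleset(ruleset, t), TRUE)
}

#' @export
print.needgap_ruleset <- function(x, ...) {
  cat("<needgap_ruleset>", length(x$patterns), "patterns,",
      length(x$unseparable), "unseparable example(s)\n")
  for (p in utils::head(x$patterns, 10)) {
    cat("  {", paste(p$bigrams, collapse = ", "), "} from", p$source_example_id, "\n")
  }
  if (length(x$patterns) > 10) cat("  ...\n")
  invisible(x)
}

#' Serialize / read a ruleset as JSON
#'
#' @param ruleset A `needgap_ruleset`.
#' @param path File path.
#' @return `write_ruleset()`: `path` invisibly; `read_ruleset()`: the
#'   ruleset.
#' @export
write_ruleset <- function(ruleset, path) {
  stopifnot(inherits(ruleset, "needgap_ruleset"))
  jsonlite::write_json(
    list(patterns = lapply(ruleset$patterns, function(p)
           list(bigrams = as.list(p$bigrams),
                source_example_id = p$source_example_id)),
         unseparable = as.list(ruleset$unseparable),
         vocabulary = as.list(ruleset$vocabulary),
         max_size = ruleset$max_size),
    path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname write_ruleset
#' @export
read_ruleset <- function(path) {
  x <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  structure(list(
    patterns = lapply(x$patterns, function(p)
      list(bigrams = as.character(unlist(p$bigrams)),
           source_example_id = p$source_example_id)),
    unseparable = as.character(unlist(x$unseparable)),
    vocabulary = as.character(unlist(x$vocabulary)),
    max_size = as.integer(x$max_size)),
    class = "needgap_ruleset")
}

#' Binary precision, recall and F-measure
#'
#' Standard positive-class definitions with F = 2PR / (P + R). A zero
#' denominator (no predicted positives for precision, no gold positives for
#' recall) reports the metric as 0 and sets the corresponding warning flag.
#'
#' @param predicted,gold Logical vectors of equal length.
#' @return A list: `precision`, `recall`, `f`, counts `tp`/`fp`/`fn`/`tn`,
#'   and `undefined` (character vector naming any zero-denominator metrics).
#' @export
evaluate_binary <- function(predicted, gold) {
  if (length(predicted) != length(gold)) {
    stop("predicted and gold must have equal length (",
         length(predicted), " vs ", length(gold), ")")
  }
  predicted <- as.logical(predicted); gold <- as.logical(gold)
  prf_counts(tp = sum(predicted & gold), fp = sum(predicted & !gold),
             fn = sum(!predicted & gold), tn = sum(!predicted & !gold))
}

#' @rdname evaluate_binary
#' @param tp,fp,fn,tn Confusion counts.
#' @export
prf_counts <- function(tp, fp, fn, tn = 0L) {
  undefined <- character(0)
  if (tp + fp == 0) { precision <- 0; undefined <- c(undefined, "precision") }
  else precision <- tp / (tp + fp)
  if (tp + fn == 0) { recall <- 0; undefined <- c(undefined, "recall") }
  else recall <- tp / (tp + fn)
  f <- if (precision + recall == 0) 0 else 2 * precision * recall / (precision + recall)
  list(precision = precision, recall = recall, f = f,
       tp = tp, fp = fp, fn = fn, tn = tn, undefined = undefined)
}
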