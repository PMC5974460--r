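#' Information-category taxonomy
#'
#' The ten admissible information categories for forum sentences. Seven are
#' content types (medical, resource, social, psychological, background,
#' wellness, physical); "previous" marks sentences whose topic requires
#' resolving a reference to an earlier sentence; "other" is the catch-all;
#' "multiple" is admissible only in the MC annotation dialect, where a single
#' label was used for sentences spanning several categories (the CSN dialect
#' instead allows up to two labels per sentence).
#'
#' @param dialect Annotation dialect, `"MC"` or `"CSN"`.
#' @return Character vector of admissible category names.
#' @export
category_levels <- function(dialect = c("MC", "CSN")) {
  dialect <- match.arg(dialect)
  base <- c("medical", "resource", "social", "psychological", "background",
            "wellness", "physical", "previous", "other")
  if (dialect == "MC") c(base, "multiple") else base
}

#' Tokenize forum text
#'
#' Lowercases, splits on whitespace, and strips leading/trailing punctuation
#' from each token while keeping internal apostrophes and hyphens (so
#' "don't" and "self-esteem" survive intact). Deterministic; empty input
#' yields an empty token vector.
#'
#' @param text A single character string (NA treated as empty).
#' @return Character vector of tokens.
#' @examples
#' tokenize("Hi to all!")
#' @export
tokenize <- function(text) {
  stopifnot(length(text) == 1L)
  if (is.na(text) || !nzchar(text)) return(character(0))
  toks <- strsplit(tolower(text), "\\s+")[[1]]
  toks <- gsub("^[^a-z0-9]+|[^a-z0-9]+$", "", toks)
  toks[nzchar(toks)]
}

#' @rdname tokenize
#' @param texts Character vector.
#' @return `tokenize_all()`: list of token vectors, one per input string.
#' @export
tokenize_all <- function(texts) lapply(as.character(texts), tokenize)

#' Adjacent-token bigrams
#'
#' Bigrams are represented throughout the package as single space-joined
#' strings (`"how do"`), which keeps pattern sets and JSON serialisation
#' simple.
#'
#' @param tokens Character vector of tokens.
#' @return Character vector of length `max(0, length(tokens) - 1)`,
#'   order-preserving.
#' @examples
#' bigrams(c("how", "do", "i"))
#' @export
bigrams <- function(tokens) {
  n <- length(tokens)
  if (n < 2L) return(character(0))
  paste(tokens[-n], tokens[-1L])
}

#' Default abbreviation list for sentence segmentation
#'
#' @return Character vector of lowercased abbreviations ending in a period.
#' @export
default_abbreviations <- function() {
  path <- system.file("extdata", "abbreviations.txt", package = "needgap")
  read_word_list(path)
}

# Read a newline-delimited word list, skipping blank and '#' comment lines.
#' @noRd
read_word_list <- function(path) {
  x <- readLines(path, warn = FALSE, encoding = "UTF-8")
  x <- trimws(x)
  tolower(x[nzchar(x) & !startsWith(x, "#")])
}

#' Split a post into sentence-type units
#'
#' Rule-based splitter: sentence boundaries are runs of `.`, `!` or `?`
#' followed by whitespace or end of text, and newlines. A period that closes
#' a known abbreviation ("Dr.", "e.g.") is not a boundary, and a period with
#' no following whitespace (as in "3.5") never triggers one. Delimiters are
#' retained with their sentence, so concatenating the returned units (modulo
#' whitespace) recovers the input.
#'
#' @param raw_text Raw post text (may be empty).
#' @param abbreviations Character vector of abbreviation tokens (with their
#'   trailing period); defaults to the packaged list.
#' @return Character vector of sentence strings (empty input gives
#'   `character(0)`).
#' @export
segment_post <- function(raw_text, abbreviations = default_abbreviations()) {
  stopifnot(length(raw_text) == 1L)
  if (is.na(raw_text) || !nzchar(trimws(raw_text))) return(character(0))
  lines <- strsplit(raw_text, "\n", fixed = TRUE)[[1]]
  out <- character(0)
  for (line in lines) {
    out <- c(out, segment_line(line, abbreviations))
  }
  out
}

#' @noRd
segment_line <- function(line, abbreviations) {
  if (!nzchar(trimws(line))) return(character(0))
  m <- gregexpr("[.!?]+(?=\\s|$)", line, perl = TRUE)[[1]]
  if (m[1] == -1L) return(trimws(line))
  ends <- as.integer(m) + attr(m, "match.length") - 1L
  keep <- logical(length(ends))
  for (j in seq_along(ends)) {
    punct <- substring(line, m[j], ends[j])
    if (punct == ".") {
      # find the word ending at this period, including the period itself
      start <- m[j]
      while (start > 1L && !grepl("\\s", substring(line, start - 1L, start - 1L))) {
        start <- start - 1L
      }
      word <- tolower(substring(line, start, ends[j]))
      if (word %in% abbreviations) next
    }
    keep[j] <- TRUE
  }
  ends <- ends[keep]
  if (length(ends) == 0L) return(trimws(line))
  starts <- c(1L, ends + 1L)
  stops <- c(ends, nchar(line))
  units <- trimws(substring(line, starts, stops))
  units[nzchar(units)]
}

#' Construct a forum corpus
#'
#' A corpus is a flat tibble of sentences plus dialect and provenance
#' metadata. Conversations and posts are implicit in the `conversation_id`,
#' `post_id` and ordering columns; this mirrors how the data are consumed
#' (sentence-level classification with positional context).
#'
#' @param sentences A data frame with columns `conversation_id`, `post_id`,
#'   `author`, `post_order` (0-based), `index_in_post` (0-based), `text`,
#'   `categories` (list of character vectors, 1-2 labels each), `hasn`
#'   (logical). `tokens` and `sentence_id` are (re)computed.
#' @param dialect `"MC"` or `"CSN"`. In the MC dialect every sentence carries
#'   exactly one label ("multiple" marks mixed sentences); in the CSN dialect
#'   up to two labels are allowed and "multiple" is inadmissible.
#' @param provenance Free-text origin string.
#' @return An object of class `needgap_corpus`.
#' @export
new_corpus <- function(sentences, dialect = c("MC", "CSN"), provenance = "unknown") {
  dialect <- match.arg(dialect)
  s <- tibble::as_tibble(sentences)
  required <- c("conversation_id", "post_id", "author", "post_order",
                "index_in_post", "text", "categories", "hasn")
  missing <- setdiff(required, names(s))
  if (length(missing) > 0) {
    stop("corpus sentences are missing columns: ", paste(missing, collapse = ", "))
  }
  s$tokens <- tokenize_all(s$text)
  s$sentence_id <- paste(s$conversation_id, s$post_id, s$index_in_post, sep = ":")
  validate_sentences(s, dialect)
  s <- s[, c("sentence_id", "conversation_id", "post_id", "author",
             "post_order", "index_in_post", "text", "tokens", "categories", "hasn")]
  structure(list(sentences = s, dialect = dialect, provenance = provenance),
            class = "needgap_corpus")
}

#' @noRd
validate_sentences <- function(s, dialect) {
  if (anyDuplicated(s$sentence_id)) {
    stop("duplicate sentence_id values in corpus")
  }
  admissible <- category_levels(dialect)
  nlab <- lengths(s$categories)
  if (any(nlab < 1L | nlab > 2L)) {
    stop("every sentence must carry 1 or 2 category labels")
  }
  if (dialect == "MC" && any(nlab > 1L)) {
    stop("two-label sentences are only admissible in the CSN dialect")
  }
  cats <- unique(unlist(s$categories))
  bad <- setdiff(cats, admissible)
  if (length(bad) > 0) {
    stop("unknown category name(s): ", paste(bad, collapse = ", "))
  }
  # per-post sentence indices must be 0..n-1 with no gaps
  key <- paste(s$conversation_id, s$post_id)
  for (k in unique(key)) {
    idx <- sort(s$index_in_post[key == k])
    if (!identical(idx, seq_along(idx) - 1L)) {
      stop("post ", k, " has gapped or non-0-based sentence indices")
    }
  }
  if (!is.logical(s$hasn) || anyNA(s$hasn)) stop("hasn must be logical, no NA")
  invisible(s)
}

#' @export
print.needgap_corpus <- function(x, ...) {
  cat("<needgap_corpus> dialect:", x$dialect,
      "| conversations:", length(unique(x$sentences$conversation_id)),
      "| sentences:", nrow(x$sentences),
      "| provenance:", x$provenance, "\n")
  invisible(x)
}

#' Sentences of a corpus, in corpus order
#'
#' @param corpus A `needgap_corpus`.
#' @return Tibble of sentences ordered by conversation, post order, index.
#' @export
corpus_sentences <- function(corpus) {
  stopifnot(inherits(corpus, "needgap_corpus"))
  s <- corpus$sentences
  s[order(s$conversation_id, s$post_order, s$index_in_post), ]
}

#' Descriptive statistics of a corpus
#'
#' Means and standard deviations use the sample convention (n-1 denominator);
#' a single observation reports SD 0. Word counts are token counts, and
#' character counts are per token over all tokens in the corpus.
#' `category_fractions` gives each sentence weight 1 for each of its labels
#' with denominator `n_sentences`, so fractions in a two-label (CSN) corpus
#' may sum to more than 1.
#'
#' @param corpus A `needgap_corpus`.
#' @return A `needgap_stats` list: `n_conversations`, `n_posts`,
#'   `n_sentences`, `mean_sentences_per_post`, `sd_sentences_per_post`,
#'   `mean_words_per_sentence`, `sd_words_per_sentence`,
#'   `mean_chars_per_word`, `sd_chars_per_word`, `hasn_fraction`,
#'   `category_fractions`.
#' @export
corpus_stats <- function(corpus) {
  s <- corpus_sentences(corpus)
  if (nrow(s) == 0L) stop("corpus contains no sentences")
  spp <- as.integer(table(paste(s$conversation_id, s$post_id)))
  wps <- lengths(s$tokens)
  chars <- nchar(unlist(s$tokens))
  if (length(chars) == 0L) chars <- 0L
  admissible <- category_levels(corpus$dialect)
  counts <- table(factor(unlist(s$categories), levels = admissible))
  res <- list(
    n_conversations = length(unique(s$conversation_id)),
    n_posts = length(spp),
    n_sentences = nrow(s),
    mean_sentences_per_post = mean(spp),
    sd_sentences_per_post = sd0(spp),
    mean_words_per_sentence = mean(wps),
    sd_words_per_sentence = sd0(wps),
    mean_chars_per_word = mean(chars),
    sd_chars_per_word = sd0(chars),
    hasn_fraction = mean(s$hasn),
    category_fractions = as.numeric(counts) / nrow(s)
  )
  names(res$category_fractions) <- admissible
  structure(res, class = "needgap_stats")
}

# sample SD that reports 0 (not NA) for a single observation
#' @noRd
sd0 <- function(x) {
  if (length(x) < 2L) return(0)
  stats::sd(x)
}

#' @export
print.needgap_stats <- function(x, ...) {
  cat(sprintf("Corpus: %d conversations, %d posts, %d sentences\n",
              x$n_conversations, x$n_posts, x$n_sentences))
  cat(sprintf("Sentences/post: %.2f (SD %.2f)\n",
              x$mean_sentences_per_post, x$sd_sentences_per_post))
  cat(sprintf("Words/sentence: %.2f (SD %.2f)\n",
              x$mean_words_per_sentence, x$sd_words_per_sentence))
  cat(sprintf("Chars/word: %.2f (SD %.2f)\n",
              x$mean_chars_per_word, x$sd_chars_per_word))
  cat(sprintf("HASN prevalence: %.1f%%\n", 100 * x$hasn_fraction))
  cf <- sort(x$category_fractions, decreasing = TRUE)
  cat("Category fractions:",
      paste(sprintf("%s %.1f%%", names(cf), 100 * cf), collapse = ", "), "\n")
  invisible(x)
}
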