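#' Concept lexicon
#'
#' A pluggable surface-term to concept mapping used for concept profiling.
#' Terms are 1-3 lowercased tokens; tagging is greedy longest-match, so
#' "breast cancer" beats "cancer" where both apply. The packaged default is
#' a ~180-entry breast-cancer survivorship lexicon (treatments, symptoms,
#' emotions, resources, daily-living terms); users with access to richer
#' terminologies can supply their own table in the same format.
#'
#' @param path CSV with header `term,concept`; `NULL` loads the packaged
#'   default.
#' @return A `needgap_lexicon` tibble: `term`, `concept`, `n_tokens`.
#' @export
read_lexicon <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "concept_lexicon.csv", package = "needgap")
  }
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("term", "concept") %in% names(x))) {
    stop("lexicon must have columns term, concept")
  }
  x$term <- tolower(trimws(x$term))
  if (any(is.na(x$term) | !nzchar(x$term))) stop("lexicon contains empty terms")
  x <- x[!duplicated(x$term), ]
  x$n_tokens <- lengths(strsplit(x$term, "\\s+"))
  if (any(x$n_tokens > 3L)) stop("lexicon terms are limited to 3 tokens")
  structure(tibble::as_tibble(x), class = c("needgap_lexicon", class(tibble::tibble())))
}

#' Tag concepts in a token sequence
#'
#' Greedy longest-match left-to-right over tokens: at each position the
#' longest lexicon term (up to 3 tokens) starting there is matched, matches
#' do not overlap, and the scan resumes after a match.
#'
#' @param tokens Character token vector.
#' @param lexicon A `needgap_lexicon`.
#' @return Named integer vector of concept occurrence counts (empty when
#'   nothing matches).
#' @export
tag_concepts <- function(tokens, lexicon) {
  max_len <- max(lexicon$n_tokens, 1L)
  lut <- stats::setNames(lexicon$concept, lexicon$term)
  found <- character(0)
  i <- 1L
  n <- length(tokens)
  while (i <= n) {
    matched <- 0L
    for (len in rev(seq_len(min(max_len, n - i + 1L)))) {
      key <- paste(tokens[i:(i + len - 1L)], collapse = " ")
      if (!is.na(lut[key])) {
        found <- c(found, unname(lut[key]))
        matched <- len
        break
      }
    }
    i <- i + max(matched, 1L)
  }
  if (length(found) == 0L) return(integer(0))
  tab <- table(found)
  stats::setNames(as.integer(tab), names(tab))
}

#' Frequency-ranked concepts of a category
#'
#' Concept occurrences are summed over the sentences carrying the category
#' and ranked by decreasing count, ties broken alphabetically.
#'
#' @param corpus A labelled `needgap_corpus`.
#' @param category Category name (must be admissible for the corpus
#'   dialect).
#' @param lexicon A `needgap_lexicon` (packaged default if omitted).
#' @param k Number of concepts to return (default 5; fewer if fewer are
#'   distinct).
#' @return Tibble `rank`, `concept`, `count` (empty for a category with no
#'   sentences).
#' @export
rank_concepts <- function(corpus, category, lexicon = read_lexicon(), k = 5L) {
  admissible <- category_levels(corpus$dialect)
  if (!category %in% admissible) {
    stop("unknown category '", category, "' for dialect ", corpus$dialect)
  }
  s <- corpus_sentences(corpus)
  keep <- vapply(s$categories, function(cc) category %in% cc, TRUE)
  totals <- list()
  for (toks in s$tokens[keep]) {
    cc <- tag_concepts(toks, lexicon)
    for (nm in names(cc)) totals[[nm]] <- (totals[[nm]] %||% 0L) + cc[[nm]]
  }
  if (length(totals) == 0L) {
    return(tibble::tibble(rank = integer(0), concept = character(0),
                          count = integer(0)))
  }
  counts <- unlist(totals)
  ord <- order(-counts, names(counts))
  top <- utils::head(ord, k)
  tibble::tibble(rank = seq_along(top), concept = names(counts)[top],
                 count = as.integer(counts[top]))
}

#' Concept profile across need status and every category
#'
#' @param corpus A labelled `needgap_corpus`.
#' @param lexicon A `needgap_lexicon`.
#' @param k Concepts per stratum.
#' @return Tibble `stratum`, `rank`, `concept`, `count`: the need /
#'   no-need split first, then each admissible category.
#' @export
concept_profile <- function(corpus, lexicon = read_lexicon(), k = 5L) {
  s <- corpus_sentences(corpus)
  strata <- list(
    "information need" = s$hasn,
    "no information need" = !s$hasn)
  for (cat in category_levels(corpus$dialect)) {
    strata[[cat]] <- vapply(s$categories, function(cc) cat %in% cc, TRUE)
  }
  rows <- lapply(names(strata), function(nm) {
    keep <- strata[[nm]]
    totals <- list()
    for (toks in s$tokens[keep]) {
      cc <- tag_concepts(toks, lexicon)
      for (c2 in names(cc)) totals[[c2]] <- (totals[[c2]] %||% 0L) + cc[[c2]]
    }
    if (length(totals) == 0L) return(NULL)
    counts <- unlist(totals)
    ord <- utils::head(order(-counts, names(counts)), k)
    tibble::tibble(stratum = nm, rank = seq_along(ord),
                   concept = names(counts)[ord], count = as.integer(counts[ord]))
  })
  dplyr::bind_rows(rows)
}
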