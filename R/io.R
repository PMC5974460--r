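#' Write a corpus to JSON-lines
#'
#' Line 1 holds corpus-level metadata (format version, dialect, provenance);
#' every following line is one conversation with its ordered posts and
#' sentences. Tokens and sentence ids are not serialised: both are
#' deterministic functions of the text and position and are recomputed on
#' read, which guarantees the recomputability invariant can never drift.
#'
#' @param corpus A `needgap_corpus`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_corpus <- function(corpus, path) {
  stopifnot(inherits(corpus, "needgap_corpus"))
  s <- corpus_sentences(corpus)
  header <- jsonlite::toJSON(
    list(format = "needgap-corpus", version = 1L,
         dialect = corpus$dialect, provenance = corpus$provenance),
    auto_unbox = TRUE)
  lines <- character(0)
  for (cid in unique(s$conversation_id)) {
    sc <- s[s$conversation_id == cid, ]
    posts <- lapply(unique(sc$post_id), function(pid) {
      sp <- sc[sc$post_id == pid, ]
      list(
        post_id = pid,
        author = sp$author[1],
        order = sp$post_order[1],
        sentences = lapply(seq_len(nrow(sp)), function(i) {
          list(index_in_post = sp$index_in_post[i],
               text = sp$text[i],
               categories = as.list(sp$categories[[i]]),
               hasn = sp$hasn[i])
        })
      )
    })
    lines <- c(lines, jsonlite::toJSON(
      list(conversation_id = cid, posts = posts), auto_unbox = TRUE))
  }
  writeLines(c(header, lines), path, useBytes = TRUE)
  invisible(path)
}

#' Read a corpus from JSON-lines
#'
#' @param path Path to a file written by [write_corpus()] (or conforming to
#'   the same dialect). A malformed record raises an error naming the line
#'   number; an unknown category name raises an error naming it.
#' @return A `needgap_corpus`.
#' @export
read_corpus <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  if (length(lines) < 1L) stop("empty corpus file: ", path)
  header <- parse_json_line(lines[1], 1L)
  if (!identical(header$format, "needgap-corpus")) {
    stop("line 1: not a needgap corpus file (missing format header)")
  }
  dialect <- header$dialect
  rows <- list()
  for (i in seq_along(lines)[-1]) {
    conv <- parse_json_line(lines[i], i)
    if (is.null(conv$conversation_id) || is.null(conv$posts)) {
      stop("line ", i, ": conversation record missing conversation_id or posts")
    }
    for (p in conv$posts) {
      if (is.null(p$post_id) || is.null(p$sentences)) {
        stop("line ", i, ": post record missing post_id or sentences")
      }
      for (sn in p$sentences) {
        if (is.null(sn$text) || is.null(sn$categories) || is.null(sn$hasn)) {
          stop("line ", i, ": sentence record missing text, categories or hasn")
        }
        rows[[length(rows) + 1L]] <- tibble::tibble(
          conversation_id = conv$conversation_id,
          post_id = p$post_id,
          author = p$author %||% "unknown",
          post_order = as.integer(p$order %||% 0L),
          index_in_post = as.integer(sn$index_in_post),
          text = sn$text,
          categories = list(as.character(unlist(sn$categories))),
          hasn = isTRUE(sn$hasn))
      }
    }
  }
  if (length(rows) == 0L) stop("corpus file has no conversations: ", path)
  new_corpus(dplyr::bind_rows(rows), dialect = dialect,
             provenance = header$provenance %||% "unknown")
}

#' @noRd
parse_json_line <- function(line, lineno) {
  tryCatch(jsonlite::fromJSON(line, simplifyVector = FALSE),
           error = function(e) stop("line ", lineno, ": malformed JSON record (",
                                    conditionMessage(e), ")", call. = FALSE))
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read an annotation table
#'
#' @param path CSV with header `sentence_id,hasn,category1,category2`
#'   (`category2` may be empty; `hasn` is 0/1 or TRUE/FALSE).
#' @return Tibble with `sentence_id`, `hasn`, `categories` (list column).
#' @export
read_annotations <- function(path) {
  a <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  required <- c("sentence_id", "hasn", "category1")
  missing <- setdiff(required, names(a))
  if (length(missing) > 0) {
    stop("annotation file is missing columns: ", paste(missing, collapse = ", "))
  }
  if (!"category2" %in% names(a)) a$category2 <- ""
  cats <- lapply(seq_len(nrow(a)), function(i) {
    x <- c(a$category1[i], a$category2[i])
    x[nzchar(trimws(x))]
  })
  tibble::tibble(
    sentence_id = a$sentence_id,
    hasn = trimws(a$hasn) %in% c("1", "true", "TRUE", "T"),
    categories = cats)
}

#' Overlay annotations onto a corpus
#'
#' Joins on `sentence_id`. Unknown sentence ids, unknown category names, and
#' two-label rows in an MC-dialect corpus are rejected with an error.
#'
#' @param corpus A `needgap_corpus`.
#' @param annotations Tibble from [read_annotations()].
#' @return The corpus with `hasn` and `categories` replaced for annotated
#'   sentences.
#' @export
apply_annotations <- function(corpus, annotations) {
  stopifnot(inherits(corpus, "needgap_corpus"))
  s <- corpus$sentences
  unknown <- setdiff(annotations$sentence_id, s$sentence_id)
  if (length(unknown) > 0) {
    stop("annotation rows reference unknown sentence_id(s): ",
         paste(utils::head(unknown, 5), collapse = ", "))
  }
  admissible <- category_levels(corpus$dialect)
  for (i in seq_len(nrow(annotations))) {
    cats <- annotations$categories[[i]]
    bad <- setdiff(cats, admissible)
    if (length(bad) > 0) {
      stop("unknown category name(s) in annotations: ", paste(bad, collapse = ", "))
    }
    if (corpus$dialect == "MC" && length(cats) > 1L) {
      stop("sentence ", annotations$sentence_id[i],
           ": two labels are only admissible in the CSN dialect")
    }
    j <- match(annotations$sentence_id[i], s$sentence_id)
    s$categories[[j]] <- cats
    s$hasn[j] <- annotations$hasn[i]
  }
  new_corpus(s, dialect = corpus$dialect, provenance = corpus$provenance)
}

#' Write an annotation table for a corpus
#'
#' @param corpus A `needgap_corpus`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(corpus, path) {
  s <- corpus_sentences(corpus)
  out <- data.frame(
    sentence_id = s$sentence_id,
    hasn = as.integer(s$hasn),
    category1 = vapply(s$categories, `[`, "", 1L),
    category2 = vapply(s$categories, function(x) if (length(x) > 1) x[2] else "", ""),
    stringsAsFactors = FALSE)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Write a descriptive-statistics report
#'
#' Writes a one-row CSV of the scalar statistics plus per-category fraction
#' columns; when `txt_path` is given, also writes the human-readable summary
#' produced by the print method.
#'
#' @param stats A `needgap_stats` object from [corpus_stats()].
#' @param path Output CSV path.
#' @param txt_path Optional plain-text summary path.
#' @return `path`, invisibly.
#' @export
write_report <- function(stats, path, txt_path = NULL) {
  stopifnot(inherits(stats, "needgap_stats"))
  scalars <- stats[setdiff(names(stats), "category_fractions")]
  row <- c(scalars, as.list(stats$category_fractions))
  names(row) <- c(names(scalars), paste0("frac_", names(stats$category_fractions)))
  utils::write.csv(as.data.frame(row), path, row.names = FALSE)
  if (!is.null(txt_path)) {
    txt <- utils::capture.output(print(stats))
    writeLines(txt, txt_path)
  }
  invisible(path)
}
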