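#' Classifier feature specification
#'
#' Declares which feature families enter the design matrix: word and bigram
#' presence counts (filtered by `min_term_count` on the training split),
#' binary local-context indicators for the category labels of the
#' immediately preceding and following sentences, per-topic proportions
#' from an LDA model fitted on the training sentences, and averaged word
#' embeddings from a word-vector table.
#'
#' @param use_words,use_bigrams,use_local_context,use_topics,use_embeddings
#'   Logical family switches (at least one must be on).
#' @param context_source `"gold"` (neighbour labels from the annotation, as
#'   in offline evaluation) or `"predicted"` (left-to-right sequential
#'   decoding; see [classify_sequential()]).
#' @param n_topics,words_per_topic LDA size: number of topics and words
#'   reported per topic (defaults 50 and 15).
#' @param lda_iterations Gibbs sweeps when fitting the topic model.
#' @param embedding_dim Expected word-vector dimension (default 50).
#' @param min_term_count Minimum training-split frequency for a word/bigram
#'   term to enter the manifest (default 2).
#' @return A `needgap_feature_spec` list.
#' @export
feature_spec <- function(use_words = TRUE, use_bigrams = TRUE,
                         use_local_context = FALSE,
                         context_source = c("gold", "predicted"),
                         use_topics = FALSE, n_topics = 50L,
                         words_per_topic = 15L, lda_iterations = 500L,
                         use_embeddings = FALSE, embedding_dim = 50L,
                         min_term_count = 2L) {
  context_source <- match.arg(context_source)
  if (!any(use_words, use_bigrams, use_local_context, use_topics, use_embeddings)) {
    stop("at least one feature family must be enabled")
  }
  structure(list(use_words = use_words, use_bigrams = use_bigrams,
                 use_local_context = use_local_context,
                 context_source = context_source,
                 use_topics = use_topics, n_topics = as.integer(n_topics),
                 words_per_topic = as.integer(words_per_topic),
                 lda_iterations = as.integer(lda_iterations),
                 use_embeddings = use_embeddings,
                 embedding_dim = as.integer(embedding_dim),
                 min_term_count = as.integer(min_term_count)),
            class = "needgap_feature_spec")
}

#' Read a word-vector table
#'
#' Plain-text format: one `word v1 v2 ... vD` line per word, whitespace
#' delimited; lines starting with `#` are skipped.
#'
#' @param path File path.
#' @return Numeric matrix with words as row names.
#' @export
read_vector_table <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L) stop("empty vector table: ", path)
  parts <- strsplit(lines, "\\s+")
  dims <- unique(lengths(parts)) - 1L
  if (length(dims) != 1L) {
    stop("inconsistent vector dimensions in ", path, ": found ",
         paste(dims, collapse = ", "))
  }
  words <- vapply(parts, `[`, "", 1L)
  mat <- t(vapply(parts, function(p) as.numeric(p[-1L]), numeric(dims)))
  rownames(mat) <- tolower(words)
  mat
}

#' Averaged word-embedding features for a sentence
#'
#' Elementwise mean of the vectors of the tokens present in the table; an
#' all-zero vector when no token is in the table.
#'
#' @param tokens Character token vector.
#' @param vectors Matrix from [read_vector_table()].
#' @return Numeric vector of the table's dimension.
#' @export
embedding_features <- function(tokens, vectors) {
  hit <- tokens[tokens %in% rownames(vectors)]
  if (length(hit) == 0L) return(numeric(ncol(vectors)))
  colMeans(vectors[hit, , drop = FALSE])
}

#' Local-context label indicators
#'
#' For every sentence, binary indicators of each admissible category for the
#' immediately preceding and the immediately following sentence within the
#' same conversation (crossing post boundaries); at conversation boundaries
#' the missing neighbour's block is all zeros. A two-label neighbour sets
#' both of its bits.
#'
#' @param corpus A `needgap_corpus` (labels are the gold annotation), or a
#'   sentence tibble in corpus order.
#' @param label_overlay Optional named list `sentence_id -> character`
#'   categories to use instead of the stored labels (e.g. predictions).
#' @return Binary matrix with `2 * n_categories` columns named
#'   `prev_<cat>` / `next_<cat>`, rows in corpus order.
#' @export
local_context_features <- function(corpus, label_overlay = NULL) {
  if (inherits(corpus, "needgap_corpus")) {
    s <- corpus_sentences(corpus)
    cats <- category_levels(corpus$dialect)
  } else {
    s <- corpus
    cats <- category_levels("MC")
  }
  labels <- s$categories
  if (!is.null(label_overlay)) {
    idx <- match(s$sentence_id, names(label_overlay))
    labels <- lapply(seq_along(idx), function(i) {
      if (is.na(idx[i])) character(0) else label_overlay[[idx[i]]]
    })
  }
  n <- nrow(s)
  K <- length(cats)
  out <- matrix(0, n, 2L * K,
                dimnames = list(NULL, c(paste0("prev_", cats), paste0("next_", cats))))
  same_conv_prev <- c(FALSE, s$conversation_id[-1] == s$conversation_id[-n])
  same_conv_next <- c(s$conversation_id[-n] == s$conversation_id[-1], FALSE)
  for (i in seq_len(n)) {
    if (same_conv_prev[i]) {
      out[i, stats::na.omit(match(labels[[i - 1L]], cats))] <- 1
    }
    if (same_conv_next[i]) {
      out[i, K + stats::na.omit(match(labels[[i + 1L]], cats))] <- 1
    }
  }
  out
}

#' Fit a feature model on training sentences
#'
#' Freezes everything the design matrix depends on — the word/bigram term
#' manifest (terms meeting `min_term_count` in the training split), the
#' topic model, and the embedding table — from training data only, so
#' featurizing held-out sentences cannot leak test vocabulary.
#'
#' @param x A `needgap_corpus` or sentence tibble (the training split).
#' @param spec A `needgap_feature_spec`.
#' @param vectors Word-vector matrix (required when `use_embeddings`).
#' @param dialect Dialect for the context-category inventory when `x` is a
#'   tibble.
#' @param seed Seed for the topic-model fit.
#' @return A `needgap_feature_model`.
#' @export
fit_features <- function(x, spec, vectors = NULL, dialect = NULL, seed = 1L) {
  stopifnot(inherits(spec, "needgap_feature_spec"))
  if (inherits(x, "needgap_corpus")) {
    s <- corpus_sentences(x)
    dialect <- x$dialect
  } else {
    s <- x
    dialect <- dialect %||% "MC"
  }
  terms <- character(0)
  if (spec$use_words) {
    wc <- table(unlist(s$tokens))
    terms <- c(terms, paste0("w:", names(wc)[wc >= spec$min_term_count]))
  }
  if (spec$use_bigrams) {
    bc <- table(unlist(lapply(s$tokens, bigrams)))
    terms <- c(terms, paste0("b:", names(bc)[bc >= spec$min_term_count]))
  }
  lda <- NULL
  if (spec$use_topics) {
    lda <- lda_fit(s$tokens, n_topics = spec$n_topics,
                   iterations = spec$lda_iterations, seed = seed)
  }
  if (spec$use_embeddings) {
    if (is.null(vectors)) stop("use_embeddings requires a word-vector table")
    if (ncol(vectors) != spec$embedding_dim) {
      stop("vector table dimension (", ncol(vectors),
           ") does not match spec embedding_dim (", spec$embedding_dim, ")")
    }
  }
  structure(list(spec = spec, terms = terms, lda = lda, vectors = vectors,
                 dialect = dialect, seed = as.integer(seed)),
            class = "needgap_feature_model")
}

#' Realise the design matrix for a set of sentences
#'
#' @param model A `needgap_feature_model` from [fit_features()].
#' @param x Sentences to featurize (`needgap_corpus` or tibble rows).
#' @param context_corpus Corpus providing neighbour ordering and labels for
#'   local-context features (defaults to `x`; pass the full corpus when `x`
#'   is a fold so neighbours outside the fold are visible).
#' @param label_overlay Optional predicted-label overlay for context
#'   features (see [local_context_features()]).
#' @return Numeric matrix, one row per sentence of `x` in corpus order.
#' @export
featurize <- function(model, x, context_corpus = NULL, label_overlay = NULL) {
  stopifnot(inherits(model, "needgap_feature_model"))
  s <- if (inherits(x, "needgap_corpus")) corpus_sentences(x) else x
  spec <- model$spec
  blocks <- list()
  if (spec$use_words || spec$use_bigrams) {
    blocks$terms <- term_count_block(s$tokens, model$terms)
  }
  if (spec$use_local_context) {
    ctx <- context_corpus %||% x
    ctx_s <- if (inherits(ctx, "needgap_corpus")) corpus_sentences(ctx) else ctx
    full_block <- local_context_features(
      structure(list(sentences = ctx_s,
                     dialect = model$dialect,
                     provenance = "context"), class = "needgap_corpus"),
      label_overlay = label_overlay)
    blocks$context <- full_block[match(s$sentence_id, ctx_s$sentence_id), , drop = FALSE]
  }
  if (spec$use_topics) {
    set.seed(model$seed + 1L)
    tf <- t(vapply(s$tokens, function(t) topic_features(model$lda, t),
                   numeric(spec$n_topics)))
    colnames(tf) <- paste0("topic_", seq_len(spec$n_topics))
    blocks$topics <- tf
  }
  if (spec$use_embeddings) {
    ef <- t(vapply(s$tokens, function(t) embedding_features(t, model$vectors),
                   numeric(ncol(model$vectors))))
    colnames(ef) <- paste0("emb_", seq_len(ncol(model$vectors)))
    blocks$emb <- ef
  }
  out <- do.call(cbind, blocks)
  rownames(out) <- s$sentence_id
  out
}

#' @noRd
term_count_block <- function(token_list, terms) {
  n <- length(token_list)
  out <- matrix(0, n, length(terms), dimnames = list(NULL, terms))
  if (length(terms) == 0L) return(out)
  for (i in seq_len(n)) {
    toks <- token_list[[i]]
    feats <- c(paste0("w:", toks), paste0("b:", bigrams(toks)))
    tab <- table(feats)
    hit <- match(names(tab), terms)
    ok <- !is.na(hit)
    out[i, hit[ok]] <- as.numeric(tab[ok])
  }
  out
}

#' Build a design matrix and vocabulary manifest in one call
#'
#' Convenience wrapper: fits the feature model and featurizes the same
#' sentences (resubstitution). For evaluation use [fit_features()] +
#' [featurize()] with an explicit train/test separation.
#'
#' @inheritParams fit_features
#' @return List with `x` (design matrix) and `model` (the manifest).
#' @export
build_design_matrix <- function(x, spec, vectors = NULL, seed = 1L) {
  model <- fit_features(x, spec, vectors = vectors, seed = seed)
  list(x = featurize(model, x, context_corpus = x), model = model)
}
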