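#' Fit a latent Dirichlet allocation topic model by collapsed Gibbs sampling
#'
#' Symmetric priors alpha = 50/T on document-topic and beta = 0.01 on
#' topic-word distributions. Documents here are sentences; the model is used
#' to derive per-sentence topic-proportion features. The default 500
#' sampling iterations suit corpus-scale fits; tests and small demos use
#' fewer.
#'
#' @param token_list List of character token vectors (one per sentence).
#' @param n_topics Number of topics T.
#' @param alpha,beta Dirichlet hyperparameters (defaults 50/T and 0.01).
#' @param iterations Gibbs sweeps over the corpus.
#' @param seed Integer RNG seed.
#' @return A `needgap_lda` model: word-topic counts, topic totals,
#'   vocabulary, hyperparameters.
#' @export
lda_fit <- function(token_list, n_topics, alpha = 50 / n_topics, beta = 0.01,
                    iterations = 500L, seed = 1L) {
  stopifnot(n_topics >= 1L)
  set.seed(seed)
  vocab <- sort(unique(unlist(token_list)))
  if (length(vocab) == 0L) stop("cannot fit a topic model on an empty corpus")
  V <- length(vocab)
  docs <- lapply(token_list, function(t) match(t, vocab))
  doc_id <- rep.int(seq_along(docs), lengths(docs))
  w <- unlist(docs)
  n_tok <- length(w)
  if (n_tok == 0L) stop("cannot fit a topic model with no tokens")
  z <- sample.int(n_topics, n_tok, replace = TRUE)
  nwt <- matrix(0L, V, n_topics)
  ndt <- matrix(0L, length(docs), n_topics)
  nt <- integer(n_topics)
  for (i in seq_len(n_tok)) {
    nwt[w[i], z[i]] <- nwt[w[i], z[i]] + 1L
    ndt[doc_id[i], z[i]] <- ndt[doc_id[i], z[i]] + 1L
    nt[z[i]] <- nt[z[i]] + 1L
  }
  for (it in seq_len(iterations)) {
    for (i in seq_len(n_tok)) {
      wi <- w[i]; di <- doc_id[i]; zi <- z[i]
      nwt[wi, zi] <- nwt[wi, zi] - 1L
      ndt[di, zi] <- ndt[di, zi] - 1L
      nt[zi] <- nt[zi] - 1L
      p <- (nwt[wi, ] + beta) / (nt + V * beta) * (ndt[di, ] + alpha)
      zi <- sample.int(n_topics, 1L, prob = p)
      z[i] <- zi
      nwt[wi, zi] <- nwt[wi, zi] + 1L
      ndt[di, zi] <- ndt[di, zi] + 1L
      nt[zi] <- nt[zi] + 1L
    }
  }
  structure(list(nwt = nwt, nt = nt, vocab = vocab, n_topics = n_topics,
                 alpha = alpha, beta = beta, seed = as.integer(seed)),
            class = "needgap_lda")
}

#' Per-sentence topic proportions
#'
#' Folds a sentence into a fitted model by Gibbs sampling its token-topic
#' assignments against the frozen word-topic counts, then reports the
#' fraction of the sentence's tokens assigned to each topic. Out-of-
#' vocabulary tokens stay unassigned, so values sum to 1 only when every
#' token is in-model; an empty (or fully out-of-vocabulary) sentence gets an
#' all-zero block.
#'
#' @param model A `needgap_lda`.
#' @param tokens Character token vector.
#' @param iterations Fold-in Gibbs sweeps (default 20).
#' @return Numeric vector of length `n_topics`, values in `[0, 1]`.
#' @export
topic_features <- function(model, tokens, iterations = 20L) {
  stopifnot(inherits(model, "needgap_lda"))
  Tn <- model$n_topics
  out <- numeric(Tn)
  if (length(tokens) == 0L) return(out)
  w <- match(tokens, model$vocab)
  w <- w[!is.na(w)]
  if (length(w) == 0L) return(out)
  V <- length(model$vocab)
  phi <- (model$nwt + model$beta) / rep(model$nt + V * model$beta, each = V)
  ndt <- numeric(Tn)
  z <- integer(length(w))
  for (i in seq_along(w)) {
    z[i] <- sample.int(Tn, 1L, prob = phi[w[i], ])
    ndt[z[i]] <- ndt[z[i]] + 1
  }
  for (it in seq_len(iterations)) {
    for (i in seq_along(w)) {
      ndt[z[i]] <- ndt[z[i]] - 1
      p <- phi[w[i], ] * (ndt + model$alpha)
      z[i] <- sample.int(Tn, 1L, prob = p)
      ndt[z[i]] <- ndt[z[i]] + 1
    }
  }
  tabulate(z, nbins = Tn) / length(tokens)
}

#' Top words of each fitted topic
#'
#' @param model A `needgap_lda`.
#' @param n_words Words reported per topic (default 15).
#' @return Tibble with `topic`, `rank`, `word`.
#' @export
lda_top_words <- function(model, n_words = 15L) {
  stopifnot(inherits(model, "needgap_lda"))
  rows <- lapply(seq_len(model$n_topics), function(t) {
    ord <- order(model$nwt[, t], decreasing = TRUE)
    k <- min(n_words, sum(model$nwt[, t] > 0))
    if (k == 0L) return(NULL)
    tibble::tibble(topic = t, rank = seq_len(k), word = model$vocab[ord[seq_len(k)]])
  })
  dplyr::bind_rows(rows)
}
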