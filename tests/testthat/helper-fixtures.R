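# Small corpus builders used across test files.

# Build a corpus from parallel vectors; sentences are laid out one
# conversation per unique conv value, one post per unique (conv, post) pair,
# indices assigned in input order.
make_corpus <- function(texts, categories, hasn,
                        conv = "c1", post = "p1",
                        dialect = "MC", author = "user01") {
  n <- length(texts)
  conv <- rep_len(conv, n)
  post <- rep_len(post, n)
  if (!is.list(categories)) categories <- as.list(categories)
  idx <- integer(n)
  key <- paste(conv, post)
  for (k in unique(key)) idx[key == k] <- seq_len(sum(key == k)) - 1L
  order_of <- function(p) match(p, unique(p)) - 1L
  post_order <- integer(n)
  for (cv in unique(conv)) {
    sel <- conv == cv
    post_order[sel] <- order_of(post[sel])
  }
  new_corpus(tibble::tibble(
    conversation_id = conv, post_id = post,
    author = rep_len(author, n), post_order = post_order,
    index_in_post = idx, text = texts,
    categories = categories, hasn = hasn),
    dialect = dialect, provenance = "test fixture")
}

# Forum config with a uniform topic mixture: every content category and
# "previous" equally likely, uniform need rate. Used where properties must
# not depend on the skewed study mixture (e.g. coverage recovery).
balanced_config <- function(seed, n_conversations = 30, hasn_rate = 0.2,
                            label_autocorrelation = 0, ...) {
  banks <- default_vocab_banks()
  cats <- c(names(banks), "previous")
  forum_config(
    seed = seed, n_conversations = n_conversations,
    category_mixture = stats::setNames(rep(1 / length(cats), length(cats)), cats),
    hasn_rate_by_category = stats::setNames(rep(hasn_rate, length(cats)), cats),
    previous_follow_rate = 0, label_autocorrelation = label_autocorrelation,
    dialect = "MC", vocab_banks = banks, ...)
}
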