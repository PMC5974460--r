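#' Fit a binary learner on a design matrix
#'
#' Three learners are supported, mirroring the classifier comparison the
#' package is built around: `naive_bayes` is a multinomial naive Bayes on
#' counts with Laplace smoothing (negative feature values are clipped at 0,
#' as multinomial NB is defined on non-negative counts); `linear_svm` is a
#' linear-kernel SVM with C = 1 (via e1071); `random_forest` is a
#' 100-tree forest with default feature subsampling (via ranger).
#'
#' @param x Numeric design matrix.
#' @param y Logical label vector (positive class = `TRUE`).
#' @param learner `"naive_bayes"`, `"linear_svm"` or `"random_forest"`.
#' @param seed Integer seed (forest bootstrap etc.).
#' @return A `needgap_learner`.
#' @export
fit_learner <- function(x, y, learner = c("naive_bayes", "linear_svm",
                                          "random_forest"), seed = 1L) {
  learner <- match.arg(learner)
  y <- as.logical(y)
  if (length(unique(y)) < 2L) {
    return(structure(list(learner = learner, constant = y[1]),
                     class = "needgap_learner"))
  }
  colnames(x) <- make.names(colnames(x), unique = TRUE)
  fit <- switch(
    learner,
    naive_bayes = fit_multinomial_nb(x, y),
    linear_svm = e1071::svm(x = x, y = factor(y, levels = c(FALSE, TRUE)),
                            kernel = "linear", cost = 1, scale = FALSE),
    random_forest = ranger::ranger(
      x = as.data.frame(x), y = factor(y, levels = c(FALSE, TRUE)),
      num.trees = 100L, seed = seed, num.threads = 1L)
  )
  structure(list(learner = learner, fit = fit, features = colnames(x)),
            class = "needgap_learner")
}

# Multinomial naive Bayes on (non-negative) counts, Laplace smoothing 1.
#' @noRd
fit_multinomial_nb <- function(x, y) {
  x <- pmax(x, 0)
  classes <- c(FALSE, TRUE)
  log_prior <- vapply(classes, function(cl) log(mean(y == cl)), 0)
  log_theta <- vapply(classes, function(cl) {
    cs <- colSums(x[y == cl, , drop = FALSE]) + 1
    log(cs / sum(cs))
  }, numeric(ncol(x)))
  list(log_prior = log_prior, log_theta = log_theta)
}

#' @rdname fit_learner
#' @param model A fitted `needgap_learner`.
#' @param newx Design matrix with the training feature columns.
#' @return `predict_learner()`: logical prediction vector.
#' @export
predict_learner <- function(model, newx) {
  stopifnot(inherits(model, "needgap_learner"))
  if (!is.null(model$constant)) {
    return(rep(model$constant, nrow(newx)))
  }
  colnames(newx) <- make.names(colnames(newx), unique = TRUE)
  newx <- newx[, model$features, drop = FALSE]
  switch(
    model$learner,
    naive_bayes = {
      scores <- pmax(newx, 0) %*% model$fit$log_theta +
        rep(model$fit$log_prior, each = nrow(newx))
      scores[, 2] > scores[, 1]
    },
    linear_svm = as.logical(as.character(stats::predict(model$fit, newx))),
    random_forest = as.logical(as.character(
      stats::predict(model$fit, data = as.data.frame(newx),
                     num.threads = 1L)$predictions))
  )
}

# sentences usable for one-vs-rest category training: the mixed-category
# "multiple" label (MC dialect) identifies sentences that belong to several
# classes at once, so they are excluded from both positives and negatives
#' @noRd
classifiable_sentences <- function(corpus) {
  s <- corpus_sentences(corpus)
  keep <- !vapply(s$categories, function(cc) "multiple" %in% cc, TRUE)
  s[keep, ]
}

#' @noRd
positive_for <- function(sentences, category) {
  vapply(sentences$categories, function(cc) category %in% cc, TRUE)
}

#' One-vs-rest cross-validated evaluation of a category classifier
#'
#' Stratified k-fold cross-validation. For every fold the term manifest and
#' any topic model are refitted on the training portion only; local-context
#' features use the gold labels of neighbouring sentences (the offline
#' convention — neighbours may fall in any fold, but no feature definition
#' depends on test data). Confusion counts are pooled across folds and
#' positive-class precision, recall and F are computed from the pooled
#' counts (micro-averaging over folds).
#'
#' @param corpus A labelled `needgap_corpus`.
#' @param category Target category (one-vs-the-others).
#' @param learner Learner name, see [fit_learner()].
#' @param spec A `needgap_feature_spec`.
#' @param k Number of folds (default 10).
#' @param seed Seed driving fold assignment, topic fits and forests.
#' @param vectors Word-vector matrix when the spec uses embeddings.
#' @return A `needgap_eval` report.
#' @export
cross_validate <- function(corpus, category, learner = "random_forest",
                           spec = feature_spec(), k = 10L, seed = 1L,
                           vectors = NULL) {
  s <- classifiable_sentences(corpus)
  y <- positive_for(s, category)
  if (sum(y) < k) {
    stop("category '", category, "' has ", sum(y),
         " positive sentences; need at least k = ", k)
  }
  set.seed(seed)
  fold <- integer(nrow(s))
  fold[y] <- sample(rep_len(seq_len(k), sum(y)))
  fold[!y] <- sample(rep_len(seq_len(k), sum(!y)))
  tp <- fp <- fn <- tn <- 0L
  fold_sizes <- integer(k)
  for (f in seq_len(k)) {
    train <- s[fold != f, ]
    test <- s[fold == f, ]
    fold_sizes[f] <- nrow(train)
    fm <- fit_features(train, spec, vectors = vectors,
                       dialect = corpus$dialect, seed = seed + f)
    x_train <- featurize(fm, train, context_corpus = s)
    x_test <- featurize(fm, test, context_corpus = s)
    mod <- fit_learner(x_train, y[fold != f], learner, seed = seed + f)
    pred <- predict_learner(mod, x_test)
    gold <- y[fold == f]
    tp <- tp + sum(pred & gold); fp <- fp + sum(pred & !gold)
    fn <- fn + sum(!pred & gold); tn <- tn + sum(!pred & !gold)
  }
  m <- prf_counts(tp, fp, fn, tn)
  new_eval(category, learner, spec, m,
           details = list(k = k, seed = seed, fold_train_sizes = fold_sizes,
                          n_positive = sum(y), n = nrow(s)))
}

#' @noRd
new_eval <- function(category, learner, spec, m, details = list()) {
  structure(list(category = category, learner = learner, spec = spec,
                 precision = m$precision, recall = m$recall, f = m$f,
                 counts = m[c("tp", "fp", "fn", "tn")],
                 undefined = m$undefined, details = details),
            class = "needgap_eval")
}

#' @export
print.needgap_eval <- function(x, ...) {
  cat(sprintf("<needgap_eval> %s / %s: P %.2f R %.2f F %.2f\n",
              x$category, x$learner, x$precision, x$recall, x$f))
  invisible(x)
}

#' Evaluation report as a tibble row
#'
#' @param x A `needgap_eval` or list of them.
#' @return Tibble with `category`, `learner`, `precision`, `recall`, `f`.
#' @export
eval_table <- function(x) {
  if (inherits(x, "needgap_eval")) x <- list(x)
  dplyr::bind_rows(lapply(x, function(e) tibble::tibble(
    category = e$category, learner = e$learner,
    precision = e$precision, recall = e$recall, f = e$f)))
}

#' Cross-forum transfer evaluation
#'
#' Fits the feature manifest, topic model and learner on one forum's corpus
#' and evaluates on the other's; context features on the test side use the
#' test corpus's own gold neighbour labels.
#'
#' @param train_corpus,test_corpus Labelled corpora sharing the category
#'   inventory.
#' @inheritParams cross_validate
#' @return A `needgap_eval` report.
#' @export
cross_forum_eval <- function(train_corpus, test_corpus, category,
                             learner = "random_forest", spec = feature_spec(),
                             seed = 1L, vectors = NULL) {
  tr <- classifiable_sentences(train_corpus)
  te <- classifiable_sentences(test_corpus)
  y_tr <- positive_for(tr, category)
  y_te <- positive_for(te, category)
  fm <- fit_features(tr, spec, vectors = vectors,
                     dialect = train_corpus$dialect, seed = seed)
  x_tr <- featurize(fm, tr, context_corpus = tr)
  x_te <- featurize(fm, te, context_corpus = te)
  mod <- fit_learner(x_tr, y_tr, learner, seed = seed)
  pred <- predict_learner(mod, x_te)
  m <- evaluate_binary(pred, y_te)
  new_eval(category, learner, spec, m,
           details = list(train_n = nrow(tr), test_n = nrow(te), seed = seed))
}

#' Train a binary information-need (HASN) classifier
#'
#' Trains on the pooled sentences of one or more annotated corpora using the
#' supplied feature spec (words + bigrams by default, the configuration used
#' when screening unseen forum text), with the need flag as the label.
#'
#' @param corpora A `needgap_corpus` or list of them.
#' @param learner Learner name.
#' @param spec Feature spec (default words + bigrams only).
#' @param seed Integer seed.
#' @return A `needgap_hasn_model` bundling the feature model and learner.
#' @export
train_hasn_classifier <- function(corpora, learner = "random_forest",
                                  spec = feature_spec(use_words = TRUE,
                                                      use_bigrams = TRUE),
                                  seed = 1L) {
  if (inherits(corpora, "needgap_corpus")) corpora <- list(corpora)
  s <- dplyr::bind_rows(lapply(corpora, function(cp) corpus_sentences(cp)))
  if (anyDuplicated(s$sentence_id)) {
    stop("training corpora share sentence ids; pool disjoint corpora only")
  }
  if (spec$use_local_context) {
    stop("the HASN screener uses position-free features; disable local context")
  }
  fm <- fit_features(s, spec, dialect = "MC", seed = seed)
  x <- featurize(fm, s)
  mod <- fit_learner(x, s$hasn, learner, seed = seed)
  structure(list(features = fm, model = mod, learner = learner),
            class = "needgap_hasn_model")
}

#' @rdname train_hasn_classifier
#' @param model A `needgap_hasn_model`.
#' @param corpus Held-out corpus (ids disjoint from training).
#' @return `evaluate_hasn()`: a `needgap_eval`; `predict_hasn()`: logical
#'   vector in corpus order.
#' @export
predict_hasn <- function(model, corpus) {
  stopifnot(inherits(model, "needgap_hasn_model"))
  s <- corpus_sentences(corpus)
  predict_learner(model$model, featurize(model$features, s))
}

#' @rdname train_hasn_classifier
#' @export
evaluate_hasn <- function(model, corpus) {
  s <- corpus_sentences(corpus)
  m <- evaluate_binary(predict_hasn(model, corpus), s$hasn)
  new_eval("hasn", model$learner, model$features$spec, m,
           details = list(test_n = nrow(s)))
}

#' Train a deployable one-vs-rest category classifier
#'
#' @inheritParams cross_validate
#' @return A `needgap_category_model`.
#' @export
train_category_classifier <- function(corpus, category,
                                      learner = "random_forest",
                                      spec = feature_spec(), seed = 1L,
                                      vectors = NULL) {
  s <- classifiable_sentences(corpus)
  fm <- fit_features(s, spec, vectors = vectors,
                     dialect = corpus$dialect, seed = seed)
  x <- featurize(fm, s, context_corpus = s)
  mod <- fit_learner(x, positive_for(s, category), learner, seed = seed)
  structure(list(category = category, features = fm, model = mod),
            class = "needgap_category_model")
}

#' Sequential left-to-right category decoding
#'
#' Production-mode alternative to gold-label context: sentences are decoded
#' in corpus order, the preceding-sentence context bits are filled from the
#' labels already predicted, and the following-sentence bits stay zero (the
#' future is unseen). With `context_source = "gold"` specs this reduces to
#' ordinary batch prediction.
#'
#' @param models List of `needgap_category_model`s (one per category).
#' @param corpus Corpus to decode.
#' @return Tibble `sentence_id`, `predicted` (list of category vectors).
#' @export
classify_sequential <- function(models, corpus) {
  s <- corpus_sentences(corpus)
  cats <- vapply(models, function(m) m$category, "")
  uses_pred_ctx <- vapply(models, function(m)
    m$features$spec$use_local_context &&
      m$features$spec$context_source == "predicted", TRUE)
  predicted <- stats::setNames(vector("list", nrow(s)), s$sentence_id)
  overlay <- stats::setNames(rep(list(character(0)), nrow(s)), s$sentence_id)
  for (i in seq_len(nrow(s))) {
    row <- s[i, ]
    labs <- character(0)
    for (j in seq_along(models)) {
      fm <- models[[j]]$features
      xi <- featurize(fm, row, context_corpus = s,
                      label_overlay = if (uses_pred_ctx[j]) overlay else NULL)
      if (predict_learner(models[[j]]$model, xi)) labs <- c(labs, cats[j])
    }
    predicted[[i]] <- labs
    overlay[[i]] <- labs
  }
  tibble::tibble(sentence_id = s$sentence_id, predicted = unname(predicted))
}
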