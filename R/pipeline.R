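#' Pipeline run configuration
#'
#' One master seed drives three independent sub-streams (corpus, pages,
#' raters) so individual stages can be re-run reproducibly. Stage outputs
#' land under `out_dir`, together with a plain-text log (ISO timestamps)
#' and a manifest listing every artifact with its MD5 checksum and the
#' configuration that produced it.
#'
#' @param out_dir Output directory (created if missing).
#' @param seed Master integer seed.
#' @param profile `"MC"` or `"CSN"` synthetic-forum profile.
#' @param n_conversations Conversations to generate.
#' @param coverage_fraction Education-page topic coverage in `[0, 1]`.
#' @param n_pages,words_per_page Education-page corpus size.
#' @param sensitivity,false_positive_rate Simulated-rater operating point.
#' @param learner Learner for the need classifier.
#' @param top_k Retrieved pages per query.
#' @param stages Stage subset to run, in order, from
#'   `c("synth", "stats", "rules", "hasn", "concepts", "gap")`.
#' @return A `needgap_run_config` list.
#' @export
pipeline_config <- function(out_dir, seed = 7L, profile = c("MC", "CSN"),
                            n_conversations = 40L, coverage_fraction = 0.5,
                            n_pages = 16L, words_per_page = 150L,
                            sensitivity = 0.9, false_positive_rate = 0.05,
                            learner = "random_forest", top_k = 2L,
                            stages = c("synth", "stats", "rules", "hasn",
                                       "concepts", "gap")) {
  profile <- match.arg(profile)
  stages <- match.arg(stages, several.ok = TRUE)
  structure(list(out_dir = out_dir, seed = as.integer(seed), profile = profile,
                 n_conversations = as.integer(n_conversations),
                 coverage_fraction = coverage_fraction,
                 n_pages = as.integer(n_pages),
                 words_per_page = as.integer(words_per_page),
                 sensitivity = sensitivity,
                 false_positive_rate = false_positive_rate,
                 learner = learner, top_k = as.integer(top_k),
                 stages = stages),
            class = "needgap_run_config")
}

#' Run the end-to-end pipeline
#'
#' Orchestrates: corpus synthesis, descriptive statistics, rule induction
#' for need detection (with a train/test split and an evaluation against
#' the statistical need classifier), concept profiling, and the knowledge-
#' gap assessment (query construction, BM25 retrieval over generated
#' education pages, simulated rater verdicts, agreement and coverage).
#' Re-running with the same configuration reproduces identical artifacts;
#' a failing stage leaves a `FAILED` marker naming the stage and rethrows.
#'
#' @param config A `needgap_run_config`.
#' @return Invisibly, a list of in-memory stage results.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "needgap_run_config"))
  if (!dir.exists(config$out_dir)) dir.create(config$out_dir, recursive = TRUE)
  log_path <- file.path(config$out_dir, "pipeline.log")
  cat("", file = log_path)
  log_line <- function(...) {
    cat(format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"), " ", ..., "\n",
        sep = "", file = log_path, append = TRUE)
  }
  seeds <- substream_seeds(config$seed)
  out <- list()
  current_stage <- NA_character_
  result <- tryCatch({
    for (stage in config$stages) {
      current_stage <- stage
      log_line("stage ", stage, " start (seed ", config$seed, ")")
      out <- run_stage(stage, config, seeds, out, log_line)
      log_line("stage ", stage, " done")
    }
    out
  }, error = function(e) {
    writeLines(paste0("stage ", current_stage, ": ", conditionMessage(e)),
               file.path(config$out_dir, "FAILED"))
    log_line("stage ", current_stage, " FAILED: ", conditionMessage(e))
    stop(e)
  })
  write_manifest(config)
  log_line("pipeline complete")
  invisible(result)
}

#' @noRd
run_stage <- function(stage, config, seeds, out, log_line) {
  od <- config$out_dir
  if (stage == "synth") {
    fc <- if (config$profile == "MC") {
      mc_profile(seed = seeds[["corpus"]], n_conversations = config$n_conversations)
    } else {
      csn_profile(seed = seeds[["corpus"]], n_conversations = config$n_conversations)
    }
    out$corpus <- generate_corpus(fc)
    write_corpus(out$corpus, file.path(od, "corpus.jsonl"))
    write_annotations(out$corpus, file.path(od, "annotations.csv"))
    ec <- education_config(seed = seeds[["pages"]], n_pages = config$n_pages,
                           words_per_page = config$words_per_page,
                           coverage_fraction = config$coverage_fraction)
    out$education <- generate_education_pages(ec, fc$vocab_banks,
                                              dir = file.path(od, "pages"))
    log_line("generated ", nrow(out$corpus$sentences), " sentences, ",
             config$n_pages, " pages")
  } else if (stage == "stats") {
    out$stats <- corpus_stats(require_stage(out, "corpus"))
    write_report(out$stats, file.path(od, "stats.csv"),
                 txt_path = file.path(od, "stats.txt"))
  } else if (stage == "rules") {
    corpus <- require_stage(out, "corpus")
    split <- split_conversations(corpus, frac = 0.8, seed = seeds[["corpus"]])
    pos <- split$train[split$train$hasn, ]
    neg <- split$train[!split$train$hasn, ]
    out$ruleset <- induce_patterns(pos, neg)
    write_ruleset(out$ruleset, file.path(od, "ruleset.json"))
    pred <- match_all(out$ruleset, split$test)
    out$rules_eval <- evaluate_binary(pred, split$test$hasn)
    out$rules_split <- split
    log_line(sprintf("rules: %d patterns; held-out P %.2f R %.2f F %.2f",
                     length(out$ruleset$patterns), out$rules_eval$precision,
                     out$rules_eval$recall, out$rules_eval$f))
  } else if (stage == "hasn") {
    corpus <- require_stage(out, "corpus")
    split <- out$rules_split %||%
      split_conversations(corpus, frac = 0.8, seed = seeds[["corpus"]])
    train_corpus <- new_corpus(split$train, corpus$dialect, "pipeline train split")
    test_corpus <- new_corpus(split$test, corpus$dialect, "pipeline test split")
    model <- train_hasn_classifier(train_corpus, learner = config$learner,
                                   seed = config$seed)
    out$hasn_eval <- evaluate_hasn(model, test_corpus)
    cmp <- eval_table(out$hasn_eval)
    cmp$approach <- "statistical"
    if (!is.null(out$rules_eval)) {
      cmp <- rbind(cmp, data.frame(category = "hasn", learner = "rules",
                                   precision = out$rules_eval$precision,
                                   recall = out$rules_eval$recall,
                                   f = out$rules_eval$f,
                                   approach = "rule-based"))
    }
    utils::write.csv(cmp, file.path(od, "hasn_eval.csv"), row.names = FALSE)
    log_line(sprintf("hasn classifier (%s): F %.2f", config$learner,
                     out$hasn_eval$f))
  } else if (stage == "concepts") {
    out$concepts <- concept_profile(require_stage(out, "corpus"))
    utils::write.csv(out$concepts, file.path(od, "concepts.csv"),
                     row.names = FALSE)
  } else if (stage == "gap") {
    corpus <- require_stage(out, "corpus")
    edu <- out$education
    if (is.null(edu)) stop("gap stage requires the synth stage's education pages")
    index <- index_pages(file.path(od, "pages"))
    out$queries <- build_queries(corpus, index)
    write_queries(out$queries, file.path(od, "queries.csv"))
    out$results <- retrieve_all(out$queries, index, top_k = config$top_k)
    utils::write.csv(out$results, file.path(od, "retrieval.csv"),
                     row.names = FALSE)
    rc <- rater_config(seed = seeds[["raters"]], sensitivity = config$sensitivity,
                       false_positive_rate = config$false_positive_rate)
    out$ratings <- simulate_raters(out$results, out$queries,
                                   edu$gold_coverage, rc)
    utils::write.csv(out$ratings, file.path(od, "ratings.csv"),
                     row.names = FALSE)
    out$gap <- gap_report(out$queries, out$ratings)
    write_gap_report(out$gap, file.path(od, "gap_report.csv"),
                     txt_path = file.path(od, "gap_report.txt"))
    write_review_file(out$queries, out$results, corpus, edu$pages,
                      file.path(od, "review.md"))
    log_line(sprintf("gap: %d queries; coverage any %.1f%% all %.1f%%",
                     out$gap$n_queries, 100 * out$gap$coverage_any,
                     100 * out$gap$coverage_all))
  }
  out
}

#' @noRd
require_stage <- function(out, what) {
  x <- out[[what]]
  if (is.null(x)) stop("stage requires '", what, "' from an earlier stage")
  x
}

# conversation-level train/test split (no conversation straddles the split)
#' @noRd
split_conversations <- function(corpus, frac = 0.8, seed = 1L) {
  s <- corpus_sentences(corpus)
  convs <- unique(s$conversation_id)
  set.seed(seed)
  n_train <- max(1L, round(frac * length(convs)))
  train_ids <- sample(convs, n_train)
  list(train = s[s$conversation_id %in% train_ids, ],
       test = s[!s$conversation_id %in% train_ids, ])
}

#' @noRd
write_manifest <- function(config) {
  files <- sort(list.files(config$out_dir, recursive = TRUE, full.names = TRUE))
  # the log carries wall-clock timestamps; manifest checksums cover only the
  # deterministic artifacts
  files <- files[!basename(files) %in% c("manifest.json", "pipeline.log")]
  manifest <- list(
    config = unclass(config),
    artifacts = lapply(files, function(f)
      list(path = sub(paste0("^", config$out_dir, "/?"), "", f),
           md5 = unname(tools::md5sum(f)))))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
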