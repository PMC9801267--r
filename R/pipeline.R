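#' Run the baseline retriever over all topics
#'
#' Retrieves up to `config$cap` candidates per topic with the expanded
#' boolean query, extracts reranking features for each candidate, and
#' assembles the baseline run (top 1000 by retrieval score). When no
#' synonym table is supplied every term expands to itself alone, with a
#' warning.
#'
#' @param articles an [article_collection()].
#' @param topics topic `data.frame`.
#' @param synonyms a [synonym_table()] or `NULL`.
#' @param config a [retriever_config()].
#' @param scorer_pb scorer backend for the `pb` feature (default
#'   [zero_scorer()]).
#' @param index optional prebuilt index (rebuilt from `articles` otherwise).
#' @param tag run tag (default `"baseline"`).
#' @return list with `run` (baseline run `data.frame`), `candidates` (named
#'   list by topic id of feature `data.frame`s, each at most `config$cap`
#'   rows) and `index`.
#' @export
run_baseline <- function(articles, topics, synonyms = NULL,
                         config = retriever_config(),
                         scorer_pb = zero_scorer(), index = NULL,
                         tag = "baseline") {
  if (is.null(synonyms)) {
    warning("no synonym table supplied; terms expand to themselves alone")
    synonyms <- synonym_table()
  }
  if (is.null(index)) index <- build_index(articles)
  candidates <- list()
  runs <- list()
  for (i in seq_len(nrow(topics))) {
    topic <- topics[i, , drop = FALSE]
    hits <- retrieve_candidates(topic, synonyms, index, config)
    feats <- extract_features(topic, hits, articles, scorer_pb = scorer_pb)
    candidates[[as.character(topic$id)]] <- feats
    if (nrow(hits) > 0L) {
      keep <- seq_len(min(nrow(hits), RUN_CAP))
      runs[[length(runs) + 1L]] <- data.frame(
        topic = topic$id, article = hits$article[keep], rank = keep,
        score = hits$score[keep], tag = tag, stringsAsFactors = FALSE)
    }
  }
  run <- if (length(runs)) do.call(rbind, runs) else
    data.frame(topic = integer(0), article = character(0), rank = integer(0),
               score = numeric(0), tag = character(0), stringsAsFactors = FALSE)
  list(run = run, candidates = candidates, index = index)
}

#' Rerank baseline candidates for every topic
#'
#' @param candidates named list of feature `data.frame`s (from
#'   [run_baseline()]).
#' @param preset preset name from [reranker_presets()].
#' @param fb_scores optional named list of trainable-scorer outputs per
#'   topic.
#' @param lr_fit optional fitted regressor for full presets.
#' @param cap run cap (default 1000).
#' @return a run `data.frame`.
#' @export
rerank_all <- function(candidates, preset = "auto-1", fb_scores = NULL,
                       lr_fit = NULL, cap = RUN_CAP) {
  runs <- lapply(names(candidates), function(tid) {
    if (nrow(candidates[[tid]]) == 0L) return(NULL)
    rerank_candidates(as.integer(tid), candidates[[tid]], preset = preset,
                      fb_scores = fb_scores[[tid]], lr_fit = lr_fit,
                      cap = cap)
  })
  out <- do.call(rbind, runs)
  if (is.null(out)) {
    out <- data.frame(topic = integer(0), article = character(0),
                      rank = integer(0), score = numeric(0),
                      tag = character(0), stringsAsFactors = FALSE)
  }
  out
}

#' Run the full two-stage pipeline
#'
#' Baseline retrieval, then either a feature-only automatic rerank (auto
#' presets) or the expert-in-the-loop active-learning loop followed by the
#' full combiner rerank (full presets; requires an oracle), then evaluation
#' against the supplied judgments.
#'
#' @inheritParams run_baseline
#' @param qrels optional truth [judgment_set()] for evaluation.
#' @param preset reranker preset (default `"full-3"`).
#' @param oracle annotation oracle; required for full presets.
#' @param loop a [loop_config()] (its preset is overridden by `preset`).
#' @param scorer trainable-scorer backend for the loop.
#' @param metrics metric names for [evaluate_run()].
#' @return list with `run`, `baseline` (the [run_baseline()] output),
#'   `history` (loop history or `NULL`), `state` (final loop state or
#'   `NULL`) and `metrics` (or `NULL` when no qrels given).
#' @export
run_full <- function(articles, topics, synonyms = NULL, qrels = NULL,
                     preset = "full-3", oracle = NULL,
                     config = retriever_config(), loop = loop_config(),
                     scorer = hash_scorer(), scorer_pb = zero_scorer(),
                     metrics = c("p10", "rprec", "ndcg30-std", "ndcg30-exp")) {
  row <- .preset_row(preset)
  base <- run_baseline(articles, topics, synonyms, config,
                       scorer_pb = scorer_pb)
  history <- NULL
  state <- NULL
  if (row$mode == "auto") {
    run <- rerank_all(base$candidates, preset = preset)
  } else {
    if (is.null(oracle)) {
      stop("preset '", preset, "' requires expert annotations: supply an ",
           "oracle (e.g. make_oracle()) or use an auto preset")
    }
    loop$preset <- preset
    state <- init_active_state(topics, base$candidates, articles,
                               scorer = scorer, config = loop)
    state <- run_loop(state, oracle, qrels = qrels)
    history <- state$history
    fb <- lapply(names(state$candidates), function(tid) {
      scorer_score(state$scorer, state$topic_texts[[tid]],
                   state$candidate_text[[tid]])
    })
    names(fb) <- names(state$candidates)
    run <- rerank_all(state$candidates, preset = preset, fb_scores = fb,
                      lr_fit = state$lr_fit)
  }
  metrics_out <- if (!is.null(qrels)) evaluate_run(run, qrels, metrics)
  list(run = run, baseline = base, history = history, state = state,
       metrics = metrics_out)
}

#' Recall of truth-relevant documents at a cutoff
#'
#' Fraction of relevant (tier >= `threshold`) judged documents that appear
#' in the top `k` of the run, averaged over topics.
#'
#' @param run run `data.frame`.
#' @param qrels a [judgment_set()].
#' @param k cutoff (default 1000).
#' @param threshold minimum relevant tier (default 1).
#' @return mean recall over topics with at least one relevant document.
#' @export
recall_at_k <- function(run, qrels, k = 1000L, threshold = 1L) {
  topics <- sort(unique(qrels$topic))
  vals <- vapply(topics, function(tid) {
    rel <- qrels$article[qrels$topic == tid & qrels$tier >= threshold]
    if (length(rel) == 0L) return(NA_real_)
    top <- utils::head(.topic_ranking(run, tid), k)
    mean(rel %in% top)
  }, numeric(1))
  mean(vals, na.rm = TRUE)
}
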