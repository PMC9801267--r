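#' Annotation store
#'
#' Records expert annotations as (topic, article, tier, iteration) rows; at
#' most one record per (topic, article). The normalized label fed to the
#' trainable scorer is `tier / 4` in \[0, 1\].
#'
#' @param topic,article,tier,iteration parallel vectors.
#' @return `data.frame` of class `annotation_store`.
#' @export
annotation_store <- function(topic = integer(0), article = character(0),
                             tier = integer(0), iteration = integer(0)) {
  tier <- as.integer(tier)
  if (any(tier < 0L | tier > 4L)) stop("tiers must be in 0..4")
  out <- data.frame(topic = as.integer(topic), article = as.character(article),
                    tier = tier, iteration = as.integer(iteration),
                    stringsAsFactors = FALSE)
  if (anyDuplicated(out[c("topic", "article")])) {
    stop("duplicate (topic, article) annotation")
  }
  class(out) <- c("annotation_store", "data.frame")
  out
}

#' @param store an `annotation_store`.
#' @param path 4-column delimited file (topic, article, tier, iteration).
#' @rdname annotation_store
#' @export
write_annotations <- function(store, path) {
  writeLines(sprintf("%d\t%s\t%d\t%d", store$topic, store$article,
                     store$tier, store$iteration), path)
  invisible(path)
}

#' @rdname annotation_store
#' @export
read_annotations <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           colClasses = c("integer", "character", "integer",
                                          "integer"),
                           col.names = c("topic", "article", "tier",
                                         "iteration"))
  annotation_store(tab$topic, tab$article, tab$tier, tab$iteration)
}

#' Mean annotated relevance
#'
#' Arithmetic mean of the normalized labels `tier / 4` over all annotations;
#' the empirical stop signal of the active loop.
#'
#' @param store a non-empty [annotation_store()].
#' @return mean in \[0, 1\].
#' @export
mean_annotated_relevance <- function(store) {
  if (nrow(store) == 0L) stop("annotation store is empty")
  mean(store$tier / 4)
}

#' Annotation oracle contract
#'
#' An oracle answers `oracle_annotate(oracle, topic, article)` with a tier in
#' 0..4, deterministically within a run. [make_oracle()] builds one from a
#' simulated expert; `function_oracle()` wraps any `function(topic, article)`.
#'
#' @param oracle an oracle object.
#' @param topic topic id.
#' @param article article id.
#' @return integer tier in 0..4.
#' @export
oracle_annotate <- function(oracle, topic, article) UseMethod("oracle_annotate")

#' @param fn a `function(topic, article)` returning a tier.
#' @rdname oracle_annotate
#' @export
function_oracle <- function(fn) {
  structure(list(fn = fn), class = c("function_oracle", "oracle"))
}

#' @export
oracle_annotate.function_oracle <- function(oracle, topic, article) {
  tier <- as.integer(oracle$fn(topic, article))
  if (is.na(tier) || tier < 0L || tier > 4L) {
    stop("oracle returned an invalid tier for topic ", topic, ", article ",
         article)
  }
  tier
}

#' Active-loop configuration
#'
#' @param max_iter maximum number of iterations (default 22).
#' @param per_topic annotations per topic per iteration (default 1).
#' @param stop_window stop patience: halt once the mean annotated relevance
#'   has stayed below its running maximum for this many consecutive
#'   iterations (default 3).
#' @param preset reranker preset used inside the loop (default `"full-1"`:
#'   with the desk-scale lexical scorer backend the regressor and the
#'   text-pair scorer are weighted equally; `"full-3"`, which trusts the
#'   text-pair scorer five-fold, mirrors the production configuration built
#'   around a fine-tuned transformer).
#' @param cold_start_preset auto preset ranking the candidates before the
#'   first annotations exist (default `"auto-1"`).
#' @param refit_lr refit the feature linear regressor each iteration
#'   (default `TRUE`; `FALSE` freezes the preset coefficients).
#' @return list of class `loop_config`.
#' @export
loop_config <- function(max_iter = 22L, per_topic = 1L, stop_window = 3L,
                        preset = "full-1", cold_start_preset = "auto-1",
                        refit_lr = TRUE) {
  stopifnot(max_iter >= 0L, per_topic >= 1L, stop_window >= 1L)
  structure(list(max_iter = as.integer(max_iter),
                 per_topic = as.integer(per_topic),
                 stop_window = as.integer(stop_window), preset = preset,
                 cold_start_preset = cold_start_preset, refit_lr = refit_lr),
            class = "loop_config")
}

#' Select documents for expert annotation
#'
#' Top-1 (or top-`per_topic`) active feedback: for every topic, the highest
#' ranked candidate(s) not yet in the store. Topics whose candidates are all
#' annotated contribute nothing.
#'
#' @param rankings named list (by topic id) of article-id vectors in current
#'   rank order.
#' @param store an [annotation_store()].
#' @param per_topic selections per topic (default 1).
#' @return `data.frame(topic, article)`.
#' @export
select_for_annotation <- function(rankings, store, per_topic = 1L) {
  sel <- lapply(names(rankings), function(tid) {
    done <- store$article[store$topic == as.integer(tid)]
    todo <- setdiff(rankings[[tid]], done)
    utils::head(todo, per_topic)
  })
  data.frame(topic = rep(as.integer(names(rankings)), lengths(sel)),
             article = unlist(sel, use.names = FALSE),
             stringsAsFactors = FALSE)
}

#' Initialize active-loop state
#'
#' Bundles everything one loop run needs: the per-topic candidate features,
#' the candidate texts for the trainable scorer, and the (initially
#' unfitted) scorer. Initial rankings come from the cold-start auto preset.
#'
#' @param topics topic `data.frame` (columns `id`, `disease`, `gene`,
#'   `treatment`).
#' @param candidates named list (by topic id) of feature `data.frame`s from
#'   [extract_features()].
#' @param articles the [article_collection()].
#' @param scorer trainable-scorer backend (default [hash_scorer()]).
#' @param config a [loop_config()].
#' @param normalize_es divide each topic's `es` feature by its per-topic
#'   maximum before fitting/applying the regressor (default `TRUE`), so that
#'   annotations pooled across topics share a comparable retrieval-score
#'   scale; `FALSE` keeps raw BM25 scores.
#' @return list of class `active_state`.
#' @export
init_active_state <- function(topics, candidates, articles,
                              scorer = hash_scorer(),
                              config = loop_config(), normalize_es = TRUE) {
  stopifnot(all(as.character(topics$id) %in% names(candidates)))
  if (normalize_es) {
    candidates <- lapply(candidates, function(cd) {
      if (nrow(cd) > 0L && max(cd$es) > 0) cd$es <- cd$es / max(cd$es)
      cd
    })
  }
  texts <- lapply(as.character(topics$id), function(tid) {
    m <- match(candidates[[tid]]$article, articles$id)
    article_text(articles[m, , drop = FALSE])
  })
  names(texts) <- as.character(topics$id)
  qtexts <- topic_text(topics)
  names(qtexts) <- as.character(topics$id)
  rankings <- lapply(as.character(topics$id), function(tid) {
    run <- rerank_candidates(as.integer(tid), candidates[[tid]],
                             preset = config$cold_start_preset,
                             cap = nrow(candidates[[tid]]))
    run$article
  })
  names(rankings) <- as.character(topics$id)
  structure(list(topics = topics, candidates = candidates,
                 candidate_text = texts, topic_texts = qtexts,
                 scorer = scorer, lr_fit = NULL, config = config,
                 store = annotation_store(), rankings = rankings,
                 history = NULL),
            class = "active_state")
}

# rescore every topic's candidates with the current scorer/regressor
.loop_rerank <- function(state) {
  cfg <- state$config
  for (tid in names(state$candidates)) {
    fb <- scorer_score(state$scorer, state$topic_texts[[tid]],
                       state$candidate_text[[tid]])
    run <- rerank_candidates(as.integer(tid), state$candidates[[tid]],
                             preset = cfg$preset, fb_scores = fb,
                             lr_fit = state$lr_fit,
                             cap = nrow(state$candidates[[tid]]))
    state$rankings[[tid]] <- run$article
  }
  state
}

#' Run one active-learning iteration
#'
#' Annotates the highest-ranked unannotated document of every topic via the
#' oracle, refits the trainable scorer on all annotations collected so far
#' (and, unless frozen, the feature linear regressor once at least 5
#' annotations exist), recomputes all candidate rankings with the full
#' combiner, and appends an iteration record.
#'
#' @param state an `active_state`.
#' @param oracle an annotation oracle.
#' @param qrels optional truth [judgment_set()]; when supplied, the held-out
#'   mean NDCG@30 (exponential gains) of the refreshed rankings is recorded.
#' @return the updated state.
#' @export
run_iteration <- function(state, oracle, qrels = NULL) {
  iter <- if (is.null(state$history)) 1L else nrow(state$history) + 1L
  sel <- select_for_annotation(state$rankings, state$store,
                               state$config$per_topic)
  if (nrow(sel) > 0L) {
    tiers <- integer(nrow(sel))
    for (i in seq_len(nrow(sel))) {
      tiers[i] <- tryCatch(
        oracle_annotate(oracle, sel$topic[i], sel$article[i]),
        error = function(e) stop("annotation failed at iteration ", iter,
                                 " for topic ", sel$topic[i], ", article ",
                                 sel$article[i], ": ", conditionMessage(e),
                                 call. = FALSE))
    }
    state$store <- annotation_store(
      topic = c(state$store$topic, sel$topic),
      article = c(state$store$article, sel$article),
      tier = c(state$store$tier, tiers),
      iteration = c(state$store$iteration, rep(iter, nrow(sel)))
    )
  }
  if (nrow(state$store) > 0L) {
    tt <- state$topic_texts[as.character(state$store$topic)]
    at <- vapply(seq_len(nrow(state$store)), function(i) {
      tid <- as.character(state$store$topic[i])
      j <- match(state$store$article[i], state$candidates[[tid]]$article)
      state$candidate_text[[tid]][j]
    }, character(1))
    state$scorer <- scorer_fit(state$scorer, unname(unlist(tt)), at,
                               state$store$tier / 4)
    if (isTRUE(state$config$refit_lr) && nrow(state$store) >= 5L) {
      feats <- do.call(rbind, lapply(seq_len(nrow(state$store)), function(i) {
        tid <- as.character(state$store$topic[i])
        cand <- state$candidates[[tid]]
        cand[match(state$store$article[i], cand$article),
             c("es", "pb", "ty", "ct"), drop = FALSE]
      }))
      state$lr_fit <- fit_linear_regressor(feats, state$store$tier / 4)
    }
  }
  state <- .loop_rerank(state)
  rec <- data.frame(iteration = iter, n_new = nrow(sel),
                    n_annotations = nrow(state$store),
                    mean_relevance = if (nrow(state$store)) {
                      mean_annotated_relevance(state$store)
                    } else NA_real_,
                    heldout_ndcg30_exp = NA_real_)
  if (!is.null(qrels)) {
    rec$heldout_ndcg30_exp <- mean(vapply(names(state$rankings), function(tid) {
      ndcg_at_k(state$rankings[[tid]], qrels, as.integer(tid), k = 30L,
                gains = "exponential")
    }, numeric(1)))
  }
  state$history <- rbind(state$history, rec)
  state
}

#' Run the expert-in-the-loop active-learning loop
#'
#' Iterates [run_iteration()] until the iteration budget is exhausted, the
#' stop rule fires (the mean annotated relevance has stayed strictly below
#' its running maximum for `stop_window` consecutive iterations), or no
#' unannotated candidates remain.
#'
#' @inheritParams run_iteration
#' @param state an `active_state` from [init_active_state()].
#' @return the final state, with `history` (one row per iteration), the
#'   fitted `scorer` and the final `rankings`.
#' @export
run_loop <- function(state, oracle, qrels = NULL) {
  cfg <- state$config
  best <- -Inf
  declining <- 0L
  for (it in seq_len(cfg$max_iter)) {
    before <- nrow(state$store)
    state <- run_iteration(state, oracle, qrels)
    if (nrow(state$store) == before) break  # nothing left to annotate
    mr <- state$history$mean_relevance[nrow(state$history)]
    if (mr > best) {
      best <- mr
      declining <- 0L
    } else {
      declining <- declining + 1L
    }
    if (declining >= cfg$stop_window) break
  }
  state
}
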