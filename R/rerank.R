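#' Publication-type evidence scores
#'
#' The default map rates each MEDLINE publication type by the clinical
#' evidence quality it signals, on an integer scale from -2 (retractions,
#' errata) to 2 (clinical trials, meta-analyses, systematic reviews).
#' Matching is case-insensitive; unknown labels score 0.
#'
#' @return named integer vector `label -> score`.
#' @export
pub_type_score_map <- function() {
  c("comment" = -1L, "editorial" = -1L,
    "published erratum" = -2L, "retraction of publication" = -2L,
    "english abstract" = 0L, "journal article" = 0L, "letter" = 0L,
    "review" = 0L,
    "case reports" = 1L, "observational study" = 1L,
    "clinical trial" = 2L, "meta-analysis" = 2L, "systematic review" = 2L)
}

#' Publication-type score of an article
#'
#' An article carrying several publication types scores as its strongest
#' evidence form (the maximum mapped score). An empty label set scores 0.
#'
#' @param pub_types character vector of publication-type labels.
#' @param map named integer vector (default [pub_type_score_map()]).
#' @return integer score in -2..2.
#' @export
publication_type_score <- function(pub_types, map = pub_type_score_map()) {
  if (length(pub_types) == 0L) return(0L)
  sc <- map[tolower(pub_types)]
  sc[is.na(sc)] <- 0L
  max(as.integer(sc))
}

#' Citation-count quantile
#'
#' Empirical CDF position of an article's citation count within the corpus:
#' the fraction of corpus articles with a citation count less than or equal
#' to this article's. Under a degenerate (all-equal) distribution every
#' article scores 1.
#'
#' @param count citation count(s) to place (vectorized).
#' @param corpus_counts non-empty vector of all corpus citation counts.
#' @return quantile(s) in \[0, 1\].
#' @export
citation_quantile <- function(count, corpus_counts) {
  stopifnot(length(corpus_counts) > 0L)
  sorted <- sort(corpus_counts)
  findInterval(count, sorted) / length(sorted)
}

#' Extract reranking features for retrieved candidates
#'
#' Per (topic, article) candidate: `es` the retrieval score, `pb` the
#' pluggable text-pair score in \[0, 1\], `ty` the publication-type score and
#' `ct` the citation quantile.
#'
#' @param topic one-row topic `data.frame` or list.
#' @param hits `data.frame(article, score)` from [retrieve_candidates()].
#' @param articles the [article_collection()] (corpus statistics source).
#' @param scorer_pb a trainable-scorer backend for the `pb` feature
#'   (default [zero_scorer()]).
#' @param type_map publication-type score map.
#' @return `data.frame(article, es, pb, ty, ct)`.
#' @export
extract_features <- function(topic, hits, articles,
                             scorer_pb = zero_scorer(),
                             type_map = pub_type_score_map()) {
  m <- match(hits$article, articles$id)
  if (anyNA(m)) stop("candidate article absent from the corpus: ",
                     hits$article[which(is.na(m))[1L]])
  data.frame(
    article = hits$article,
    es = hits$score,
    pb = scorer_score(scorer_pb, topic_text(topic),
                      article_text(articles[m, , drop = FALSE])),
    ty = vapply(articles$pub_types[m], publication_type_score, integer(1),
                map = type_map),
    ct = citation_quantile(articles$citation_count[m],
                           articles$citation_count),
    stringsAsFactors = FALSE
  )
}

#' Concatenated query / article text
#'
#' The query text of a topic is its disease, gene and treatment concatenated;
#' the text of an article is its title and abstract concatenated.
#'
#' @param topic one-row topic `data.frame` or list.
#' @return a character string (vectorized over articles).
#' @export
topic_text <- function(topic) {
  paste(topic$disease, topic$gene, topic$treatment)
}

#' @param articles rows of an [article_collection()].
#' @rdname topic_text
#' @export
article_text <- function(articles) {
  paste(articles$title, articles$abstract)
}

#' Fit the evidence linear regressor
#'
#' Ordinary least squares of expert labels on the four reranking features
#' `(es, pb, ty, ct)` with an intercept. A rank-deficient design yields the
#' minimum-norm least-squares solution (via the singular value
#' decomposition) rather than an error.
#'
#' @param features `data.frame` (or matrix) with columns `es`, `pb`, `ty`,
#'   `ct`; at least 5 rows, all finite.
#' @param labels numeric response, one per row.
#' @return list of class `evidence_lm` with `coef` (named, length 4),
#'   `intercept`, and `se` (coefficient standard errors, `NA` when not
#'   estimable).
#' @export
fit_linear_regressor <- function(features, labels) {
  X <- as.matrix(as.data.frame(features)[, c("es", "pb", "ty", "ct")])
  storage.mode(X) <- "double"
  y <- as.numeric(labels)
  if (nrow(X) < 5L) stop("need at least 5 training pairs")
  if (!all(is.finite(X)) || !all(is.finite(y))) stop("features/labels must be finite")
  A <- cbind(intercept = 1, X)
  sv <- svd(A)
  tol <- max(dim(A)) * max(sv$d) * .Machine$double.eps
  pos <- sv$d > tol
  dinv <- ifelse(pos, 1 / sv$d, 0)
  beta <- sv$v %*% (dinv * crossprod(sv$u, y))
  beta <- drop(beta)
  names(beta) <- colnames(A)
  resid <- y - drop(A %*% beta)
  dof <- nrow(A) - sum(pos)
  se <- rep(NA_real_, ncol(A))
  if (dof > 0 && all(pos)) {
    sigma2 <- sum(resid^2) / dof
    covb <- sv$v %*% (dinv^2 * t(sv$v)) * sigma2
    se <- sqrt(diag(covb))
  }
  names(se) <- colnames(A)
  structure(list(coef = beta[-1L], intercept = unname(beta[1L]),
                 se = se, df_residual = dof),
            class = "evidence_lm")
}

#' @param fit an `evidence_lm`.
#' @param features feature `data.frame` to predict for.
#' @rdname fit_linear_regressor
#' @export
predict_linear <- function(fit, features) {
  X <- as.matrix(as.data.frame(features)[, c("es", "pb", "ty", "ct")])
  drop(X %*% fit$coef) + fit$intercept
}

#' Reranker weight presets
#'
#' The preset table holds the named run configurations: automatic
#' runs combine max-normalized features with fixed weights; full runs
#' combine a linear-regressor prediction with the trainable text-pair
#' scorer's output as `w_lr * LR + w_fb * FB` (for full presets the
#' `w_es..w_ct` columns hold the shipped regressor coefficients, applied to
#' raw features with intercept 0 when no freshly fitted regressor is
#' supplied). Ablation presets isolate single features.
#'
#' @return `data.frame` with one row per preset: `preset`, `run_id`, `mode`
#'   (`"auto"` or `"full"`), `w_es`, `w_pb`, `w_ty`, `w_ct`, `w_lr`, `w_fb`.
#' @export
reranker_presets <- function() {
  lr <- c(-0.465, -0.141, -0.617, -0.005)
  out <- rbind(
    data.frame(preset = "auto-1", run_id = "damoespb1", mode = "auto",
               w_es = 1.0, w_pb = 0.5, w_ty = 1.5, w_ct = 0.0,
               w_lr = NA_real_, w_fb = NA_real_),
    data.frame(preset = "auto-2", run_id = "damoespb2", mode = "auto",
               w_es = 1.0, w_pb = 0.5, w_ty = 1.0, w_ct = 0.0,
               w_lr = NA_real_, w_fb = NA_real_),
    data.frame(preset = "full-1", run_id = "damoespcbh1", mode = "full",
               w_es = lr[1], w_pb = lr[2], w_ty = lr[3], w_ct = lr[4],
               w_lr = 1.0, w_fb = 1.0),
    data.frame(preset = "full-2", run_id = "damoespcbh2", mode = "full",
               w_es = lr[1], w_pb = lr[2], w_ty = lr[3], w_ct = lr[4],
               w_lr = 1.0, w_fb = 2.0),
    data.frame(preset = "full-3", run_id = "damoespcbh3", mode = "full",
               w_es = lr[1], w_pb = lr[2], w_ty = lr[3], w_ct = lr[4],
               w_lr = 1.0, w_fb = 5.0),
    data.frame(preset = "retriever+pb", run_id = NA_character_, mode = "auto",
               w_es = 1.0, w_pb = 1.0, w_ty = 0.0, w_ct = 0.0,
               w_lr = NA_real_, w_fb = NA_real_),
    data.frame(preset = "retriever+ty", run_id = NA_character_, mode = "auto",
               w_es = 1.0, w_pb = 0.0, w_ty = 1.0, w_ct = 0.0,
               w_lr = NA_real_, w_fb = NA_real_),
    data.frame(preset = "retriever+ct", run_id = NA_character_, mode = "auto",
               w_es = 1.0, w_pb = 0.0, w_ty = 0.0, w_ct = 1.0,
               w_lr = NA_real_, w_fb = NA_real_),
    data.frame(preset = "lr-only", run_id = NA_character_, mode = "full",
               w_es = lr[1], w_pb = lr[2], w_ty = lr[3], w_ct = lr[4],
               w_lr = 1.0, w_fb = 0.0),
    data.frame(preset = "fb-only", run_id = NA_character_, mode = "full",
               w_es = lr[1], w_pb = lr[2], w_ty = lr[3], w_ct = lr[4],
               w_lr = 0.0, w_fb = 1.0)
  )
  out
}

.preset_row <- function(preset) {
  tab <- reranker_presets()
  i <- match(preset, tab$preset)
  if (is.na(i)) {
    stop("unknown preset '", preset, "'; available: ",
         paste(tab$preset, collapse = ", "))
  }
  tab[i, , drop = FALSE]
}

#' Automatic-run score combination
#'
#' `w_es * es/es_max + w_pb * pb/pb_max + w_ty * ty/ty_max + w_ct * ct/ct_max`
#' where the maxima are taken over the candidate set of the same topic; a
#' feature whose per-topic maximum is 0 contributes 0.
#'
#' @param features `data.frame` with columns `es`, `pb`, `ty`, `ct` for one
#'   topic's candidates.
#' @param weights numeric of length 4 (`w_es`, `w_pb`, `w_ty`, `w_ct`).
#' @param maxima optional per-topic feature maxima (defaults to the maxima of
#'   `features` itself).
#' @return numeric combined scores.
#' @export
combine_auto <- function(features, weights, maxima = NULL) {
  weights <- as.numeric(weights)
  stopifnot(length(weights) == 4L)
  cols <- c("es", "pb", "ty", "ct")
  if (is.null(maxima)) {
    maxima <- vapply(cols, function(cn) max(features[[cn]]), numeric(1))
  }
  out <- numeric(nrow(as.data.frame(features)))
  for (k in seq_along(cols)) {
    if (maxima[[k]] != 0) {
      out <- out + weights[k] * features[[cols[k]]] / maxima[[k]]
    }
  }
  out
}

#' Full-run score combination
#'
#' `r = w_lr * lr_prediction + w_fb * fb_score`.
#'
#' @param lr_prediction linear-regressor prediction(s).
#' @param fb_score trainable text-pair scorer output(s).
#' @param w_lr,w_fb combiner weights.
#' @return numeric combined scores.
#' @export
combine_full <- function(lr_prediction, fb_score, w_lr, w_fb) {
  stopifnot(all(is.finite(lr_prediction)), all(is.finite(fb_score)))
  w_lr * lr_prediction + w_fb * fb_score
}

#' Rerank retrieved candidates by evidence quality
#'
#' Reorders one topic's candidates with the selected preset's combiner and
#' truncates to the run cap. Ties are broken by ascending article id.
#' Reranking permutes and truncates only: no document outside the candidate
#' set can appear.
#'
#' @param topic_id integer topic id.
#' @param features candidate features from [extract_features()] (columns
#'   `article`, `es`, `pb`, `ty`, `ct`), in candidate order.
#' @param preset preset name from [reranker_presets()].
#' @param fb_scores trainable-scorer outputs per candidate (full presets;
#'   default 0).
#' @param lr_fit optional fitted [fit_linear_regressor()] used for the LR
#'   prediction in full presets; when `NULL` the preset's shipped
#'   coefficients are applied to raw features with intercept 0.
#' @param cap run cap (default 1000).
#' @param tag run tag (defaults to the preset name).
#' @return run `data.frame(topic, article, rank, score, tag)`.
#' @export
rerank_candidates <- function(topic_id, features, preset = "auto-1",
                              fb_scores = NULL, lr_fit = NULL,
                              cap = RUN_CAP, tag = preset) {
  row <- .preset_row(preset)
  n <- nrow(features)
  if (row$mode == "auto") {
    r <- combine_auto(features, c(row$w_es, row$w_pb, row$w_ty, row$w_ct))
  } else {
    lr_pred <- if (!is.null(lr_fit)) {
      predict_linear(lr_fit, features)
    } else {
      drop(as.matrix(features[, c("es", "pb", "ty", "ct")]) %*%
             c(row$w_es, row$w_pb, row$w_ty, row$w_ct))
    }
    if (is.null(fb_scores)) fb_scores <- numeric(n)
    r <- combine_full(lr_pred, fb_scores, row$w_lr, row$w_fb)
  }
  ord <- order(-r, features$article, method = "radix")
  keep <- utils::head(ord, cap)
  data.frame(topic = topic_id, article = features$article[keep],
             rank = seq_along(keep), score = r[keep], tag = tag,
             stringsAsFactors = FALSE)
}
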