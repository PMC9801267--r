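#' Trainable text-pair scorer contract
#'
#' A trainable scorer maps a (query text, article text) pair to an evidence
#' score in \[0, 1\] and can be (re)fitted to labeled pairs by minimizing
#' squared error. Backends implement two generics: `scorer_fit(scorer,
#' topic_text, article_text, labels)` returns a fitted scorer, and
#' `scorer_score(scorer, topic_text, article_text)` returns deterministic
#' scores in \[0, 1\]. Query text is the concatenated disease, gene and
#' treatment; article text is the concatenated title and abstract (see
#' [topic_text()] / [article_text()]).
#'
#' The default backend is [hash_scorer()], a hashed bag-of-words ridge
#' regressor: deterministic, desk-scale, and honoring the mean-squared-error
#' objective. A transformer text-pair backend (domain-pretrained BERT
#' encoder over `query [SEP] article`, sigmoid head on the CLS state,
#' trained with Adam at learning rate 4e-5, batch size 16, 10 epochs per
#' refit) is the reference configuration for production-scale use; it is
#' intentionally not implemented here, the contract being the integration
#' surface.
#'
#' @param scorer a scorer backend object.
#' @param topic_text character vector (or scalar, recycled) of query texts.
#' @param article_text character vector of article texts.
#' @param labels numeric labels in \[0, 1\].
#' @return `scorer_fit()` a fitted scorer; `scorer_score()` numeric scores
#'   in \[0, 1\].
#' @name trainable_scorer
NULL

#' @rdname trainable_scorer
#' @export
scorer_fit <- function(scorer, topic_text, article_text, labels) {
  UseMethod("scorer_fit")
}

#' @rdname trainable_scorer
#' @export
scorer_score <- function(scorer, topic_text, article_text) {
  UseMethod("scorer_score")
}

#' Degenerate scorer backends
#'
#' `zero_scorer()` always scores 0; `constant_scorer(value)` always scores
#' `value`. Both ignore fitting. Useful as placeholders for the pluggable
#' pretrained (`pb`) feature when no pretraining data exists.
#'
#' @param value constant score in \[0, 1\].
#' @return a scorer backend.
#' @export
zero_scorer <- function() constant_scorer(0)

#' @rdname zero_scorer
#' @export
constant_scorer <- function(value) {
  stopifnot(value >= 0, value <= 1)
  structure(list(value = value), class = c("constant_scorer", "scorer"))
}

#' @export
scorer_fit.constant_scorer <- function(scorer, topic_text, article_text, labels) {
  scorer
}

#' @export
scorer_score.constant_scorer <- function(scorer, topic_text, article_text) {
  rep(scorer$value, max(length(topic_text), length(article_text)))
}

#' Hashed bag-of-words ridge scorer
#'
#' The default trainable-scorer backend. Each pair is featurized by hashing
#' the article's distinct tokens and, separately prefixed, the tokens shared
#' by the query and the article (the lexical-overlap signal) into `dim`
#' presence buckets; rows are L2-normalized so the ridge penalty is
#' scale-free in document length. Fitting solves the ridge-regularized
#' least-squares problem `(X'X + lambda I) beta = X'y` in closed form (in
#' dual form when the training set is smaller than `dim`), so refits are
#' deterministic and independent of training-pair order; predictions are
#' clipped to \[0, 1\]. An unfitted scorer returns 0.5.
#'
#' @param dim number of hash buckets (default 8192; larger dims reduce
#'   collision noise and the fit cost is governed by `min(n, dim)`).
#' @param lambda ridge penalty on the row-normalized design (default 0.2).
#' @return a scorer backend of class `hash_scorer`.
#' @export
hash_scorer <- function(dim = 8192L, lambda = 0.2) {
  stopifnot(dim >= 2L, lambda > 0)
  structure(list(dim = as.integer(dim), lambda = lambda, beta = NULL),
            class = c("hash_scorer", "scorer"))
}

# deterministic polynomial string hash -> bucket in 1..dim
.hash_tokens <- function(tokens, dim) {
  vapply(tokens, function(tok) {
    h <- 0
    for (code in utf8ToInt(tok)) h <- (h * 31 + code) %% 1000003
    as.integer(h %% dim) + 1L
  }, integer(1), USE.NAMES = FALSE)
}

# sparse n x dim design matrix for text pairs; rows L2-normalized (with the
# intercept column appended first) so the ridge penalty is scale-free in
# document length
.pair_design_norm <- function(scorer, topic_text, article_text) {
  X <- cbind(.pair_design(scorer, topic_text, article_text), 1)
  X / sqrt(Matrix::rowSums(X^2))
}

# sparse n x dim design matrix for text pairs
.pair_design <- function(scorer, topic_text, article_text) {
  n <- max(length(topic_text), length(article_text))
  topic_text <- rep_len(topic_text, n)
  article_text <- rep_len(article_text, n)
  a_toks <- .tokenize_many(article_text)
  q_toks <- .tokenize_many(topic_text)
  feats <- lapply(seq_len(n), function(i) {
    ov <- intersect(q_toks[[i]], a_toks[[i]])
    unique(c(paste0("a:", a_toks[[i]]),
             if (length(ov)) paste0("m:", ov)))
  })
  vocab <- unique(unlist(feats, use.names = FALSE))
  if (is.null(vocab) || length(vocab) == 0L) {
    return(Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                                dims = c(n, scorer$dim)))
  }
  buckets <- .hash_tokens(vocab, scorer$dim)
  ii <- rep.int(seq_len(n), lengths(feats))
  jj <- buckets[match(unlist(feats, use.names = FALSE), vocab)]
  Matrix::sparseMatrix(i = ii, j = jj, x = 1, dims = c(n, scorer$dim))
}

#' @export
scorer_fit.hash_scorer <- function(scorer, topic_text, article_text, labels) {
  y <- as.numeric(labels)
  stopifnot(all(is.finite(y)))
  X <- .pair_design_norm(scorer, topic_text, article_text)
  d <- scorer$dim + 1L
  n <- nrow(X)
  if (n < d) {
    # dual form: beta = X' (XX' + lambda I)^-1 y, identical solution,
    # n x n solve instead of d x d
    K <- as.matrix(Matrix::tcrossprod(X)) + scorer$lambda * diag(n)
    alpha <- solve(K, y)
    scorer$beta <- as.numeric(Matrix::crossprod(X, alpha))
  } else {
    G <- as.matrix(Matrix::crossprod(X)) + scorer$lambda * diag(d)
    scorer$beta <- drop(solve(G, as.numeric(Matrix::crossprod(X, y))))
  }
  scorer
}

#' @export
scorer_score.hash_scorer <- function(scorer, topic_text, article_text) {
  n <- max(length(topic_text), length(article_text))
  if (is.null(scorer$beta)) return(rep(0.5, n))
  X <- .pair_design_norm(scorer, topic_text, article_text)
  pmin(1, pmax(0, as.numeric(X %*% scorer$beta)))
}
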