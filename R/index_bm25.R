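#' Tokenize text
#'
#' Lowercased maximal alphanumeric runs, in order. Empty or `NA` text yields
#' an empty token vector.
#'
#' @param text a single character string.
#' @return character vector of tokens.
#' @export
tokenize <- function(text) {
  if (length(text) == 0L || is.na(text) || !nzchar(text)) return(character(0))
  toks <- strsplit(tolower(text), "[^a-z0-9]+")[[1]]
  toks[nzchar(toks)]
}

# vectorized tokenization: list of token vectors, one per input string
.tokenize_many <- function(texts) {
  texts[is.na(texts)] <- ""
  toks <- strsplit(tolower(texts), "[^a-z0-9]+")
  lapply(toks, function(t) t[nzchar(t)])
}

#' Okapi BM25 parameters
#'
#' @param k1 term-frequency saturation, >= 0 (default 1.2).
#' @param b length-normalization strength in \[0, 1\] (default 0.75).
#' @return list of class `bm25_params`.
#' @export
bm25_params <- function(k1 = 1.2, b = 0.75) {
  stopifnot(is.numeric(k1), k1 >= 0, is.numeric(b), b >= 0, b <= 1)
  structure(list(k1 = k1, b = b), class = "bm25_params")
}

INDEX_FIELDS <- c("title", "abstract")

#' Build a fielded inverted index
#'
#' Indexes the title and abstract fields of an article collection. Each field
#' stores a sparse document-term count matrix, per-document token lengths,
#' the mean length, and per-term document frequencies. Building is
#' deterministic for a fixed input.
#'
#' @param articles an [article_collection()] (non-empty).
#' @param params default [bm25_params()] stored with the index.
#' @return object of class `inverted_index`.
#' @export
build_index <- function(articles, params = bm25_params()) {
  if (nrow(articles) == 0L) stop("cannot index an empty collection")
  if (anyDuplicated(articles$id)) stop("duplicate article ids")
  fields <- lapply(INDEX_FIELDS, function(fld) {
    toks <- .tokenize_many(articles[[fld]])
    lens <- lengths(toks)
    vocab <- sort(unique(unlist(toks, use.names = FALSE)))
    if (length(vocab) == 0L) {
      dtm <- Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                                  dims = c(nrow(articles), 0L))
    } else {
      di <- rep.int(seq_along(toks), lens)
      tj <- match(unlist(toks, use.names = FALSE), vocab)
      dtm <- Matrix::sparseMatrix(i = di, j = tj, x = 1,
                                  dims = c(nrow(articles), length(vocab)))
    }
    colnames(dtm) <- vocab
    list(dtm = dtm, df = Matrix::colSums(dtm > 0), lens = lens,
         avglen = mean(lens), vocab = vocab)
  })
  names(fields) <- INDEX_FIELDS
  structure(list(doc_ids = articles$id, N = nrow(articles),
                 params = params, fields = fields),
            class = "inverted_index")
}

#' @export
print.inverted_index <- function(x, ...) {
  cat(sprintf("<inverted_index> %d documents; vocab title=%d abstract=%d\n",
              x$N, length(x$fields$title$vocab), length(x$fields$abstract$vocab)))
  invisible(x)
}

#' Postings list for a term
#'
#' @param index an `inverted_index`.
#' @param term single token.
#' @param field `"title"` or `"abstract"`.
#' @return `data.frame(article, tf)` sorted by article id.
#' @export
postings <- function(index, term, field) {
  f <- index$fields[[field]]
  j <- match(term, f$vocab)
  if (is.na(j)) {
    return(data.frame(article = character(0), tf = numeric(0),
                      stringsAsFactors = FALSE))
  }
  tf <- f$dtm[, j]
  hit <- which(tf > 0)
  out <- data.frame(article = index$doc_ids[hit], tf = tf[hit],
                    stringsAsFactors = FALSE)
  out[order(out$article), , drop = FALSE]
}

#' Document frequency of a term
#'
#' @inheritParams postings
#' @param field one index field, or `NULL` for the collection-wide df (number
#'   of documents containing the term in any field).
#' @return integer count.
#' @export
doc_frequency <- function(index, term, field = NULL) {
  if (!is.null(field)) {
    f <- index$fields[[field]]
    j <- match(term, f$vocab)
    return(if (is.na(j)) 0L else as.integer(f$df[j]))
  }
  present <- rep(FALSE, index$N)
  for (f in index$fields) {
    j <- match(term, f$vocab)
    if (!is.na(j)) present <- present | (f$dtm[, j] > 0)
  }
  sum(present)
}

# BM25 score of a single term against every document in a field.
# idf = ln(1 + (N - df + 0.5) / (df + 0.5)): the non-negative engine variant.
.bm25_vec <- function(index, term, field, params = index$params) {
  f <- index$fields[[field]]
  j <- match(term, f$vocab)
  if (is.na(j)) return(numeric(index$N))
  tf <- f$dtm[, j]
  df <- f$df[j]
  idf <- log(1 + (index$N - df + 0.5) / (df + 0.5))
  norm <- if (f$avglen > 0) 1 - params$b + params$b * f$lens / f$avglen else 1
  out <- numeric(index$N)
  hit <- tf > 0
  out[hit] <- idf * tf[hit] * (params$k1 + 1) / (tf[hit] + params$k1 * norm[hit])
  out
}

#' BM25 score of one term for one article
#'
#' `idf(term) * tf * (k1 + 1) / (tf + k1 * (1 - b + b * len/avglen))` with
#' `idf = ln(1 + (N - df + 0.5) / (df + 0.5))`; 0 when the term is absent
#' from the article's field. Lengths are normalized against the field's own
#' mean length.
#'
#' @inheritParams postings
#' @param article article id.
#' @param params [bm25_params()]; defaults to those stored with the index.
#' @return a single score.
#' @export
bm25_score <- function(index, term, field, article, params = index$params) {
  i <- match(article, index$doc_ids)
  if (is.na(i)) stop("unknown article id: ", article)
  .bm25_vec(index, term, field, params)[i]
}

# ---- query algebra ---------------------------------------------------------

#' Query clauses
#'
#' The query algebra mirrors engine semantics: `term_clause()` scores one
#' token in one field scaled by `boost`; `synonym_clause()` scores a possibly
#' multiword synonym as the bag-of-tokens sum of its tokens' BM25 scores,
#' scaled by `weight`; `dis_max()` scores `max(s) + tie_breaker * (sum(s) -
#' max(s))` over its subqueries; `bool_query()` requires every `must` clause
#' to match and adds the scores of `must` and matching `should` clauses. A
#' clause matches a document iff its score is > 0; a document failing a
#' `must` clause is not a hit.
#'
#' @param term,text query text (a `synonym_clause` may be multiword).
#' @param field `"title"` or `"abstract"`.
#' @param boost,weight non-negative score multiplier.
#' @param ... subqueries of a `dis_max`.
#' @param tie_breaker real in \[0, 1\].
#' @param must,should lists of clauses.
#' @return a query object (class `query_clause`).
#' @name query
NULL

#' @rdname query
#' @export
term_clause <- function(term, field, boost = 1) {
  stopifnot(boost >= 0)
  structure(list(term = term, field = match.arg(field, INDEX_FIELDS),
                 boost = boost),
            class = c("term_clause", "query_clause"))
}

#' @rdname query
#' @export
synonym_clause <- function(text, field, weight = 1) {
  stopifnot(weight >= 0)
  structure(list(text = text, field = match.arg(field, INDEX_FIELDS),
                 weight = weight),
            class = c("synonym_clause", "query_clause"))
}

#' @rdname query
#' @export
dis_max <- function(..., tie_breaker = 0) {
  subs <- list(...)
  if (length(subs) == 1L && is.list(subs[[1]]) &&
      !inherits(subs[[1]], "query_clause")) {
    subs <- subs[[1]]
  }
  stopifnot(length(subs) >= 1L, tie_breaker >= 0, tie_breaker <= 1)
  structure(list(subs = subs, tie_breaker = tie_breaker),
            class = c("dis_max", "query_clause"))
}

#' @rdname query
#' @export
bool_query <- function(must = list(), should = list()) {
  if (inherits(must, "query_clause")) must <- list(must)
  if (inherits(should, "query_clause")) should <- list(should)
  structure(list(must = must, should = should),
            class = c("bool_query", "query_clause"))
}

# Score a query against every document: list(score = numeric N, match = logical N)
.score_all <- function(index, query, params = index$params) {
  if (inherits(query, "term_clause")) {
    s <- query$boost * .bm25_vec(index, query$term, query$field, params)
    return(list(score = s, match = s > 0))
  }
  if (inherits(query, "synonym_clause")) {
    toks <- tokenize(query$text)
    s <- numeric(index$N)
    for (t in toks) s <- s + .bm25_vec(index, t, query$field, params)
    s <- query$weight * s
    return(list(score = s, match = s > 0))
  }
  if (inherits(query, "dis_max")) {
    parts <- lapply(query$subs, function(q) .score_all(index, q, params))
    S <- vapply(parts, function(p) ifelse(p$match, p$score, 0), numeric(index$N))
    S <- matrix(S, nrow = index$N)
    mx <- apply(S, 1L, max)
    sm <- rowSums(S)
    match <- Reduce(`|`, lapply(parts, `[[`, "match"))
    return(list(score = mx + query$tie_breaker * (sm - mx), match = match))
  }
  if (inherits(query, "bool_query")) {
    score <- numeric(index$N)
    if (length(query$must) > 0L) {
      mparts <- lapply(query$must, function(q) .score_all(index, q, params))
      match <- Reduce(`&`, lapply(mparts, `[[`, "match"))
      for (p in mparts) score <- score + ifelse(p$match, p$score, 0)
    } else {
      match <- rep(FALSE, index$N)
    }
    if (length(query$should) > 0L) {
      sparts <- lapply(query$should, function(q) .score_all(index, q, params))
      for (p in sparts) score <- score + ifelse(p$match, p$score, 0)
      if (length(query$must) == 0L) {
        match <- Reduce(`|`, lapply(sparts, `[[`, "match"))
      }
    }
    return(list(score = ifelse(match, score, 0), match = match))
  }
  stop("not a query clause: ", paste(class(query), collapse = "/"))
}

#' Score a query against one article
#'
#' @param index an `inverted_index`.
#' @param query a query clause.
#' @param article article id.
#' @param params optional [bm25_params()].
#' @return the score, or `NA_real_` when the article is not a hit for the
#'   query (e.g. a failed `must` clause).
#' @export
score_query <- function(index, query, article, params = index$params) {
  i <- match(article, index$doc_ids)
  if (is.na(i)) stop("unknown article id: ", article)
  r <- .score_all(index, query, params)
  if (r$match[i]) r$score[i] else NA_real_
}

#' Execute a query
#'
#' Returns all and only matching documents, sorted by score descending with
#' ties broken by ascending article id, truncated to `limit`.
#'
#' @inheritParams score_query
#' @param limit maximum number of hits (>= 1).
#' @return `data.frame(article, score)` in rank order.
#' @export
execute_query <- function(index, query, limit = 10000L, params = index$params) {
  stopifnot(limit >= 1L)
  r <- .score_all(index, query, params)
  hit <- which(r$match)
  if (length(hit) == 0L) {
    return(data.frame(article = character(0), score = numeric(0),
                      stringsAsFactors = FALSE))
  }
  ids <- index$doc_ids[hit]
  sc <- r$score[hit]
  ord <- order(-sc, ids, method = "radix")
  keep <- utils::head(ord, limit)
  data.frame(article = ids[keep], score = sc[keep], stringsAsFactors = FALSE)
}
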