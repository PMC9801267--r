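# Independent brute-force oracles and random-case generators shared across
# the suite. Everything here recomputes from raw article text, never through
# the package's index structures.

orc_tokens <- function(text) {
  toks <- strsplit(tolower(text), "[^a-z0-9]+")[[1]]
  toks[nzchar(toks)]
}

# per-corpus token statistics computed by direct counting
orc_stats <- function(articles) {
  fields <- lapply(c(title = "title", abstract = "abstract"), function(f) {
    toks <- lapply(articles[[f]], orc_tokens)
    lens <- lengths(toks)
    list(toks = toks, lens = lens, avglen = mean(lens))
  })
  list(fields = fields, N = nrow(articles), ids = articles$id)
}

orc_bm25 <- function(st, term, field, i, k1 = 1.2, b = 0.75) {
  f <- st$fields[[field]]
  tf <- sum(f$toks[[i]] == term)
  if (tf == 0) return(0)
  df <- sum(vapply(f$toks, function(t) term %in% t, logical(1)))
  idf <- log(1 + (st$N - df + 0.5) / (df + 0.5))
  norm <- if (f$avglen > 0) 1 - b + b * f$lens[i] / f$avglen else 1
  idf * tf * (k1 + 1) / (tf + k1 * norm)
}

# scalar recursive query scorer; returns list(score, match) for document i
orc_score <- function(st, q, i, k1 = 1.2, b = 0.75) {
  if (inherits(q, "term_clause")) {
    s <- q$boost * orc_bm25(st, q$term, q$field, i, k1, b)
    return(list(score = s, match = s > 0))
  }
  if (inherits(q, "synonym_clause")) {
    s <- 0
    for (t in orc_tokens(q$text)) s <- s + orc_bm25(st, t, q$field, i, k1, b)
    s <- q$weight * s
    return(list(score = s, match = s > 0))
  }
  if (inherits(q, "dis_max")) {
    parts <- lapply(q$subs, orc_score, st = st, i = i, k1 = k1, b = b)
    sc <- vapply(parts, function(p) if (p$match) p$score else 0, numeric(1))
    match <- any(vapply(parts, `[[`, logical(1), "match"))
    return(list(score = max(sc) + q$tie_breaker * (sum(sc) - max(sc)),
                match = match))
  }
  if (inherits(q, "bool_query")) {
    s <- 0
    if (length(q$must) > 0) {
      mp <- lapply(q$must, orc_score, st = st, i = i, k1 = k1, b = b)
      match <- all(vapply(mp, `[[`, logical(1), "match"))
      for (p in mp) if (p$match) s <- s + p$score
    } else {
      match <- FALSE
    }
    if (length(q$should) > 0) {
      sp <- lapply(q$should, orc_score, st = st, i = i, k1 = k1, b = b)
      for (p in sp) if (p$match) s <- s + p$score
      if (length(q$must) == 0) {
        match <- any(vapply(sp, `[[`, logical(1), "match"))
      }
    }
    return(list(score = if (match) s else 0, match = match))
  }
  stop("unknown clause")
}

# full brute-force execution: every matching doc, ordered by score desc then id
orc_execute <- function(articles, q, limit = 10000L, k1 = 1.2, b = 0.75) {
  st <- orc_stats(articles)
  res <- lapply(seq_len(st$N), function(i) orc_score(st, q, i, k1, b))
  match <- vapply(res, `[[`, logical(1), "match")
  sc <- vapply(res, `[[`, numeric(1), "score")
  ids <- st$ids[match]
  sc <- sc[match]
  ord <- order(-sc, ids, method = "radix")
  head(data.frame(article = ids[ord], score = sc[ord],
                  stringsAsFactors = FALSE), limit)
}

# random small corpus: <= max_docs docs, fields of <= max_len tokens over a
# tiny vocabulary so term overlaps are frequent
rand_corpus <- function(max_docs = 20L, max_len = 8L,
                        vocab = c("alpha", "beta", "gamma", "delta", "egfr",
                                  "braf", "tumor", "trial")) {
  n <- sample(2:max_docs, 1)
  mk <- function() {
    vapply(seq_len(n), function(i) {
      paste(sample(vocab, sample(0:max_len, 1), replace = TRUE),
            collapse = " ")
    }, character(1))
  }
  article_collection(id = sprintf("D%03d", seq_len(n)), title = mk(),
                     abstract = mk())
}

rand_clause <- function(vocab) {
  field <- sample(c("title", "abstract"), 1)
  if (runif(1) < 0.5) {
    term_clause(sample(vocab, 1), field, boost = round(runif(1, 0, 3), 2))
  } else {
    synonym_clause(paste(sample(vocab, sample(1:2, 1)), collapse = " "),
                   field, weight = round(runif(1, 0.1, 2), 2))
  }
}

rand_dismax <- function(vocab) {
  k <- sample(1:3, 1)
  dis_max(lapply(seq_len(k), function(i) rand_clause(vocab)),
          tie_breaker = round(runif(1), 2))
}

rand_query <- function(vocab = c("alpha", "beta", "gamma", "delta", "egfr",
                                 "braf", "tumor", "trial", "zeta")) {
  n_must <- sample(0:2, 1)
  n_should <- sample(0:2, 1)
  if (n_must + n_should == 0) n_must <- 1
  bool_query(
    must = lapply(seq_len(n_must), function(i) rand_dismax(vocab)),
    should = lapply(seq_len(n_should), function(i) rand_dismax(vocab))
  )
}

# direct-sum NDCG computed with an explicit loop, independent of ndcg_at_k
orc_ndcg <- function(ranking, qrels, topic, k, gains) {
  gmap <- if (identical(gains, "standard")) c(0, 1, 2, 3, 4) else c(0, 1, 2, 4, 8)
  dcg <- 0
  for (i in seq_len(min(k, length(ranking)))) {
    hit <- qrels$tier[qrels$topic == topic & qrels$article == ranking[i]]
    g <- if (length(hit)) gmap[hit + 1] else 0
    dcg <- dcg + g / log2(i + 1)
  }
  tiers <- sort(qrels$tier[qrels$topic == topic], decreasing = TRUE)
  idcg <- 0
  for (i in seq_len(min(k, length(tiers)))) {
    idcg <- idcg + gmap[tiers[i] + 1] / log2(i + 1)
  }
  if (idcg == 0) 0 else dcg / idcg
}

# small fully wired benchmark for loop and pipeline tests
tiny_benchmark <- function(seed = 11L, n_docs = 400L, n_topics = 3L) {
  generate_benchmark(synth_config(n_docs = n_docs, n_topics = n_topics,
                                  vocab_size = 300L, seed = seed))
}

mean_ndcg30_exp <- function(run, qrels) {
  topics <- sort(unique(run$topic))
  mean(vapply(topics, function(tid) {
    sub <- run[run$topic == tid, , drop = FALSE]
    ndcg_at_k(sub$article[order(sub$rank)], qrels, tid, k = 30L,
              gains = "exponential")
  }, numeric(1)))
}
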