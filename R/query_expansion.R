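#' Synonym tables
#'
#' A synonym table maps a query term to an ordered synonym list with the
#' original term first. Files are two-column delimited (`term<TAB>synonym`,
#' comma also accepted), repeated rows per term; the original term is
#' prepended when absent so that the first synonym always equals the term
#' itself.
#'
#' @param path two-column delimited file.
#' @return named list of character vectors (class `synonym_table`).
#' @export
read_synonym_table <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  tab <- list()
  for (i in seq_along(lines)) {
    ln <- lines[[i]]
    parts <- if (grepl("\t", ln)) strsplit(ln, "\t")[[1]] else strsplit(ln, ",")[[1]]
    parts <- trimws(parts)
    if (length(parts) != 2L || any(!nzchar(parts))) {
      stop("synonym table line ", i, ": expected 2 non-empty fields")
    }
    tab[[parts[1L]]] <- c(tab[[parts[1L]]], parts[2L])
  }
  synonym_table(tab)
}

#' @param table named list `term -> character vector of synonyms`.
#' @rdname read_synonym_table
#' @export
synonym_table <- function(table = list()) {
  tab <- lapply(names(table), function(term) {
    syns <- unique(as.character(table[[term]]))
    syns <- syns[nzchar(syns)]
    if (length(syns) == 0L || syns[1L] != term) syns <- c(term, setdiff(syns, term))
    syns
  })
  names(tab) <- names(table)
  structure(tab, class = "synonym_table")
}

#' @param term query term.
#' @rdname read_synonym_table
#' @export
synonyms_for <- function(table, term) {
  if (!is.null(table[[term]])) table[[term]] else term
}

#' @param path output file.
#' @rdname read_synonym_table
#' @export
write_synonym_table <- function(table, path) {
  lines <- unlist(lapply(names(table), function(term) {
    paste(term, table[[term]], sep = "\t")
  }), use.names = FALSE)
  writeLines(if (is.null(lines)) character(0) else lines, path)
  invisible(path)
}

#' Baseline retriever configuration
#'
#' @param tie_breaker dis_max tie breaker (default 0.8).
#' @param title_boost boost factor of the title field (default 3.0).
#' @param abstract_boost boost factor of the abstract field (default 1.0).
#' @param keywords evidence-signal keywords added as should-clauses
#'   (default `c("trial", "patient")`), acting as a weak classifier for
#'   evidence-based papers.
#' @param cap maximum number of retrieved candidates per topic
#'   (default 10000).
#' @return list of class `retriever_config`.
#' @export
retriever_config <- function(tie_breaker = 0.8, title_boost = 3.0,
                             abstract_boost = 1.0,
                             keywords = c("trial", "patient"),
                             cap = 10000L) {
  stopifnot(tie_breaker >= 0, tie_breaker <= 1, title_boost > 0,
            abstract_boost > 0, cap >= 1L)
  structure(list(tie_breaker = tie_breaker, title_boost = title_boost,
                 abstract_boost = abstract_boost,
                 keywords = as.character(keywords), cap = as.integer(cap)),
            class = "retriever_config")
}

# df of a (possibly multiword) synonym: number of documents containing all of
# its tokens, looking across title and abstract together
.synonym_df <- function(index, text) {
  toks <- tokenize(text)
  if (length(toks) == 0L) return(0L)
  present <- rep(TRUE, index$N)
  for (t in toks) {
    any_field <- rep(FALSE, index$N)
    for (f in index$fields) {
      j <- match(t, f$vocab)
      if (!is.na(j)) any_field <- any_field | (f$dtm[, j] > 0)
    }
    present <- present & any_field
  }
  sum(present)
}

#' Synonym weights from normalized document frequency
#'
#' `weight(s_i) = df(s_i) / max_j df(s_j)`, where the df of a multiword
#' synonym counts documents containing all of its tokens in title or
#' abstract. Normalizing by the maximum lowers the rank contribution of rare
#' synonyms; when every synonym has df 0 all weights fall back to 1.
#'
#' @param synonyms character vector of synonyms (original term first).
#' @param index an `inverted_index`.
#' @return `data.frame(text, df, weight)` in input order.
#' @export
synonym_weights <- function(synonyms, index) {
  stopifnot(length(synonyms) >= 1L)
  df <- vapply(synonyms, .synonym_df, numeric(1), index = index)
  mx <- max(df)
  w <- if (mx == 0) rep(1, length(df)) else df / mx
  data.frame(text = synonyms, df = as.integer(df), weight = w,
             row.names = NULL, stringsAsFactors = FALSE)
}

# dis_max over one concept's weighted synonyms, one clause per synonym per field
.concept_dismax <- function(synonyms, index, config) {
  w <- synonym_weights(synonyms, index)
  clauses <- list()
  for (i in seq_len(nrow(w))) {
    clauses <- c(clauses, list(
      synonym_clause(w$text[i], "title", weight = w$weight[i] * config$title_boost),
      synonym_clause(w$text[i], "abstract", weight = w$weight[i] * config$abstract_boost)
    ))
  }
  dis_max(clauses, tie_breaker = config$tie_breaker)
}

#' Assemble the boolean query for a topic
#'
#' The query must match the disease and the treatment and should match the
#' gene, each as a dis_max over weighted synonym clauses spanning both
#' fields. The treatment is never expanded (it is its own sole synonym).
#' Each configured keyword adds one should term clause (abstract field,
#' boost 1).
#'
#' @param topic one-row topic `data.frame` (or list) with `disease`, `gene`,
#'   `treatment`.
#' @param table a [synonym_table()] (may lack entries; a missing term expands
#'   to itself alone).
#' @param index an `inverted_index`.
#' @param config a [retriever_config()].
#' @return a [bool_query()].
#' @export
build_topic_query <- function(topic, table = synonym_table(), index,
                              config = retriever_config()) {
  stopifnot(nzchar(topic$disease), nzchar(topic$gene), nzchar(topic$treatment))
  must <- list(
    .concept_dismax(synonyms_for(table, topic$disease), index, config),
    .concept_dismax(topic$treatment, index, config)
  )
  should <- list(.concept_dismax(synonyms_for(table, topic$gene), index, config))
  for (kw in config$keywords) {
    should <- c(should, list(term_clause(kw, "abstract", boost = 1)))
  }
  bool_query(must = must, should = should)
}

#' Retrieve candidate articles for a topic
#'
#' Executes the expanded boolean topic query and truncates to the candidate
#' cap. The returned score is the retrieval (`es`) feature of each hit.
#'
#' @inheritParams build_topic_query
#' @param params optional [bm25_params()].
#' @return `data.frame(article, score)` in rank order, at most `config$cap`
#'   rows.
#' @export
retrieve_candidates <- function(topic, table = synonym_table(), index,
                                config = retriever_config(),
                                params = index$params) {
  q <- build_topic_query(topic, table, index, config)
  execute_query(index, q, limit = config$cap, params = params)
}
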