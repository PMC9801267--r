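#' Construct an article collection
#'
#' An article collection is a `data.frame` with one row per literature record
#' and columns `id` (unique PMID-like string), `title`, `abstract` (possibly
#' empty), `pub_types` (list column of character vectors of publication-type
#' labels) and `citation_count` (non-negative integer). Unknown
#' publication-type labels are retained verbatim; downstream scoring maps
#' unknowns to 0.
#'
#' @param id character vector of unique, non-empty record identifiers.
#' @param title character vector of titles.
#' @param abstract character vector of abstracts; `NA` becomes `""`.
#' @param pub_types list of character vectors (one per record), or `NULL`.
#' @param citation_count integer vector of non-negative counts, or `NULL`.
#' @return A `data.frame` of class `article_collection`.
#' @export
article_collection <- function(id, title, abstract = "", pub_types = NULL,
                               citation_count = NULL) {
  n <- length(id)
  id <- as.character(id)
  if (any(!nzchar(id)) || anyNA(id)) {
    stop("article ids must be non-empty strings")
  }
  if (anyDuplicated(id)) {
    stop("duplicate article id: ", id[duplicated(id)][1L])
  }
  title <- rep_len(as.character(title), n)
  abstract <- rep_len(as.character(abstract), n)
  abstract[is.na(abstract)] <- ""
  title[is.na(title)] <- ""
  if (is.null(pub_types)) pub_types <- rep(list(character(0)), n)
  if (length(pub_types) != n) stop("pub_types must have one entry per record")
  pub_types <- lapply(pub_types, function(p) as.character(p[!is.na(p) & nzchar(p)]))
  if (is.null(citation_count)) citation_count <- integer(n)
  citation_count <- rep_len(as.integer(citation_count), n)
  citation_count[is.na(citation_count)] <- 0L
  if (any(citation_count < 0L)) stop("citation_count must be >= 0")
  out <- data.frame(id = id, title = title, abstract = abstract,
                    citation_count = citation_count, stringsAsFactors = FALSE)
  out$pub_types <- pub_types
  class(out) <- c("article_collection", "data.frame")
  out
}

#' Read an article collection
#'
#' Two dialects are supported. `"record-lines"` is one JSON object per line
#' with fields `id`, `title`, `abstract`, `pub_types`, `citation_count`;
#' missing `abstract` becomes `""`, missing `pub_types` the empty set and
#' missing `citation_count` 0. `"medline-xml"` parses a MEDLINE/PubMed XML
#' subset (`PMID`, `ArticleTitle`, `AbstractText`, `PublicationType`); the
#' XML carries no citation counts, so those can be merged from a two-column
#' sidecar table via `citations`.
#'
#' @param path file to read.
#' @param dialect `"record-lines"` (default) or `"medline-xml"`.
#' @param citations optional path to a tab-separated `id<TAB>count` sidecar
#'   table of citation counts (used for either dialect).
#' @return An [article_collection()].
#' @export
read_article_collection <- function(path, dialect = c("record-lines", "medline-xml"),
                                    citations = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  coll <- switch(dialect,
    "record-lines" = .read_record_lines(path),
    "medline-xml" = .read_medline_xml(path)
  )
  if (!is.null(citations)) {
    ct <- utils::read.table(citations, sep = "\t", header = FALSE,
                            col.names = c("id", "count"),
                            colClasses = c("character", "integer"))
    m <- match(coll$id, ct$id)
    coll$citation_count[!is.na(m)] <- ct$count[m[!is.na(m)]]
  }
  coll
}

.read_record_lines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    return(article_collection(character(0), character(0)))
  }
  recs <- lapply(seq_along(lines), function(i) {
    rec <- tryCatch(jsonlite::fromJSON(lines[[i]]),
                    error = function(e) stop("malformed record at line ", i, ": ",
                                             conditionMessage(e), call. = FALSE))
    if (is.null(rec$id) || !nzchar(as.character(rec$id)[1L])) {
      stop("malformed record at line ", i, ": missing field 'id'", call. = FALSE)
    }
    if (is.null(rec$title)) {
      stop("malformed record at line ", i, ": missing field 'title'", call. = FALSE)
    }
    rec
  })
  article_collection(
    id = vapply(recs, function(r) as.character(r$id)[1L], character(1)),
    title = vapply(recs, function(r) as.character(r$title)[1L], character(1)),
    abstract = vapply(recs, function(r) {
      if (is.null(r$abstract)) "" else as.character(r$abstract)[1L]
    }, character(1)),
    pub_types = lapply(recs, function(r) {
      if (is.null(r$pub_types)) character(0) else as.character(unlist(r$pub_types))
    }),
    citation_count = vapply(recs, function(r) {
      if (is.null(r$citation_count)) 0L else as.integer(r$citation_count)[1L]
    }, integer(1))
  )
}

.read_medline_xml <- function(path) {
  doc <- xml2::read_xml(path)
  arts <- xml2::xml_find_all(doc, ".//MedlineCitation")
  if (length(arts) == 0L) return(article_collection(character(0), character(0)))
  one <- function(node, xpath) {
    hit <- xml2::xml_find_first(node, xpath)
    if (inherits(hit, "xml_missing")) "" else xml2::xml_text(hit)
  }
  article_collection(
    id = vapply(arts, one, character(1), xpath = "./PMID"),
    title = vapply(arts, one, character(1), xpath = ".//ArticleTitle"),
    abstract = vapply(arts, function(a) {
      paste(xml2::xml_text(xml2::xml_find_all(a, ".//Abstract/AbstractText")),
            collapse = " ")
    }, character(1)),
    pub_types = lapply(arts, function(a) {
      xml2::xml_text(xml2::xml_find_all(a, ".//PublicationTypeList/PublicationType"))
    })
  )
}

#' Write an article collection as record-lines (JSON per line)
#'
#' @param collection an [article_collection()].
#' @param path output file.
#' @export
write_article_collection <- function(collection, path) {
  lines <- vapply(seq_len(nrow(collection)), function(i) {
    jsonlite::toJSON(list(
      id = collection$id[i],
      title = collection$title[i],
      abstract = collection$abstract[i],
      pub_types = collection$pub_types[[i]],
      citation_count = collection$citation_count[i]
    ), auto_unbox = TRUE)
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read precision-medicine topics
#'
#' Topics are delimited lines `id, disease, gene, treatment`. The delimiter is
#' auto-detected per line, tab preferred over comma. Order is preserved.
#'
#' @param path topic file.
#' @return `data.frame` with columns `id` (integer), `disease`, `gene`,
#'   `treatment`.
#' @export
read_topics <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    return(data.frame(id = integer(0), disease = character(0),
                      gene = character(0), treatment = character(0),
                      stringsAsFactors = FALSE))
  }
  rows <- lapply(seq_along(lines), function(i) {
    ln <- lines[[i]]
    parts <- if (grepl("\t", ln)) strsplit(ln, "\t")[[1]] else strsplit(ln, ",")[[1]]
    parts <- trimws(parts)
    if (length(parts) != 4L || any(!nzchar(parts))) {
      stop("topic line ", i, ": expected 4 non-empty fields, got ",
           length(parts), call. = FALSE)
    }
    id <- suppressWarnings(as.integer(parts[1L]))
    if (is.na(id)) stop("topic line ", i, ": non-integer id '", parts[1L], "'",
                        call. = FALSE)
    list(id = id, disease = parts[2L], gene = parts[3L], treatment = parts[4L])
  })
  data.frame(
    id = vapply(rows, `[[`, integer(1), "id"),
    disease = vapply(rows, `[[`, character(1), "disease"),
    gene = vapply(rows, `[[`, character(1), "gene"),
    treatment = vapply(rows, `[[`, character(1), "treatment"),
    stringsAsFactors = FALSE
  )
}

#' Read / write TREC qrels
#'
#' Qrels are whitespace-delimited 4-column lines `topic 0 docid tier`, one
#' graded relevance judgment per (topic, document) pair, tiers on the 5-point
#' scale 0..4.
#'
#' @param path qrels file.
#' @return `data.frame` of class `judgment_set` with columns `topic`
#'   (integer), `article` (character), `tier` (integer in 0..4).
#' @export
read_qrels <- function(path) {
  tab <- utils::read.table(path, header = FALSE, colClasses = "character",
                           col.names = c("topic", "iter", "article", "tier"))
  judgment_set(topic = as.integer(tab$topic), article = tab$article,
               tier = suppressWarnings(as.integer(tab$tier)))
}

#' @param topic,article,tier parallel vectors of judgments.
#' @rdname read_qrels
#' @export
judgment_set <- function(topic = integer(0), article = character(0),
                         tier = integer(0)) {
  tier <- as.integer(tier)
  if (anyNA(tier) || any(tier < 0L | tier > 4L)) {
    stop("relevance tiers must be integers in 0..4")
  }
  out <- data.frame(topic = as.integer(topic), article = as.character(article),
                    tier = tier, stringsAsFactors = FALSE)
  if (anyDuplicated(out[c("topic", "article")])) {
    stop("duplicate (topic, article) judgment")
  }
  class(out) <- c("judgment_set", "data.frame")
  out
}

#' @param qrels a `judgment_set`.
#' @rdname read_qrels
#' @export
write_qrels <- function(qrels, path) {
  writeLines(sprintf("%d 0 %s %d", qrels$topic, qrels$article, qrels$tier), path)
  invisible(path)
}

#' Look up judged tiers
#'
#' @param qrels a `judgment_set`.
#' @param topic topic id (scalar).
#' @param article character vector of article ids.
#' @return integer tiers, `NA` where the pair is unjudged.
#' @export
judged_tier <- function(qrels, topic, article) {
  sub <- qrels[qrels$topic == topic, , drop = FALSE]
  sub$tier[match(article, sub$article)]
}

# maximum run length per topic allowed in submissions
RUN_CAP <- 1000L

#' Read / write TREC run files
#'
#' A run is an ordered, scored document list per topic, serialised in the
#' 6-column TREC format `topic Q0 docid rank score tag`. Ranks must be
#' consecutive from 1, scores non-increasing with rank, article ids unique
#' per topic, and at most 1000 documents per topic.
#'
#' @param run `data.frame` with columns `topic`, `article`, `rank`, `score`
#'   and optionally `tag`.
#' @param path run file.
#' @param tag run tag written in column 6 (defaults to the run's `tag`
#'   column, else `"run"`).
#' @return `read_run()` returns the run `data.frame`; `write_run()` the path.
#' @export
write_run <- function(run, path, tag = NULL) {
  validate_run(run)
  if (is.null(tag)) tag <- if (!is.null(run$tag)) run$tag[1L] else "run"
  writeLines(sprintf("%d Q0 %s %d %.10g %s",
                     run$topic, run$article, run$rank, run$score, tag), path)
  invisible(path)
}

#' @rdname write_run
#' @export
read_run <- function(path) {
  tab <- utils::read.table(path, header = FALSE, colClasses = "character",
                           col.names = c("topic", "q0", "article", "rank",
                                         "score", "tag"))
  run <- data.frame(topic = as.integer(tab$topic), article = tab$article,
                    rank = as.integer(tab$rank), score = as.numeric(tab$score),
                    tag = tab$tag, stringsAsFactors = FALSE)
  validate_run(run)
  run
}

#' Validate run-ranking invariants
#'
#' @param run a run `data.frame`.
#' @return the run, invisibly; errors when an invariant fails.
#' @export
validate_run <- function(run) {
  for (tid in unique(run$topic)) {
    sub <- run[run$topic == tid, , drop = FALSE]
    sub <- sub[order(sub$rank), , drop = FALSE]
    if (nrow(sub) > RUN_CAP) {
      stop("topic ", tid, ": ", nrow(sub), " entries exceed the ", RUN_CAP,
           "-document run cap")
    }
    if (!identical(sub$rank, seq_len(nrow(sub)))) {
      stop("topic ", tid, ": ranks must be consecutive from 1")
    }
    if (is.unsorted(rev(sub$score))) {
      stop("topic ", tid, ": scores must be non-increasing with rank")
    }
    if (anyDuplicated(sub$article)) {
      stop("topic ", tid, ": duplicate article ids in run")
    }
  }
  invisible(run)
}
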