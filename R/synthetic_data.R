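# run expr under a temporary RNG state seeded with `seed`
.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", .GlobalEnv)) {
    get(".Random.seed", .GlobalEnv)
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
          else suppressWarnings(rm(".Random.seed", envir = .GlobalEnv)))
  set.seed(seed)
  force(expr)
}

#' Synthetic-benchmark generator configuration
#'
#' The generator emulates the statistical structure the retrieval pipeline
#' assumes: topic concepts mentioned through synonyms at a controlled rate,
#' five evidence tiers driven monotonically by concept-match quality,
#' publication type and citation standing, and a heavy-tailed citation
#' distribution. Defaults give the package's standard benchmark: 5000
#' documents, 10 topics.
#'
#' @param n_docs number of documents (default 5000).
#' @param n_topics number of topics (default 10).
#' @param vocab_size background vocabulary size (default 2000).
#' @param synonyms_per_concept non-canonical synonyms per disease/gene
#'   concept (default 3).
#' @param substitution_rate probability that a concept mention uses a
#'   non-canonical synonym (default 0.3).
#' @param concept_doc_rate fraction of documents bearing some topic's
#'   concepts (default 0.3).
#' @param p_disease,p_gene,p_treatment probability that a concept-bearing
#'   document mentions each topic element (defaults 1.0, 0.7, 0.95).
#' @param tier_weights weights of (concept-match quality, normalized
#'   publication-type score, citation quantile) in the simulated expert's
#'   tier model (default `c(0.55, 0.30, 0.15)`).
#' @param tier_noise_sd bounded gaussian noise added to the expert's latent
#'   score before rounding (default 0: noiseless expert).
#' @param citation_meanlog,citation_sdlog discretized log-normal citation
#'   distribution parameters (defaults 1.5, 1.5).
#' @param pub_type_freqs named sampling frequencies over publication-type
#'   labels (defaults approximate MEDLINE composition over the 13 mapped
#'   labels).
#' @param title_len,abstract_len `c(min, max)` background token counts.
#' @param seed integer seed; all generation is bit-reproducible per seed.
#' @return list of class `synth_config`.
#' @export
synth_config <- function(n_docs = 5000L, n_topics = 10L, vocab_size = 2000L,
                         synonyms_per_concept = 3L, substitution_rate = 0.3,
                         concept_doc_rate = 0.3,
                         p_disease = 1.0, p_gene = 0.7, p_treatment = 0.95,
                         tier_weights = c(match = 0.55, ty = 0.30, ct = 0.15),
                         tier_noise_sd = 0,
                         citation_meanlog = 1.5, citation_sdlog = 1.5,
                         pub_type_freqs = NULL,
                         title_len = c(4L, 8L), abstract_len = c(40L, 80L),
                         seed = 7L) {
  if (is.null(pub_type_freqs)) {
    pub_type_freqs <- c("journal article" = 0.30, "review" = 0.12,
                        "clinical trial" = 0.12, "case reports" = 0.10,
                        "observational study" = 0.08, "letter" = 0.05,
                        "comment" = 0.06, "editorial" = 0.04,
                        "meta-analysis" = 0.06, "systematic review" = 0.05,
                        "english abstract" = 0.01,
                        "published erratum" = 0.005,
                        "retraction of publication" = 0.005)
  }
  stopifnot(n_docs >= 1L, n_topics >= 1L, vocab_size >= 10L,
            substitution_rate >= 0, substitution_rate <= 1,
            concept_doc_rate >= 0, concept_doc_rate <= 1,
            all(c(p_disease, p_gene, p_treatment) >= 0),
            all(c(p_disease, p_gene, p_treatment) <= 1),
            length(tier_weights) == 3L, all(tier_weights >= 0),
            tier_noise_sd >= 0, abs(sum(pub_type_freqs) - 1) < 1e-8)
  structure(as.list(environment()), class = "synth_config")
}

# concept token vocabularies for one config
.concept_terms <- function(config) {
  k <- seq_len(config$n_topics)
  syn <- function(prefix) {
    lapply(k, function(i) {
      sprintf("%s%02dv%d", prefix, i, seq_len(config$synonyms_per_concept))
    })
  }
  list(disease = sprintf("disease%02d", k), disease_syn = syn("dsyn"),
       gene = sprintf("gene%02d", k), gene_syn = syn("gsyn"),
       treatment = sprintf("drug%02d", k))
}

#' Generate a synthetic corpus with ground-truth concept assignments
#'
#' Documents are background tokens plus, for concept-bearing documents, the
#' topic's disease/gene/treatment tokens, each drawn canonical-or-synonym
#' per the substitution rate. Mentions always appear in the abstract and
#' with probability 0.5 also in the title; the title additionally carries
#' the tokens of the document's publication-type label (as real titles do).
#' Publication types and citation counts are drawn from the configured
#' distributions.
#'
#' @param config a [synth_config()].
#' @return list with `articles` (an [article_collection()]), `topics`
#'   (topic `data.frame`), `synonyms` (a [synonym_table()] over disease and
#'   gene terms), and `truth` (`data.frame` per concept-bearing document:
#'   `topic`, `article`, `has_d`, `has_g`, `has_t`, `match_q`).
#' @export
generate_corpus <- function(config = synth_config()) {
  .with_seed(config$seed, {
    terms <- .concept_terms(config)
    vocab <- sprintf("w%04d", seq_len(config$vocab_size))
    n <- config$n_docs
    ids <- sprintf("PM%05d", seq_len(n))
    bearing <- stats::runif(n) < config$concept_doc_rate
    topic_of <- ifelse(bearing, sample.int(config$n_topics, n, replace = TRUE),
                       0L)
    ptypes <- sample(names(config$pub_type_freqs), n, replace = TRUE,
                     prob = config$pub_type_freqs)
    citations <- as.integer(floor(stats::rlnorm(n, config$citation_meanlog,
                                                config$citation_sdlog)))
    has_d <- bearing & stats::runif(n) < config$p_disease
    has_g <- bearing & stats::runif(n) < config$p_gene
    has_t <- bearing & stats::runif(n) < config$p_treatment

    pick_mention <- function(topic, canonical, synonyms) {
      if (stats::runif(1) < config$substitution_rate &&
          config$synonyms_per_concept > 0L) {
        sample(synonyms[[topic]], 1L)
      } else {
        canonical[topic]
      }
    }
    titles <- character(n)
    abstracts <- character(n)
    for (i in seq_len(n)) {
      mentions <- character(0)
      if (has_d[i]) {
        mentions <- c(mentions, pick_mention(topic_of[i], terms$disease,
                                             terms$disease_syn))
      }
      if (has_g[i]) {
        mentions <- c(mentions, pick_mention(topic_of[i], terms$gene,
                                             terms$gene_syn))
      }
      if (has_t[i]) mentions <- c(mentions, terms$treatment[topic_of[i]])
      tl <- sample(seq.int(config$title_len[1L], config$title_len[2L]), 1L)
      al <- sample(seq.int(config$abstract_len[1L], config$abstract_len[2L]), 1L)
      title <- c(sample(vocab, tl, replace = TRUE),
                 mentions[stats::runif(length(mentions)) < 0.5],
                 tokenize(ptypes[i]))
      kw <- character(0)
      if (stats::runif(1) < 0.4) kw <- c(kw, "patient")
      trial_ish <- ptypes[i] %in% c("clinical trial", "meta-analysis",
                                    "systematic review")
      if (stats::runif(1) < (if (trial_ish) 0.6 else 0.1)) kw <- c(kw, "trial")
      abstract <- c(sample(vocab, al, replace = TRUE),
                    rep(mentions, sample(1:2, 1L)), kw)
      titles[i] <- paste(title, collapse = " ")
      abstracts[i] <- paste(sample(abstract), collapse = " ")
    }
    articles <- article_collection(ids, titles, abstracts,
                                   pub_types = as.list(ptypes),
                                   citation_count = citations)
    topics <- data.frame(id = seq_len(config$n_topics),
                         disease = terms$disease, gene = terms$gene,
                         treatment = terms$treatment, stringsAsFactors = FALSE)
    syn_tab <- c(
      stats::setNames(lapply(seq_len(config$n_topics), function(i) {
        c(terms$disease[i], terms$disease_syn[[i]])
      }), terms$disease),
      stats::setNames(lapply(seq_len(config$n_topics), function(i) {
        c(terms$gene[i], terms$gene_syn[[i]])
      }), terms$gene)
    )
    keep <- which(bearing)
    truth <- data.frame(topic = topic_of[keep], article = ids[keep],
                        has_d = has_d[keep], has_g = has_g[keep],
                        has_t = has_t[keep],
                        match_q = (has_d[keep] + has_g[keep] + has_t[keep]) / 3,
                        stringsAsFactors = FALSE)
    list(articles = articles, topics = topics,
         synonyms = synonym_table(syn_tab), truth = truth)
  })
}

#' Simulated expert annotator
#'
#' Assigns an evidence tier to every (topic, concept-bearing article) pair
#' as a clamped, rounded monotone function of concept-match quality, the
#' normalized publication-type score and the citation quantile, plus
#' optional bounded gaussian noise. Non-bearing pairs are tier 0. The
#' resulting annotator is deterministic: all (noised) tiers are drawn once
#' at construction.
#'
#' @param corpus output of [generate_corpus()].
#' @param config the [synth_config()] used (supplies tier weights, noise and
#'   seed).
#' @return list of class `simulated_expert` with a `tier` lookup table.
#' @export
simulated_expert <- function(corpus, config = synth_config()) {
  w <- config$tier_weights / sum(config$tier_weights)
  truth <- corpus$truth
  m <- match(truth$article, corpus$articles$id)
  ty <- vapply(corpus$articles$pub_types[m], publication_type_score, integer(1))
  ctq <- citation_quantile(corpus$articles$citation_count[m],
                           corpus$articles$citation_count)
  s <- w[1L] * truth$match_q + w[2L] * (ty + 2) / 4 + w[3L] * ctq
  noise <- if (config$tier_noise_sd > 0) {
    .with_seed(config$seed + 1L,
               pmax(-1, pmin(1, stats::rnorm(nrow(truth), 0,
                                             config$tier_noise_sd))))
  } else {
    numeric(nrow(truth))
  }
  tier <- pmax(0L, pmin(4L, as.integer(round(4 * s + noise))))
  structure(list(
    tiers = stats::setNames(tier, paste(truth$topic, truth$article)),
    weights = w
  ), class = "simulated_expert")
}

#' @param expert a `simulated_expert`.
#' @param topic,article pair to rate.
#' @rdname simulated_expert
#' @export
expert_tier <- function(expert, topic, article) {
  tier <- unname(expert$tiers[paste(topic, article)])
  ifelse(is.na(tier), 0L, as.integer(tier))
}

#' Truth judgments from the simulated expert
#'
#' One graded judgment per (topic, concept-bearing article) pair at the
#' expert's tier, plus (as in real assessment pools) a deterministic sample
#' of non-bearing articles judged tier 0 per topic. Articles outside the
#' pool are unjudged (evaluation treats them as tier 0).
#'
#' @param corpus output of [generate_corpus()].
#' @param expert a [simulated_expert()].
#' @param config the [synth_config()] used (supplies the seed).
#' @param n_zero judged tier-0 non-bearing articles per topic (default 30).
#' @return a [judgment_set()].
#' @export
generate_truth_qrels <- function(corpus, expert, config = synth_config(),
                                 n_zero = 30L) {
  nonbearing <- setdiff(corpus$articles$id, unique(corpus$truth$article))
  zero <- .with_seed(config$seed + 2L, {
    do.call(rbind, lapply(seq_len(nrow(corpus$topics)), function(tid) {
      pick <- sample(nonbearing, min(n_zero, length(nonbearing)))
      data.frame(topic = tid, article = pick, stringsAsFactors = FALSE)
    }))
  })
  judgment_set(
    topic = c(corpus$truth$topic, zero$topic),
    article = c(corpus$truth$article, zero$article),
    tier = c(expert_tier(expert, corpus$truth$topic, corpus$truth$article),
             rep(0L, nrow(zero)))
  )
}

#' Oracle over a simulated expert
#'
#' Wraps a [simulated_expert()] into the annotation-oracle contract; its
#' answers equal the truth-qrels tiers, enabling closed-loop tests whose
#' held-out evaluation uses the same noiseless truth.
#'
#' @param expert a [simulated_expert()].
#' @return an oracle for [run_iteration()] / [run_loop()].
#' @export
make_oracle <- function(expert) {
  function_oracle(function(topic, article) expert_tier(expert, topic, article))
}

#' Generate the full synthetic benchmark
#'
#' Corpus, topics, synonym table, simulated expert and truth qrels in one
#' call.
#'
#' @param config a [synth_config()].
#' @return list with `articles`, `topics`, `synonyms`, `truth`, `expert`,
#'   `qrels`, `oracle` and the `config`.
#' @export
generate_benchmark <- function(config = synth_config()) {
  corpus <- generate_corpus(config)
  expert <- simulated_expert(corpus, config)
  c(corpus, list(expert = expert,
                 qrels = generate_truth_qrels(corpus, expert, config),
                 oracle = make_oracle(expert), config = config))
}
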