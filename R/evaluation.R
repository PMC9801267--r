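#' Gain maps for graded relevance
#'
#' Maps the five evidence tiers 0..4 to gains: `"standard"` uses 0,1,2,3,4
#' and `"exponential"` 0,1,2,4,8.
#'
#' @param name `"standard"` or `"exponential"`, or a numeric vector of length
#'   5 (gain of tier 0 first, must start at 0 and be non-decreasing).
#' @return numeric vector of length 5 (gain of tiers 0..4).
#' @export
gain_map <- function(name = c("standard", "exponential")) {
  if (is.numeric(name)) {
    stopifnot(length(name) == 5L, name[1L] == 0, !is.unsorted(name))
    return(as.numeric(name))
  }
  switch(match.arg(name),
         standard = c(0, 1, 2, 3, 4),
         exponential = c(0, 1, 2, 4, 8))
}

# ranked article ids for one topic out of a run data.frame
.topic_ranking <- function(run, topic) {
  sub <- run[run$topic == topic, , drop = FALSE]
  sub$article[order(sub$rank)]
}

#' Precision at rank k
#'
#' Fraction of the top `k` ranked documents that are relevant. A judged
#' document is relevant when its tier reaches `threshold`; unjudged
#' documents count as irrelevant. Rankings shorter than `k` (including empty
#' ones) keep the divisor `k`.
#'
#' @param ranking character vector of article ids in rank order.
#' @param qrels a [judgment_set()].
#' @param topic topic id.
#' @param k cutoff rank (default 10).
#' @param threshold minimum relevant tier (default 1).
#' @return precision in \[0, 1\].
#' @export
precision_at_k <- function(ranking, qrels, topic, k = 10L, threshold = 1L) {
  stopifnot(k >= 1L)
  if (length(ranking) == 0L) return(0)
  top <- utils::head(ranking, k)
  tiers <- judged_tier(qrels, topic, top)
  sum(!is.na(tiers) & tiers >= threshold) / k
}

#' R-precision
#'
#' Precision at rank `R`, where `R` is the number of relevant (tier >=
#' `threshold`) judged documents for the topic. `R = 0` returns 0 by
#' convention.
#'
#' @inheritParams precision_at_k
#' @return precision in \[0, 1\].
#' @export
r_precision <- function(ranking, qrels, topic, threshold = 1L) {
  sub <- qrels[qrels$topic == topic, , drop = FALSE]
  R <- sum(sub$tier >= threshold)
  if (R == 0L) return(0)
  precision_at_k(ranking, qrels, topic, k = R, threshold = threshold)
}

# discount of rank i
.dcg_discount <- function(i) 1 / log2(i + 1)

#' Normalized discounted cumulative gain at rank k
#'
#' `DCG_k = sum_{i=1..k} gain(rel_i) / log2(i + 1)` (rank-1 discount 1);
#' unjudged documents contribute gain 0. The ideal DCG reorders all judged
#' documents of the topic by tier. `IDCG = 0` yields 0.
#'
#' @inheritParams precision_at_k
#' @param gains a [gain_map()] (name or 5-vector).
#' @param k cutoff rank (default 30).
#' @return NDCG in \[0, 1\].
#' @export
ndcg_at_k <- function(ranking, qrels, topic, k = 30L, gains = "standard") {
  stopifnot(k >= 1L)
  g <- gain_map(gains)
  top <- utils::head(ranking, k)
  tiers <- judged_tier(qrels, topic, top)
  tiers[is.na(tiers)] <- 0L
  dcg <- sum(g[tiers + 1L] * .dcg_discount(seq_along(top)))
  judged <- sort(qrels$tier[qrels$topic == topic], decreasing = TRUE)
  ideal <- utils::head(g[judged + 1L], k)
  idcg <- sum(ideal * .dcg_discount(seq_along(ideal)))
  if (idcg == 0) 0 else dcg / idcg
}

#' Sample a stratified judgment pool
#'
#' Emulates the two-stratum assessment protocol: every document in the fully
#' judged top stratum (ranks 1..`depth`) is judged, and each document in the
#' sampled stratum (`stratum[1]`..`stratum[2]`) is judged independently with
#' probability `p`. Deterministic per seed.
#'
#' @param ranking character vector of article ids in rank order (length >=
#'   `depth`).
#' @param qrels truth [judgment_set()] supplying the tiers of sampled
#'   documents.
#' @param topic topic id.
#' @param depth fully judged depth (default 30).
#' @param stratum sampled stratum rank bounds (default `c(31, 100)`).
#' @param p sampling rate in (0, 1\] (default 0.25).
#' @param seed integer seed.
#' @return list of class `sampled_judgments`: `depth`, `stratum`, `p`,
#'   `seed`, and `judged`, a `data.frame(rank, article, tier)` covering the
#'   top stratum plus the sampled subset.
#' @export
sample_judgment_pool <- function(ranking, qrels, topic, depth = 30L,
                                 stratum = c(31L, 100L), p = 0.25,
                                 seed = 1L) {
  stopifnot(p > 0, p <= 1, length(ranking) >= depth,
            stratum[1L] == depth + 1L, stratum[2L] >= stratum[1L])
  top_ranks <- seq_len(min(depth, length(ranking)))
  strat_ranks <- seq.int(stratum[1L], min(stratum[2L], length(ranking)))
  if (length(strat_ranks) > 0L) {
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
    set.seed(seed)
    keep <- stats::runif(length(strat_ranks)) < p
    if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
    strat_ranks <- strat_ranks[keep]
  }
  ranks <- c(top_ranks, strat_ranks)
  arts <- ranking[ranks]
  tiers <- judged_tier(qrels, topic, arts)
  tiers[is.na(tiers)] <- 0L
  structure(list(depth = depth, stratum = stratum, p = p, seed = seed,
                 judged = data.frame(rank = ranks, article = arts,
                                     tier = tiers, stringsAsFactors = FALSE)),
            class = "sampled_judgments")
}

#' Inferred NDCG from stratified sampled judgments
#'
#' Estimates NDCG over the pooled depth (top stratum + sampled stratum) from
#' a [sample_judgment_pool()]. The DCG estimate sums the judged gains of the
#' top stratum exactly; in the sampled stratum, judged positions use their
#' gain and unjudged positions are imputed with the mean gain of the judged
#' documents of that stratum (0 when none is judged, with a warning). The
#' ideal DCG is built from the judged gains with sampled-stratum gain counts
#' inflated to the stratum size (`n_stratum / n_judged`, the self-normalized
#' form of `1/p` inflation: identical in expectation and at `p = 1`, with
#' lower variance), laid out over fractional rank occupancies.
#'
#' Ratio estimators of this kind carry a small `O(1/n_judged)` bias; by
#' default a parametric-bootstrap correction is applied: the judged stratum
#' composition is expanded into a pseudo-truth over the full stratum, the
#' sampling design is re-simulated on it `n_boot` times (deterministically,
#' seeded from the pool's seed), and the measured pseudo-bias is subtracted.
#' At `p = 1` with full judgments the estimate equals exact NDCG
#' bit-for-bit.
#'
#' @param ranking character vector of article ids in rank order.
#' @param sampled a `sampled_judgments` object.
#' @param gains a [gain_map()].
#' @param correct_bias apply the bootstrap bias correction (default `TRUE`).
#' @param n_boot bootstrap replicates for the correction (default 80).
#' @return estimated NDCG.
#' @export
inferred_ndcg <- function(ranking, sampled, gains = "standard",
                          correct_bias = TRUE, n_boot = 80L) {
  g <- gain_map(gains)
  jd <- sampled$judged
  depth_all <- min(sampled$stratum[2L], length(ranking))
  top <- jd[jd$rank <= sampled$depth, , drop = FALSE]
  strat <- jd[jd$rank > sampled$depth, , drop = FALSE]
  n_strat <- max(0L, depth_all - sampled$depth)
  if (n_strat > 0L && nrow(strat) == 0L) {
    warning("no judged documents in the sampled stratum; imputing gain 0")
  }
  disc <- .dcg_discount(seq_len(depth_all))
  cumd <- c(0, cumsum(disc))
  est <- .infndcg_plugin(g, top$tier, top$rank, strat$tier, strat$rank,
                         sampled$depth, depth_all, disc, cumd)
  if (correct_bias && sampled$p < 1 && n_strat > 0L && nrow(strat) >= 2L) {
    # pseudo-truth: judged tiers at their ranks, unjudged ranks filled by
    # cycling the judged tier sequence; re-simulate the design on it
    pseudo <- integer(n_strat)
    sr <- strat$rank - sampled$depth
    pseudo[sr] <- strat$tier
    unj <- setdiff(seq_len(n_strat), sr)
    pseudo[unj] <- strat$tier[((seq_along(unj) - 1L) %% nrow(strat)) + 1L]
    full <- .infndcg_plugin(g, top$tier, top$rank, pseudo,
                            sampled$depth + seq_len(n_strat),
                            sampled$depth, depth_all, disc, cumd)
    boots <- .with_seed(sampled$seed + 10457L, {
      vapply(seq_len(n_boot), function(k) {
        keep <- which(stats::runif(n_strat) < sampled$p)
        if (length(keep) == 0L) keep <- 1L
        .infndcg_plugin(g, top$tier, top$rank, pseudo[keep],
                        sampled$depth + keep, sampled$depth, depth_all,
                        disc, cumd)
      }, numeric(1))
    })
    est <- est - (mean(boots) - full)
  }
  est
}

# plug-in inferred-NDCG estimate from judged tiers at their ranks.
# disc: discount vector over 1..depth_all; cumd: c(0, cumsum(disc)).
.infndcg_plugin <- function(g, top_tiers, top_ranks, strat_tiers, strat_ranks,
                            depth, depth_all, disc, cumd) {
  contrib <- numeric(depth_all)
  contrib[top_ranks] <- g[top_tiers + 1L] * disc[top_ranks]
  n_strat <- depth_all - depth
  n <- length(strat_tiers)
  if (n_strat > 0L) {
    mean_gain <- if (n) mean(g[strat_tiers + 1L]) else 0
    strat_contrib <- rep(mean_gain, n_strat)
    strat_contrib[strat_ranks - depth] <- g[strat_tiers + 1L]
    contrib[(depth + 1L):depth_all] <- strat_contrib *
      disc[(depth + 1L):depth_all]
  }
  dcg <- sum(contrib)
  gains_all <- c(g[top_tiers + 1L], g[strat_tiers + 1L])
  wts <- c(rep(1, length(top_tiers)),
           rep(if (n) n_strat / n else 0, n))
  ord <- order(-gains_all)
  gains_all <- gains_all[ord]
  wts <- wts[ord]
  if (all(wts == 1)) {
    # integer unit occupancies: use the exact discounts term by term so that
    # a fully judged pool reproduces exact NDCG bit for bit
    len <- min(length(gains_all), depth_all)
    idcg <- sum(gains_all[seq_len(len)] * disc[seq_len(len)])
  } else {
    pos <- pmin(cumsum(wts), depth_all)
    lower <- pmin(c(0, pos[-length(pos)]), depth_all)
    cum_at <- function(x) {
      fl <- floor(x)
      frac <- x - fl
      cumd[fl + 1L] + ifelse(frac > 0, frac * disc[pmin(fl + 1L, depth_all)], 0)
    }
    idcg <- sum(gains_all * (cum_at(pos) - cum_at(lower)))
  }
  if (idcg == 0) 0 else dcg / idcg
}

#' Evaluate a run against judgments
#'
#' Computes topic-wise metric values and their mean over topics.
#' Available metrics: `p10`, `rprec`, `ndcg<k>-std`, `ndcg<k>-exp` (any
#' cutoff k, e.g. `ndcg30-exp`), and `infndcg` (inferred NDCG under a
#' stratified sample of the truth judgments, standard gains).
#'
#' @param run run `data.frame` (columns `topic`, `article`, `rank`, `score`).
#' @param qrels a [judgment_set()].
#' @param metrics character vector of metric names.
#' @param seed seed for the infNDCG judgment-pool sample.
#' @return `data.frame` with one row per (topic, metric) plus a `"mean"` row
#'   per metric.
#' @export
evaluate_run <- function(run, qrels, metrics = c("p10", "rprec", "ndcg30-std",
                                                 "ndcg30-exp"),
                         seed = 1L) {
  topics <- sort(unique(run$topic))
  rows <- list()
  for (m in metrics) {
    vals <- vapply(topics, function(tid) {
      rk <- .topic_ranking(run, tid)
      if (m == "p10") return(precision_at_k(rk, qrels, tid, k = 10L))
      if (m == "rprec") return(r_precision(rk, qrels, tid))
      if (m == "infndcg") {
        if (length(rk) < 30L) return(ndcg_at_k(rk, qrels, tid, k = 100L))
        sj <- sample_judgment_pool(rk, qrels, tid, seed = seed + tid)
        return(inferred_ndcg(rk, sj))
      }
      mm <- regmatches(m, regexec("^ndcg([0-9]+)-(std|exp)$", m))[[1]]
      if (length(mm) == 3L) {
        gains <- if (mm[3L] == "std") "standard" else "exponential"
        return(ndcg_at_k(rk, qrels, tid, k = as.integer(mm[2L]), gains = gains))
      }
      stop("unknown metric: ", m)
    }, numeric(1))
    rows[[m]] <- data.frame(metric = m,
                            topic = c(as.character(topics), "mean"),
                            value = c(vals, mean(vals)),
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
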