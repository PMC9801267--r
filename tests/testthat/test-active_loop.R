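test_that("annotation stores normalize labels and reject duplicates", {
  st <- annotation_store(topic = c(1L, 2L), article = c("A", "B"),
                         tier = c(4L, 0L), iteration = c(1L, 1L))
  expect_equal(mean_annotated_relevance(st), 0.5)
  expect_equal(mean_annotated_relevance(
    annotation_store(1L, "A", 4L, 1L)), 1)
  expect_error(mean_annotated_relevance(annotation_store()), "empty")
  expect_error(annotation_store(c(1L, 1L), c("A", "A"), c(1L, 2L), c(1L, 2L)),
               "duplicate")
  set.seed(41)
  tiers <- sample(0:4, 30, replace = TRUE)
  st2 <- annotation_store(rep(1:3, 10), sprintf("D%02d", 1:30), tiers,
                          rep(1:10, each = 3))
  expect_equal(mean_annotated_relevance(st2), mean(tiers / 4))
  path <- withr::local_tempfile()
  write_annotations(st2, path)
  expect_equal(read_annotations(path), st2, ignore_attr = TRUE)
})

test_that("top-1 selection picks the best unannotated document per topic", {
  rankings <- list("1" = c("A", "B", "C"), "2" = c("X", "Y"))
  empty <- annotation_store()
  sel <- select_for_annotation(rankings, empty)
  expect_equal(sel$article, c("A", "X"))
  st <- annotation_store(topic = 1L, article = "A", tier = 3L, iteration = 1L)
  sel2 <- select_for_annotation(rankings, st)
  expect_equal(sel2$article[sel2$topic == 1], "B")
  # exhausted topics contribute nothing
  st3 <- annotation_store(topic = c(2L, 2L), article = c("X", "Y"),
                          tier = c(1L, 2L), iteration = c(1L, 2L))
  sel3 <- select_for_annotation(rankings, st3)
  expect_equal(sel3$topic, 1L)
})

test_that("iterations grow the store by one per topic and record history", {
  b <- tiny_benchmark()
  base <- run_baseline(b$articles, b$topics, b$synonyms)
  st <- init_active_state(b$topics, base$candidates, b$articles,
                          config = loop_config(max_iter = 3L,
                                               stop_window = 99L))
  st1 <- run_iteration(st, b$oracle, qrels = b$qrels)
  expect_equal(nrow(st1$store), nrow(b$topics))
  st2 <- run_iteration(st1, b$oracle)
  expect_equal(nrow(st2$store), 2L * nrow(b$topics))
  expect_equal(st2$history$iteration, 1:2)
  expect_equal(st2$history$n_new, rep(nrow(b$topics), 2))
  expect_false(is.na(st1$history$heldout_ndcg30_exp[1]))
  # annotations equal the oracle's tiers
  expect_equal(st1$store$tier,
               vapply(seq_len(nrow(st1$store)), function(i) {
                 oracle_annotate(b$oracle, st1$store$topic[i],
                                 st1$store$article[i])
               }, integer(1)))
})

test_that("the loop respects the iteration budget and the stop rule", {
  b <- tiny_benchmark()
  base <- run_baseline(b$articles, b$topics, b$synonyms)
  st0 <- init_active_state(b$topics, base$candidates, b$articles,
                           config = loop_config(max_iter = 0L))
  out0 <- run_loop(st0, b$oracle)
  expect_null(out0$history)
  expect_null(out0$scorer$beta)

  st <- init_active_state(b$topics, base$candidates, b$articles,
                          config = loop_config(max_iter = 22L,
                                               stop_window = 2L))
  out <- run_loop(st, b$oracle)
  expect_lte(nrow(out$history), 22L)
  mr <- out$history$mean_relevance
  if (nrow(out$history) < 22L && nrow(out$history) >= 3L) {
    # the last stop_window iterations sit strictly below the running maximum
    n <- length(mr)
    expect_true(all(mr[(n - 1):n] < max(mr[1:(n - 2)])))
  }
})

test_that("a scheduled oracle triggers the stop rule exactly on time", {
  # single topic; candidate tiers scheduled so mean relevance peaks at
  # iteration 2 then declines: tiers 2, 4, 1, 0, 0, 0 ...
  coll <- article_collection(
    id = sprintf("C%02d", 1:8),
    title = rep("melanoma braf vemurafenib", 8),
    abstract = sprintf("filler text %d", 1:8),
    citation_count = 1:8
  )
  topics <- data.frame(id = 1L, disease = "melanoma", gene = "braf",
                       treatment = "vemurafenib", stringsAsFactors = FALSE)
  idx <- build_index(coll)
  hits <- retrieve_candidates(topics[1, ], synonym_table(), idx)
  feats <- extract_features(topics[1, ], hits, coll)
  sched <- c(2L, 4L, 1L, 0L, 0L, 0L, 0L, 0L)
  names(sched) <- sort(feats$article)  # annotation follows id-sorted ranks
  oracle <- function_oracle(function(topic, article) sched[[article]])
  st <- init_active_state(topics, list("1" = feats), coll,
                          config = loop_config(max_iter = 10L,
                                               stop_window = 2L))
  # identical candidate scores mean id-ascending rank order throughout
  out <- run_loop(st, oracle)
  mr <- out$history$mean_relevance
  # means: 2/4, 3/4, 7/12, 7/16 -> two consecutive declines after the peak
  expect_equal(mr[1:4], c(0.5, 0.75, 7 / 12, 7 / 16))
  expect_equal(nrow(out$history), 4L)
})

test_that("refitting on all annotations is insertion-order independent", {
  b <- tiny_benchmark()
  base <- run_baseline(b$articles, b$topics, b$synonyms)
  st <- init_active_state(b$topics, base$candidates, b$articles,
                          config = loop_config(max_iter = 4L,
                                               stop_window = 99L))
  out <- run_loop(st, b$oracle)
  store <- out$store
  texts <- vapply(seq_len(nrow(store)), function(i) {
    tid <- as.character(store$topic[i])
    out$candidate_text[[tid]][match(store$article[i],
                                    out$candidates[[tid]]$article)]
  }, character(1))
  qtexts <- unname(unlist(out$topic_texts[as.character(store$topic)]))
  perm <- sample(nrow(store))
  f1 <- scorer_fit(hash_scorer(), qtexts, texts, store$tier / 4)
  f2 <- scorer_fit(hash_scorer(), qtexts[perm], texts[perm],
                   store$tier[perm] / 4)
  expect_equal(f1$beta, f2$beta, tolerance = 1e-9)
})

test_that("learning improves held-out ranking quality with a noiseless oracle", {
  # small benchmark, 5 iterations: the full ranking after learning should
  # beat the es-only baseline ordering in held-out NDCG@30
  b <- tiny_benchmark(seed = 13L)
  base <- run_baseline(b$articles, b$topics, b$synonyms)
  st <- init_active_state(b$topics, base$candidates, b$articles,
                          config = loop_config(max_iter = 5L,
                                               stop_window = 99L))
  out <- run_loop(st, b$oracle, qrels = b$qrels)
  expect_gt(tail(out$history$heldout_ndcg30_exp, 1),
            mean_ndcg30_exp(base$run, b$qrels))
})
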