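test_that("publication-type scores follow the evidence map with max aggregation", {
  expect_equal(publication_type_score("meta-analysis"), 2L)
  expect_equal(publication_type_score("comment"), -1L)
  expect_equal(publication_type_score("published erratum"), -2L)
  expect_equal(publication_type_score(c("journal article", "clinical trial")), 2L)
  expect_equal(publication_type_score(c("comment", "letter")), 0L)
  expect_equal(publication_type_score(character(0)), 0L)
  expect_equal(publication_type_score("Something Unmapped"), 0L)
  expect_equal(publication_type_score("Meta-Analysis"), 2L)  # case-insensitive
  m <- pub_type_score_map()
  expect_true(all(m >= -2L & m <= 2L))
  expect_length(m, 13L)
})

test_that("citation quantiles are the empirical CDF with ties counted in", {
  expect_equal(citation_quantile(1, c(0, 1, 2, 3)), 0.5)
  expect_equal(citation_quantile(3, c(0, 1, 2, 3)), 1)
  expect_equal(citation_quantile(5, rep(5, 10)), 1)
  expect_equal(citation_quantile(0, c(0, 1, 2, 3)), 0.25)
  expect_equal(citation_quantile(c(0, 3), c(0, 1, 2, 3)), c(0.25, 1))
})

test_that("feature extraction wires es/pb/ty/ct together", {
  coll <- article_collection(
    id = c("A", "B"), title = c("egfr tumor", "egfr tumor trial"),
    abstract = c("gefitinib patient", "gefitinib"),
    pub_types = list("meta-analysis", "comment"),
    citation_count = c(10L, 2L)
  )
  idx <- build_index(coll)
  topic <- list(id = 1L, disease = "tumor", gene = "egfr",
                treatment = "gefitinib")
  hits <- retrieve_candidates(topic, synonym_table(), idx)
  f <- extract_features(topic, hits, coll)
  expect_equal(f$es, hits$score)
  expect_equal(f$pb, rep(0, nrow(f)))  # zero-scorer backend
  expect_equal(f$ty[f$article == "A"], 2L)
  expect_equal(f$ty[f$article == "B"], -1L)
  expect_equal(sort(f$ct), c(0.5, 1))
  # cross-module consistency: es equals the direct query score
  q <- build_topic_query(topic, synonym_table(), idx, retriever_config())
  expect_equal(f$es[1], score_query(idx, q, f$article[1]))
  # unknown article -> error
  bad <- hits
  bad$article[1] <- "MISSING"
  expect_error(extract_features(topic, bad, coll), "absent")
})

test_that("the linear regressor recovers planted coefficients", {
  # noiseless: labels = 2*es, everything else irrelevant
  set.seed(5)
  f <- data.frame(es = runif(50), pb = runif(50), ty = sample(-2:2, 50, TRUE),
                  ct = runif(50))
  fit <- fit_linear_regressor(f, 2 * f$es)
  expect_equal(unname(fit$coef), c(2, 0, 0, 0), tolerance = 1e-8)
  expect_equal(fit$intercept, 0, tolerance = 1e-8)

  # constant labels -> zero slopes, intercept = label
  fitc <- fit_linear_regressor(f, rep(0.7, 50))
  expect_equal(unname(fitc$coef), rep(0, 4), tolerance = 1e-10)
  expect_equal(fitc$intercept, 0.7, tolerance = 1e-10)

  # noisy recovery within 3 standard errors
  set.seed(6)
  beta <- c(es = 0.8, pb = -0.3, ty = 0.1, ct = 0.5)
  X <- data.frame(es = runif(500), pb = runif(500),
                  ty = sample(-2:2, 500, TRUE), ct = runif(500))
  y <- as.matrix(X) %*% beta + 0.25 + rnorm(500, 0, 0.05)
  fit2 <- fit_linear_regressor(X, y)
  expect_true(all(abs(fit2$coef - beta) <= 3 * fit2$se[-1]))
  expect_equal(predict_linear(fit2, X), drop(as.matrix(X) %*% fit2$coef) +
                 fit2$intercept)

  expect_error(fit_linear_regressor(X[1:4, ], y[1:4]), "at least 5")
})

test_that("rank-deficient designs yield the minimum-norm solution", {
  # pb duplicates es exactly: infinitely many LS solutions
  f <- data.frame(es = c(1, 2, 3, 4, 5), pb = c(1, 2, 3, 4, 5),
                  ty = 0, ct = 0)
  fit <- fit_linear_regressor(f, 2 * f$es)
  # minimum-norm splits the weight equally between the two aliased columns
  expect_equal(unname(fit$coef[1]), unname(fit$coef[2]), tolerance = 1e-8)
  expect_equal(predict_linear(fit, f), 2 * f$es, tolerance = 1e-8)
})

test_that("combiners apply the documented formulas and monotonicity", {
  f <- data.frame(es = c(4, 2), pb = c(0.5, 0.25), ty = c(2, 1),
                  ct = c(1, 0.5))
  # all features at their maxima sum to the weights
  expect_equal(combine_auto(f, c(1.0, 0.5, 1.5, 0.0))[1], 3.0)
  # a zero per-topic maximum contributes nothing
  f0 <- data.frame(es = c(1, 2), pb = 0, ty = 0, ct = 0)
  expect_equal(combine_auto(f0, c(1, 1, 1, 1)), c(0.5, 1))
  # w_ct = 0 means ct never affects the ordering
  fa <- data.frame(es = c(3, 1), pb = c(0, 0), ty = c(1, 1), ct = c(0, 1))
  fb <- fa
  fb$ct <- rev(fb$ct)
  w <- c(1, 0.5, 1.5, 0)
  expect_equal(order(-combine_auto(fa, w)), order(-combine_auto(fb, w)))
  # publication type dominates when only ty differs and w_ty > 0
  fc <- data.frame(es = c(1, 1), pb = c(0, 0), ty = c(-1, 2), ct = c(0.5, 0.5))
  sc <- combine_auto(fc, c(1, 0.5, 1.5, 0))
  expect_gt(sc[2], sc[1])

  expect_equal(combine_full(0.2, 0.5, 1.0, 5.0), 2.7)
  expect_equal(combine_full(c(0.1, 0.9), c(1, 0), 1, 0), c(0.1, 0.9))
  expect_equal(combine_full(0, 0.4, 0, 1), 0.4)
})

test_that("the preset table matches the documented run configurations", {
  p <- reranker_presets()
  a1 <- p[p$preset == "auto-1", ]
  expect_equal(c(a1$w_es, a1$w_pb, a1$w_ty, a1$w_ct), c(1.0, 0.5, 1.5, 0.0))
  expect_equal(a1$run_id, "damoespb1")
  f3 <- p[p$preset == "full-3", ]
  expect_equal(c(f3$w_es, f3$w_pb, f3$w_ty, f3$w_ct),
               c(-0.465, -0.141, -0.617, -0.005))
  expect_equal(c(f3$w_lr, f3$w_fb), c(1.0, 5.0))
  expect_equal(p$w_fb[p$preset == "full-2"], 2.0)
})

test_that("reranking permutes and truncates candidates with id tie-breaks", {
  n <- 1500L
  f <- data.frame(article = sprintf("D%04d", 1:n), es = runif(n),
                  pb = 0, ty = sample(-2:2, n, TRUE), ct = runif(n))
  run <- rerank_candidates(1L, f, preset = "auto-1")
  expect_equal(nrow(run), 1000L)
  expect_equal(run$rank, 1:1000)
  expect_true(all(run$article %in% f$article))
  expect_true(!is.unsorted(rev(run$score)))
  # brute-force sort oracle
  sc <- combine_auto(f, c(1.0, 0.5, 1.5, 0.0))
  want <- f$article[order(-sc, f$article)][1:1000]
  expect_identical(run$article, want)
  # identical scores -> ascending article id order
  f2 <- data.frame(article = c("Z", "A", "M"), es = 1, pb = 0, ty = 0, ct = 1)
  run2 <- rerank_candidates(1L, f2, preset = "auto-1")
  expect_identical(run2$article, c("A", "M", "Z"))
  expect_error(rerank_candidates(1L, f2, preset = "nope"), "auto-1")
})
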