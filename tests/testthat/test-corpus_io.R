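test_that("article collections enforce id invariants and defaults", {
  coll <- article_collection(id = c("A1", "A2"), title = c("T1", "T2"),
                             abstract = c("x", NA))
  expect_equal(coll$abstract, c("x", ""))
  expect_equal(coll$citation_count, c(0L, 0L))
  expect_equal(coll$pub_types, list(character(0), character(0)))
  expect_error(article_collection(c("X1", "X1"), "t"), "duplicate")
  expect_error(article_collection(c("A", ""), "t"), "non-empty")
  expect_error(article_collection("A", "t", citation_count = -1L), ">= 0")
})

test_that("record-lines round-trips a collection and rejects malformed input", {
  coll <- article_collection(
    id = c("PM1", "PM2", "PM3"),
    title = c("EGFR in NSCLC", "BRAF melanoma", "plain title"),
    abstract = c("some abstract text", "", "third one"),
    pub_types = list(c("journal article", "clinical trial"), character(0),
                     "review"),
    citation_count = c(12L, 0L, 3L)
  )
  path <- withr::local_tempfile(fileext = ".jsonl")
  write_article_collection(coll, path)
  back <- read_article_collection(path)
  expect_equal(back$id, coll$id)
  expect_equal(back$title, coll$title)
  expect_equal(back$abstract, coll$abstract)
  expect_equal(back$pub_types, coll$pub_types)
  expect_equal(back$citation_count, coll$citation_count)

  bad <- withr::local_tempfile(fileext = ".jsonl")
  writeLines(c('{"id":"A","title":"t"}', '{"title":"no id"}'), bad)
  expect_error(read_article_collection(bad), "line 2.*id")
  writeLines(c('{"id":"A","title":"t"}', '{"id":"A","title":"again"}'), bad)
  expect_error(read_article_collection(bad), "duplicate")
  # missing optional fields take the documented defaults
  writeLines('{"id":"A","title":"t"}', bad)
  one <- read_article_collection(bad)
  expect_equal(one$abstract, "")
  expect_equal(one$pub_types[[1]], character(0))
  expect_equal(one$citation_count, 0L)
})

test_that("the MEDLINE XML subset reader maps fields and sidecar citations", {
  xml <- '<PubmedArticleSet>
    <PubmedArticle><MedlineCitation><PMID>101</PMID>
      <Article><ArticleTitle>Trial of drug X</ArticleTitle>
        <Abstract><AbstractText>Part one.</AbstractText>
          <AbstractText>Part two.</AbstractText></Abstract>
        <PublicationTypeList><PublicationType>Clinical Trial</PublicationType>
          <PublicationType>Journal Article</PublicationType>
        </PublicationTypeList></Article>
    </MedlineCitation></PubmedArticle>
    <PubmedArticle><MedlineCitation><PMID>102</PMID>
      <Article><ArticleTitle>No abstract here</ArticleTitle></Article>
    </MedlineCitation></PubmedArticle>
  </PubmedArticleSet>'
  path <- withr::local_tempfile(fileext = ".xml")
  writeLines(xml, path)
  ct <- withr::local_tempfile()
  writeLines("101\t42", ct)
  coll <- read_article_collection(path, "medline-xml", citations = ct)
  expect_equal(coll$id, c("101", "102"))
  expect_equal(coll$abstract[1], "Part one. Part two.")
  expect_equal(coll$abstract[2], "")
  expect_equal(coll$pub_types[[1]], c("Clinical Trial", "Journal Article"))
  expect_equal(coll$citation_count, c(42L, 0L))
})

test_that("topic files parse with delimiter auto-detection, order preserved", {
  path <- withr::local_tempfile()
  writeLines(c("1, colorectal cancer, ABL proto-oncogene 1, Regorafenib",
               "11\tBreast cancer\tCyclin dependent kinase 4\tAbemaciclib"),
             path)
  topics <- read_topics(path)
  expect_equal(topics$id, c(1L, 11L))
  expect_equal(topics$disease[1], "colorectal cancer")
  expect_equal(topics$gene[1], "ABL proto-oncogene 1")
  expect_equal(topics$treatment[2], "Abemaciclib")

  writeLines(character(0), path)
  expect_equal(nrow(read_topics(path)), 0L)
  writeLines("2, only, three", path)
  expect_error(read_topics(path), "line 1")
})

test_that("qrels round-trip and reject out-of-range tiers", {
  path <- withr::local_tempfile()
  writeLines("3 0 PM17 4", path)
  qr <- read_qrels(path)
  expect_equal(qr$topic, 3L)
  expect_equal(qr$article, "PM17")
  expect_equal(qr$tier, 4L)

  writeLines("3 0 PM17 7", path)
  expect_error(read_qrels(path), "0..4")
  expect_error(judgment_set(c(1, 1), c("A", "A"), c(2, 3)), "duplicate")

  set.seed(42)
  rand <- judgment_set(topic = rep(1:5, each = 10),
                       article = paste0("D", rep(1:10, 5)),
                       tier = sample(0:4, 50, replace = TRUE))
  write_qrels(rand, path)
  expect_equal(read_qrels(path), rand, ignore_attr = TRUE)
})

test_that("run files obey TREC invariants and round-trip to 6 columns", {
  run <- data.frame(topic = 1L, article = c("A", "B"), rank = 1:2,
                    score = c(2.5, 1.5), tag = "t1",
                    stringsAsFactors = FALSE)
  path <- withr::local_tempfile()
  write_run(run, path)
  lines <- readLines(path)
  expect_equal(lines[1], "1 Q0 A 1 2.5 t1")
  expect_length(strsplit(lines[1], " ")[[1]], 6L)
  expect_equal(read_run(path), run, ignore_attr = TRUE)

  big <- data.frame(topic = 1L, article = paste0("D", 1:1001),
                    rank = 1:1001, score = seq(1001, 1, -1))
  expect_error(write_run(big, path), "cap")
  bad <- data.frame(topic = 1L, article = c("A", "B"), rank = 1:2,
                    score = c(1, 2))
  expect_error(write_run(bad, path), "non-increasing")
  bad2 <- data.frame(topic = 1L, article = c("A", "A"), rank = 1:2,
                     score = c(2, 1))
  expect_error(write_run(bad2, path), "duplicate")

  set.seed(7)
  rand <- do.call(rbind, lapply(1:3, function(tid) {
    n <- sample(5:20, 1)
    data.frame(topic = tid, article = sprintf("T%dD%02d", tid, 1:n),
               rank = 1:n, score = round(sort(runif(n, 0, 10),
                                              decreasing = TRUE), 6),
               tag = "rt", stringsAsFactors = FALSE)
  }))
  write_run(rand, path)
  back <- read_run(path)
  expect_equal(back$article, rand$article)
  expect_equal(back$score, rand$score, tolerance = 1e-9)
})
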