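test_that("clean_text applies the full normalization rule list", {
  expect_equal(clean_text("Hochwasser!! @amt http://x.co <b>5</b>"),
               "hochwasser")
  expect_equal(clean_text(""), "")
  expect_equal(clean_text("#Regen Regen"), "regen regen")
  expect_equal(clean_text("#Regen Regen", drop_hashtag_words = TRUE), "regen")
  expect_equal(clean_text("  viele   SPACES \t hier "), "viele spaces hier")
  expect_equal(clean_text("Umlaute: schön & müde; 42mal"),
               "umlaute schön müde mal")
  expect_equal(clean_text("www.beispiel.de und <a href='x'>link</a>"),
               "und link")
  expect_error(clean_text(5), "character")
})

test_that("clean_text is idempotent", {
  raw <- c("Hochwasser!! @amt http://x.co <b>5</b>", "", "#A b C 12 <i>x</i>",
           "ÄÖÜ äöü ß — mixed Ünïcode!", "a    b\nc\td")
  once <- clean_text(raw)
  expect_identical(clean_text(once), once)
})

test_that("lexicon construction enforces its invariants", {
  expect_error(lexicon("angst", "angst"), "disjoint")
  expect_error(lexicon("angst*", "angst"), "disjoint")  # stems collide too
  expect_error(lexicon("two words", "gut"), "whitespace")
  expect_error(lexicon("Angst", "gut"), "lowercase")
  lex <- lexicon(c("angst", "flut*"), "gut", "der")
  expect_s3_class(lex, "lexicon")
})

test_that("tokenize_and_filter removes stopwords and keeps order", {
  lex <- lexicon("angst", "gut", stopwords = c("der", "die"))
  expect_equal(tokenize_and_filter("der regen kommt", lex),
               c("regen", "kommt"))
  expect_equal(tokenize_and_filter("", lex), character(0))
  for (s in c("der die der", "a der b die c", "die")) {
    toks <- tokenize_and_filter(s, lex)
    expect_false(any(toks %in% lex$stopwords))
  }
})

test_that("score_sentiment follows the majority rule with neutral ties", {
  lex <- lexicon(c("angst", "flut*"), c("gut", "super"))
  expect_equal(score_sentiment(c("angst", "flutwelle"), lex), "negative")
  expect_equal(score_sentiment(character(0), lex), "neutral")
  expect_equal(score_sentiment(c("gut", "angst"), lex), "neutral")
  expect_equal(score_sentiment(c("gut", "super", "angst"), lex), "positive")
  # stem matching is optional
  expect_equal(score_sentiment("flutwelle", lex, stem = FALSE), "neutral")
})

test_that("aggregate_panel counts, deduplicates and reports skips", {
  g <- tiny_graph()
  docs <- data.frame(
    doc_id = c("d1", "d2", "d3", "d3", "d4"),
    label = c("negative", "negative", "neutral", "neutral", "positive"),
    timestamp = c("2019-01-02", "2019-01-03", "2019-01-05", "2019-01-05",
                  "2019-02-01"),
    region = c("A", "A", "A", "A", "B"))
  p <- aggregate_panel(docs, g, "2019-01-01", n_weeks = 6)
  expect_equal(unname(p$ttw["A", 1]), 3L)   # duplicate d3 counted once
  expect_equal(unname(p$ntw["A", 1]), 2L)
  expect_equal(unname(p$ttw["B", 5]), 1L)
  expect_equal(sum(p$ttw), 4L)

  # out-of-window documents are skipped with a count; unknown regions error
  docs$timestamp[5] <- "2020-06-01"
  expect_message(p2 <- aggregate_panel(docs, g, "2019-01-01", n_weeks = 6),
                 "skipped 1")
  expect_equal(attr(p2, "skipped"), 1L)
  docs$region[1] <- "Z"
  expect_error(suppressMessages(aggregate_panel(docs, g, "2019-01-01", 6)),
               "unknown region")

  # empty stream -> all-zero panel on the full grid
  p0 <- aggregate_panel(docs[0, ], g, "2019-01-01", n_weeks = 6)
  expect_equal(dim(p0$ttw), c(4L, 6L))
  expect_true(all(p0$ttw == 0L))
})

test_that("document conservation holds on random corpora", {
  g <- tiny_graph()
  set.seed(99)
  n <- 300
  docs <- data.frame(
    doc_id = sprintf("d%03d", sample(250, n, replace = TRUE)),  # forces dupes
    label = sample(c("negative", "positive", "neutral"), n, replace = TRUE),
    timestamp = as.Date("2019-01-01") + sample(0:41, n, replace = TRUE),
    region = sample(g$region_ids, n, replace = TRUE))
  p <- aggregate_panel(docs, g, "2019-01-01", n_weeks = 6)
  uni <- docs[!duplicated(docs$doc_id), ]
  expect_equal(sum(p$ttw), nrow(uni))
  expect_equal(sum(p$ntw), sum(uni$label == "negative"))
  expect_true(all(p$ntw <= p$ttw))
})

test_that("label_documents pipes cleaning, filtering and scoring", {
  lex <- default_lexicon()
  docs <- data.frame(
    doc_id = c("a", "b", "c"),
    text = c("Die Flut ist eine KATASTROPHE!", "Danke, super Tag :)",
             "der Zug ist da"),
    timestamp = "2021-07-01", region = "NW")
  out <- label_documents(docs, lex)
  expect_equal(out$label, c("negative", "positive", "neutral"))
  # pre-labelled documents pass through untouched
  docs$label <- c("positive", "positive", "positive")
  expect_equal(label_documents(docs, lex)$label, rep("positive", 3))
})

test_that("panel and lexicon CSV round-trips", {
  b <- tiny_bundle(seed = 3, mean_ttw = 50)
  dir <- withr::local_tempdir()
  write_panel_csv(b$panel, file.path(dir, "p.csv"))
  p2 <- read_panel_csv(file.path(dir, "p.csv"))
  expect_equal(p2$ntw, b$panel$ntw, ignore_attr = TRUE)
  expect_equal(p2$ttw, b$panel$ttw, ignore_attr = TRUE)
  expect_equal(p2$week_start, b$panel$week_start)

  lex <- default_lexicon()
  expect_gt(length(lex$negative_terms), 10)
  expect_gt(length(lex$stopwords), 10)
})
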