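# Tokenization and keyword matching.

test_that("tokenizer lowercases, strips punctuation, keeps hashtags and urls", {
  expect_identical(tokenizeText("Breast Cancer awareness!!")[[1]],
                   c("breast", "cancer", "awareness"))
  expect_identical(tokenizeText("")[[1]], character(0))
  expect_identical(tokenizeText(NA_character_)[[1]], character(0))
  expect_identical(tokenizeText("#copd http://x.co flare")[[1]],
                   c("#copd", "<url>", "flare"))
  expect_identical(tokenizeText("@doc can't breathe")[[1]],
                   c("@doc", "can't", "breathe"))
})

test_that("longest phrase wins and ties break by lexicon order", {
  lex <- data.frame(disease = c("breast cancer", "breast cancer"),
                    keyword = c("cancer", "breast cancer"))
  m <- matchKeywords(c("i", "fear", "breast", "cancer"), lex)
  expect_identical(nrow(m), 1L)
  expect_identical(m$keyword, "breast cancer")
  expect_identical(m$offset, 2L)

  lex <- data.frame(disease = "asthma", keyword = "asthma")
  m <- matchKeywords(c("my", "asthma", "inhaler"), lex)
  expect_identical(m$offset, 1L)
})

test_that("matcher agrees with a brute-force placement oracle", {
  # oracle: enumerate every (phrase, offset) placement, then keep
  # non-overlapping placements per disease preferring earlier offsets
  # and longer phrases (the maximal-match contract)
  oracle <- function(tokens, lex) {
    out <- list()
    for (d in unique(lex$disease)) {
      phr <- lex$keyword[lex$disease == d]
      ptoks <- strsplit(phr, " ", fixed = TRUE)
      cand <- list()
      for (p in seq_along(ptoks)) {
        L <- length(ptoks[[p]])
        if (L > length(tokens)) next
        for (off in 0:(length(tokens) - L)) {
          if (all(tokens[(off + 1):(off + L)] == ptoks[[p]]))
            cand[[length(cand) + 1L]] <- list(kw = phr[p], off = off,
                                              len = L, rank = p)
        }
      }
      if (!length(cand)) next
      ord <- order(vapply(cand, `[[`, 0, "off"),
                   -vapply(cand, `[[`, 0, "len"),
                   vapply(cand, `[[`, 0, "rank"))
      used <- rep(FALSE, length(tokens))
      for (ci in ord) {
        cc <- cand[[ci]]
        span <- (cc$off + 1):(cc$off + cc$len)
        if (any(used[span])) next
        used[span] <- TRUE
        out[[length(out) + 1L]] <- data.frame(
          disease = d, keyword = cc$kw, offset = cc$off,
          stringsAsFactors = FALSE)
      }
    }
    if (!length(out)) return(data.frame(disease = character(),
                                        keyword = character(),
                                        offset = integer()))
    res <- do.call(rbind, out)
    res[order(res$disease, res$offset), ]
  }

  lex <- data.frame(
    disease = c("a", "a", "a", "b", "b"),
    keyword = c("heart attack", "heart", "attack rate", "rate", "heart attack rate"))
  words <- c("heart", "attack", "rate", "x", "y")
  withr::with_seed(42, {
    for (i in 1:100) {
      tokens <- sample(words, sample(3:12, 1), replace = TRUE)
      got <- matchKeywords(tokens, lex)
      got <- got[order(got$disease, got$offset), ]
      rownames(got) <- NULL
      want <- oracle(tokens, lex)
      rownames(want) <- NULL
      expect_identical(got, want)
    }
  })
})

test_that("filtering reproduces planted per-keyword counts exactly", {
  cfg <- generatorConfig(nMessages = 600L, seed = 31L)
  corpus <- simulateCorpus(cfg)
  lex <- default_world_lexicon(cfg)
  m <- filterCorpus(corpus, lex)
  tr <- truthData(corpus)
  planted <- table(tr$keyword[!is.na(tr$keyword)])
  kc <- keywordCounts(m)
  for (k in names(planted))
    expect_identical(kc$n[kc$keyword == k], as.integer(planted[[k]]))
  expect_identical(sort(matchedIds(m)),
                   sort(tr$message_id[!is.na(tr$keyword)]))
})

test_that("keyword-free corpora yield empty matches with zero counts", {
  corpus <- corpus_from_texts(c("just a sunny day", "nothing here"))
  lex <- data.frame(disease = "asthma", keyword = "asthma")
  m <- filterCorpus(corpus, lex)
  expect_identical(nrow(matchTable(m)), 0L)
  expect_identical(keywordCounts(m)$n, 0L)
})

test_that("unreadable records are skipped with a warning and counted", {
  corpus <- corpus_from_texts(c("asthma attack", "ok"))
  corpus@messages$text[2] <- NA_character_
  lex <- data.frame(disease = "asthma", keyword = "asthma")
  expect_warning(m <- filterCorpus(corpus, lex), "skipped")
  expect_identical(m@nSkipped, 1L)
  expect_identical(length(matchedIds(m)), 1L)
})

test_that("per-disease counts never exceed the sum of keyword counts", {
  cfg <- generatorConfig(nMessages = 400L, seed = 17L)
  corpus <- simulateCorpus(cfg)
  m <- filterCorpus(corpus, default_world_lexicon(cfg))
  kc <- keywordCounts(m); dc <- diseaseCounts(m)
  for (d in dc$disease)
    expect_lte(dc$n[dc$disease == d], sum(kc$n[kc$disease == d]))
})

test_that("filtering is idempotent", {
  cfg <- generatorConfig(nMessages = 300L, seed = 13L)
  corpus <- simulateCorpus(cfg)
  lex <- default_world_lexicon(cfg)
  m1 <- filterCorpus(corpus, lex)
  keep <- messages(corpus)$message_id %in% matchedIds(m1)
  sub <- methods::new("MessageCorpus",
                      messages = messages(corpus)[keep, ],
                      truth = truthData(corpus)[keep, ])
  m2 <- filterCorpus(sub, lex)
  a <- matchTable(m1); b <- matchTable(m2)
  rownames(a) <- rownames(b) <- NULL
  expect_identical(a[order(a$message_id, a$disease, a$offset), ],
                   b[order(b$message_id, b$disease, b$offset), ])
})

test_that("lexicon files load from CSV and YAML alike", {
  csv <- tempfile(fileext = ".csv")
  writeLines(c("disease,keyword", "asthma,asthma", "asthma,Inhaler"), csv)
  lcsv <- readLexicon(csv)
  expect_identical(lcsv$keyword, c("asthma", "inhaler"))
  yml <- tempfile(fileext = ".yaml")
  writeLines(c("asthma:", "  - asthma", "  - inhaler"), yml)
  expect_identical(readLexicon(yml)$keyword, c("asthma", "inhaler"))
  lex <- defaultLexicon()
  expect_identical(length(unique(lex$disease)), 14L)
})
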