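# Vocabulary filtering, LDA fitting, message topic loads and
# topic-disease correlations.

test_that("vocabulary applies the author-fraction threshold and drops keywords", {
  texts <- c(rep("common words here", 80),
             rep("asthma common rare", 20))
  corpus <- corpus_from_texts(texts)   # 100 distinct authors
  lex <- data.frame(disease = "asthma", keyword = "asthma")
  v <- buildVocabulary(corpus, lex, minAuthorFrac = 0.05)
  expect_true(v$retained[v$token == "common"])
  expect_true(v$retained[v$token == "rare"])       # 20% of authors
  expect_false(v$retained[v$token == "asthma"])    # keyword, 20% of authors
  # below-threshold token
  corpus2 <- corpus_from_texts(c("unique onceonly", rep("common", 99)))
  v2 <- buildVocabulary(corpus2, lex, minAuthorFrac = 0.05)
  expect_false(v2$retained[v2$token == "onceonly"])
  expect_error(buildVocabulary(corpus_from_texts(character(0)), lex),
               "empty")
})

test_that("vocabulary agrees with a brute-force author recount", {
  cfg <- generatorConfig(nMessages = 50L, nUsers = 20L, seed = 3L)
  corpus <- simulateCorpus(cfg)
  lex <- default_world_lexicon(cfg)
  v <- buildVocabulary(corpus, lex, minAuthorFrac = 0.1)
  msgs <- messages(corpus)
  toks <- tokenizeText(msgs$text)
  kwTokens <- unique(unlist(strsplit(lex$keyword, " ")))
  nAuthors <- length(unique(msgs$author_id))
  for (i in seq_len(nrow(v))) {
    users <- unique(msgs$author_id[vapply(toks, function(x)
      v$token[i] %in% x, logical(1))])
    expect_equal(v$authorFrac[i], length(users) / nAuthors)
    expect_identical(v$retained[i],
                     length(users) / nAuthors >= 0.1 &&
                       !(v$token[i] %in% kwTokens))
  }
})

test_that("collapsed Gibbs recovers planted disjoint blocks", {
  world <- block_corpus(nBlocks = 3, docsPerBlock = 50, seed = 2)
  v <- full_vocabulary(world$corpus)
  model <- fitLda(world$corpus, v, K = 3, nIter = 300, burnIn = 100,
                  seed = 11)
  expect_true(all(abs(rowSums(topicWordDist(model)) - 1) < 1e-9))
  mass <- block_recovery_mass(model, world$blockWords)
  expect_true(all(mass >= 0.9))
})

test_that("gibbs log-likelihood trends upward from initialization", {
  world <- block_corpus(nBlocks = 2, docsPerBlock = 30, seed = 5)
  model <- fitLda(world$corpus, full_vocabulary(world$corpus), K = 2,
                  nIter = 200, burnIn = 50, seed = 4)
  ll <- model@logLik
  smooth <- stats::filter(ll, rep(1 / 10, 10), sides = 1)
  smooth <- smooth[!is.na(smooth)]
  expect_gt(mean(tail(smooth, 20)), mean(head(smooth, 20)))
})

test_that("fits are reproducible for a fixed seed", {
  world <- block_corpus(nBlocks = 2, docsPerBlock = 20, seed = 9)
  v <- full_vocabulary(world$corpus)
  m1 <- fitLda(world$corpus, v, K = 2, nIter = 100, burnIn = 20, seed = 8)
  m2 <- fitLda(world$corpus, v, K = 2, nIter = 100, burnIn = 20, seed = 8)
  expect_identical(topicWordDist(m1), topicWordDist(m2))
})

test_that("message topic loads follow the word-posterior mixture formula", {
  # hand-built model: K = 4, V = 6
  set.seed(31)
  phi <- matrix(rgamma(24, 1), 4, 6)
  phi <- phi / rowSums(phi)
  colnames(phi) <- paste0("w", 1:6)
  prior <- c(0.1, 0.2, 0.3, 0.4)
  model <- methods::new("TopicModel", K = 4L, phi = phi,
                        topicPrior = prior, alpha = 1, beta = 0.01,
                        logLik = numeric(0), seed = 1L)
  # single-token message: load equals p(topic | w) exactly
  corpus <- corpus_from_texts("w3")
  load1 <- messageTopicLoads(corpus, model)[1, ]
  want <- phi[, "w3"] * prior / sum(phi[, "w3"] * prior)
  expect_equal(unname(load1), unname(want), tolerance = 1e-12)

  # brute-force double sum on a 5-token message
  corpus <- corpus_from_texts("w1 w5 w1 w2 w6")
  got <- messageTopicLoads(corpus, model)[1, ]
  toks <- c("w1", "w5", "w1", "w2", "w6")
  brute <- rep(0, 4)
  for (k in 1:4) {
    for (w in unique(toks)) {
      pwm <- sum(toks == w) / length(toks)
      ptw <- phi[k, w] * prior[k] / sum(phi[, w] * prior)
      brute[k] <- brute[k] + pwm * ptw
    }
  }
  expect_equal(unname(got), brute, tolerance = 1e-12)

  # duplicating the token list leaves relative frequencies unchanged
  corpus2 <- corpus_from_texts("w1 w5 w1 w2 w6 w1 w5 w1 w2 w6")
  expect_equal(unname(messageTopicLoads(corpus2, model)[1, ]),
               unname(got), tolerance = 1e-12)

  # uniform phi and prior give uniform loads
  uphi <- matrix(1 / 6, 4, 6, dimnames = list(NULL, paste0("w", 1:6)))
  umodel <- methods::new("TopicModel", K = 4L, phi = uphi,
                         topicPrior = rep(0.25, 4), alpha = 1, beta = 0.01,
                         logLik = numeric(0), seed = 1L)
  expect_equal(unname(messageTopicLoads(corpus, umodel)[1, ]),
               rep(0.25, 4), tolerance = 1e-12)

  # out-of-vocabulary-only message is flagged undefined
  corpus3 <- corpus_from_texts("zz yy")
  expect_true(all(is.na(messageTopicLoads(corpus3, model)[1, ])))
})

test_that("BH adjustment matches the hand-applied step-up rule", {
  loads <- matrix(c(0.9, 0.8, 0.7, 0.2, 0.1,
                    0.1, 0.2, 0.3, 0.8, 0.9), ncol = 2,
                  dimnames = list(paste0("m", 1:5), NULL))
  labels <- matrix(c(1L, 1L, 1L, 0L, 0L), ncol = 1,
                   dimnames = list(paste0("m", 1:5), "d"))
  res <- topicDiseaseCorrelations(loads, labels, alphaLevel = 0.05)
  expect_equal(res$p_adj, p.adjust(res$p, "BH"))
  # frozen hand application of the step-up rule on a 4-value family
  p <- c(0.001, 0.02, 0.03, 0.04)
  expect_equal(p.adjust(p, "BH"), c(0.004, 0.04, 0.04, 0.04))
  # and adjusted values are monotone in raw rank
  expect_true(all(diff(res$p_adj[order(res$p)]) >= -1e-15))
})

test_that("correlations find planted disease-topic enrichment and ignore order", {
  cfg <- generatorConfig(nMessages = 1500L, seed = 55L)
  corpus <- simulateCorpus(cfg)
  lex <- default_world_lexicon(cfg)
  m <- filterCorpus(corpus, lex)
  v <- buildVocabulary(corpus, lex)
  model <- fitLda(corpus, v, K = 12, nIter = 300, burnIn = 100, seed = 6)
  loads <- messageTopicLoads(corpus, model)
  labels <- diseaseLabelMatrix(m, rownames(loads))
  res <- topicDiseaseCorrelations(loads, labels)

  # the top topic for breast cancer should be one dominated by the
  # planted Awareness theme (bias 3x)
  tr <- truthData(corpus)
  bc <- res[res$disease == "breast cancer", ]
  top <- bc$topic[which.max(bc$r)]
  # which planted theme generated the messages loading on `top`?
  defined <- rownames(loads)[rowSums(is.na(loads)) == 0]
  hi <- defined[order(-loads[defined, top])][1:100]
  themes <- tr$theme[match(hi, tr$message_id)]
  expect_identical(names(which.max(table(themes))), "Awareness")

  # permutation invariance over message order (compare on a canonical
  # ordering: near-tied |r| values may legitimately swap report rows)
  perm <- withr::with_seed(1, sample(nrow(loads)))
  res2 <- topicDiseaseCorrelations(loads[perm, ], labels[perm, ])
  a <- res[order(res$disease, res$topic), ]
  b <- res2[order(res2$disease, res2$topic), ]
  rownames(a) <- rownames(b) <- NULL
  expect_equal(a, b, tolerance = 1e-10)
})

test_that("degenerate inputs give NA correlations excluded from the family", {
  loads <- cbind(const = rep(0.5, 10), var = (1:10) / 10)
  rownames(loads) <- paste0("m", 1:10)
  labels <- matrix(rep(c(0L, 1L), 5), ncol = 1,
                   dimnames = list(paste0("m", 1:10), "d"))
  res <- topicDiseaseCorrelations(loads, labels, alphaLevel = 0.05)
  expect_true(is.na(res$r[res$topic == 1]))
  expect_true(is.na(res$p_adj[res$topic == 1]))
  expect_false(any(is.na(res$p_adj[res$topic == 2])))
})
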