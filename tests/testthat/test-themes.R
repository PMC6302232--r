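# NMF theme model, message theme distributions, p(theme | disease) and
# disease-theme PMI.

# Block-separable topic-word matrix: two groups of topics with disjoint
# word support.
block_phi <- function() {
  phi <- rbind(
    c(0.5, 0.3, 0.2, 0, 0, 0),
    c(0.2, 0.5, 0.3, 0, 0, 0),
    c(0, 0, 0, 0.6, 0.3, 0.1),
    c(0, 0, 0, 0.1, 0.4, 0.5))
  colnames(phi) <- paste0("w", 1:6)
  phi
}

toy_topic_model <- function(phi = block_phi()) {
  methods::new("TopicModel", K = nrow(phi), phi = phi,
               topicPrior = rep(1 / nrow(phi), nrow(phi)),
               alpha = 1, beta = 0.01, logLik = numeric(0), seed = 1L)
}

test_that("NMF recovers block-separable topic groups perfectly", {
  for (seed in 1:5) {
    th <- fitThemes(toy_topic_model(), T = 2, seed = seed)
    cluster <- apply(th@W, 1, which.max)
    expect_identical(cluster[1], cluster[2])
    expect_identical(cluster[3], cluster[4])
    expect_false(cluster[1] == cluster[3])
  }
})

test_that("multiplicative updates never increase the reconstruction error", {
  set.seed(17)
  A <- matrix(rgamma(20 * 40, 1), 20, 40)
  A <- A / rowSums(A)
  init <- infodemics:::.nndsvd(A, 5)
  fit <- infodemics:::.nmf_mu(A, init$W, init$H, maxIter = 200, tol = 0)
  expect_true(all(diff(fit$err) <= 1e-10))
  expect_true(all(fit$W >= 0) && all(fit$H >= 0))
})

test_that("theme posteriors are proper distributions", {
  th <- fitThemes(toy_topic_model(), T = 2)
  expect_equal(unname(rowSums(th@pWordGivenTheme)), rep(1, 2))
  expect_equal(unname(rowSums(themeGivenWord(th))), rep(1, 6))
  expect_equal(sum(th@themePrior), 1)
  expect_error(fitThemes(toy_topic_model(), T = 10), "exceed")
})

test_that("message theme loads follow the mixture formula with low-index tie-break", {
  th <- fitThemes(toy_topic_model(), T = 2,
                  themeLabels = c("Alpha", "Beta"))
  # single-token message: the load is p(theme | word) exactly
  tl <- messageThemeLoads(corpus_from_texts("w5"), th)
  expect_equal(unname(tl$loads[1, ]), unname(themeGivenWord(th)["w5", ]),
               tolerance = 1e-12)

  # brute-force double sum on a 5-token message
  toks <- c("w1", "w4", "w1", "w6", "w2")
  tl2 <- messageThemeLoads(corpus_from_texts(paste(toks, collapse = " ")), th)
  ptw <- themeGivenWord(th)
  brute <- rep(0, 2)
  for (t in 1:2)
    for (w in unique(toks))
      brute[t] <- brute[t] + sum(toks == w) / length(toks) * ptw[w, t]
  expect_equal(unname(tl2$loads[1, ]), brute, tolerance = 1e-12)

  # uniform posterior forces the tie-break to the first theme
  uth <- th
  uth@pThemeGivenWord[] <- 0.5
  tlu <- messageThemeLoads(corpus_from_texts("w1 w2"), uth)
  expect_identical(unname(tlu$assigned[1]), "Alpha")

  # out-of-vocabulary messages carry no assignment
  tlo <- messageThemeLoads(corpus_from_texts("zz"), th)
  expect_true(all(is.na(tlo$loads[1, ])))
  expect_length(tlo$assigned, 0L)
})

test_that("p(theme | disease) counts hard assignments", {
  assigned <- setNames(c("A", "A", "B", "A", "B", "B", "B"),
                       paste0("m", 1:7))
  labels <- matrix(c(1L, 1L, 1L, 0L, 0L, 0L, 0L,
                     0L, 0L, 0L, 1L, 1L, 1L, 1L), ncol = 2,
                   dimnames = list(paste0("m", 1:7), c("d1", "d2")))
  stats <- themeGivenDisease(assigned, labels, themeLevels = c("A", "B"))
  expect_equal(stats$pThemeGivenDisease[stats$disease == "d1"],
               c(2 / 3, 1 / 3))
  expect_equal(stats$pct[stats$disease == "d1"], c(66.67, 33.33))
  # all of a disease's messages in one theme
  lab1 <- labels[, "d2", drop = FALSE]
  one <- setNames(rep("B", 4), paste0("m", 4:7))
  s1 <- themeGivenDisease(one, lab1, themeLevels = c("A", "B"))
  expect_equal(s1$pThemeGivenDisease, c(0, 1))
  # diseases without messages are omitted with a warning
  labz <- cbind(labels, dz = 0L)
  expect_warning(themeGivenDisease(assigned, labz,
                                   themeLevels = c("A", "B")), "omitted")
})

test_that("PMI is zero under independence and log-ratio otherwise", {
  # independence by construction: N(d,t) = N(d) N(t) / N
  stats <- data.frame(
    disease = rep(c("d1", "d2"), each = 2),
    theme = rep(c("t1", "t2"), 2),
    n = c(20, 80, 10, 40))
  out <- pmiDiseaseTheme(stats)
  expect_equal(out$pmi, rep(0, 4), tolerance = 1e-12)

  # doubling case: p(t | d) = 2 p(t) gives PMI = ln 2
  stats2 <- data.frame(
    disease = c("d1", "d1", "d2", "d2"),
    theme = c("t1", "t2", "t1", "t2"),
    n = c(30, 20, 0, 50))
  # p(t1) = 30/100; p(t1|d1) = 30/50 = 2 p(t1)
  out2 <- pmiDiseaseTheme(stats2)
  expect_equal(out2$pmi[1], log(2), tolerance = 1e-12)
  expect_true(is.na(out2$pmi[3]))  # zero joint count

  # direct hand evaluation of a 2x2 joint table
  stats3 <- data.frame(
    disease = c("d", "d", "o", "o"),
    theme = c("t", "nt", "t", "nt"),
    n = c(30, 70, 100, 800))
  out3 <- pmiDiseaseTheme(stats3)
  want <- log((30 / 1000) / ((100 / 1000) * (130 / 1000)))
  expect_equal(out3$pmi[1], want, tolerance = 1e-12)
  # configurable base
  out3b <- pmiDiseaseTheme(stats3, base = 2)
  expect_equal(out3b$pmi[1], want / log(2), tolerance = 1e-12)
})

test_that("PMI is positive exactly when the theme is over-represented", {
  withr::with_seed(9, {
    for (rep in 1:20) {
      n <- matrix(rpois(6, 40) + 1, 2, 3)
      stats <- data.frame(
        disease = rep(c("d1", "d2"), 3),
        theme = rep(c("t1", "t2", "t3"), each = 2),
        n = as.vector(n))
      out <- pmiDiseaseTheme(stats)
      N <- sum(out$n)
      for (i in seq_len(nrow(out))) {
        nd <- sum(out$n[out$disease == out$disease[i]])
        nt <- sum(out$n[out$theme == out$theme[i]])
        over <- out$n[i] / nd > nt / N
        expect_identical(out$pmi[i] > 0, over)
      }
    }
  })
})

test_that("theme probability mass sums correctly over the disease universe", {
  cfg <- generatorConfig(nMessages = 600L, seed = 77L)
  corpus <- simulateCorpus(cfg)
  lex <- default_world_lexicon(cfg)
  m <- filterCorpus(corpus, lex)
  v <- buildVocabulary(corpus, lex)
  model <- fitLda(corpus, v, K = 8, nIter = 150, burnIn = 50, seed = 2)
  th <- fitThemes(model, T = 4, seed = 1)
  tl <- messageThemeLoads(corpus, th)
  labels <- diseaseLabelMatrix(m)
  stats <- themeGivenDisease(tl$assigned, labels,
                             themeLevels = themeNames(th))
  agg <- as.numeric(tapply(stats$pThemeGivenDisease, stats$disease, sum))
  expect_equal(agg, rep(1, length(agg)), tolerance = 1e-12)
  out <- pmiDiseaseTheme(stats)
  # joint probabilities sum to 1 over the (disease, theme) universe
  expect_equal(sum(out$n) / sum(out$n), 1)
})
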