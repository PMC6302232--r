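# Shared fixtures, all built in code.

# Wrap bare texts into a MessageCorpus (no geodata, no truth).
corpus_from_texts <- function(texts, authors = NULL) {
  n <- length(texts)
  if (is.null(authors)) authors <- sprintf("a%04d", seq_len(n))
  msgs <- data.frame(
    message_id = sprintf("m%06d", seq_len(n)),
    author_id = authors,
    timestamp = rep("2014-01-01T00:00:00Z", n),
    text = texts,
    latitude = rep(NA_real_, n), longitude = rep(NA_real_, n),
    location_field = rep(NA_character_, n),
    stringsAsFactors = FALSE)
  methods::new("MessageCorpus", messages = msgs,
               truth = infodemics:::.empty_truth())
}

# Corpus of documents drawn from disjoint vocabulary blocks: document d
# uses only words of its block. Used for planted-partition recovery.
block_corpus <- function(nBlocks = 3, docsPerBlock = 50, docLen = 20,
                         wordsPerBlock = 10, seed = 1) {
  words <- lapply(seq_len(nBlocks), function(b)
    sprintf("blk%dw%02d", b, seq_len(wordsPerBlock)))
  texts <- character(0)
  blocks <- integer(0)
  withr::with_seed(seed, {
    for (b in seq_len(nBlocks)) {
      for (d in seq_len(docsPerBlock)) {
        texts <- c(texts, paste(sample(words[[b]], docLen, replace = TRUE),
                                collapse = " "))
        blocks <- c(blocks, b)
      }
    }
  })
  list(corpus = corpus_from_texts(texts),
       blocks = blocks,
       blockWords = words)
}

# Vocabulary frame accepting every token of a corpus (bypasses the
# author-frequency filter where it is not under test).
full_vocabulary <- function(corpus) {
  toks <- sort(unique(unlist(tokenizeText(messages(corpus)$text))))
  data.frame(token = toks, authorFrac = 1, retained = TRUE,
             stringsAsFactors = FALSE)
}

# Fraction of each fitted topic's probability mass on its best-matching
# planted word block (greedy one-to-one assignment by mass).
block_recovery_mass <- function(model, blockWords) {
  phi <- topicWordDist(model)
  K <- nrow(phi)
  mass <- sapply(blockWords, function(wset)
    rowSums(phi[, colnames(phi) %in% wset, drop = FALSE]))
  mass <- matrix(mass, nrow = K)
  taken <- rep(FALSE, ncol(mass))
  best <- numeric(K)
  for (k in order(-apply(mass, 1, max))) {
    b <- order(-mass[k, ])
    b <- b[!taken[b]][1]
    taken[b] <- TRUE
    best[k] <- mass[k, b]
  }
  best
}

# The generator's default keyword table as a plain lexicon.
default_world_lexicon <- function(config) {
  config@keywords[c("disease", "keyword")]
}
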