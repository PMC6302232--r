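# Topic stage: author-frequency vocabulary filtering, LDA by collapsed
# Gibbs sampling (C++ core), per-message topic distributions, and
# point-biserial topic-disease correlation with BH-FDR control.

#' Build the filtered modelling vocabulary
#'
#' Retains tokens used by at least `minAuthorFrac` of distinct authors,
#' and removes every token of every lexicon keyword phrase
#' unconditionally (so disease mentions cannot leak into the topics
#' that are later correlated with disease labels).
#'
#' @param corpus a [MessageCorpus-class] with at least one author.
#' @param lexicon data.frame `disease`, `keyword`; all phrase tokens
#'   are excluded.
#' @param minAuthorFrac minimum fraction of distinct authors using a
#'   token (default 0.05).
#' @return data.frame `token`, `authorFrac`, `retained`, ordered by
#'   decreasing author frequency then token; rows with
#'   `retained == TRUE` form the modelling vocabulary.
#' @export
buildVocabulary <- function(corpus, lexicon, minAuthorFrac = 0.05) {
  msgs <- messages(corpus)
  msgs <- msgs[!is.na(msgs$text), , drop = FALSE]
  if (!nrow(msgs)) stop("empty corpus", call. = FALSE)
  toks <- tokenizeText(msgs$text)
  nAuthors <- length(unique(msgs$author_id))
  pairs <- data.frame(
    token = unlist(toks),
    author = rep(msgs$author_id, lengths(toks)),
    stringsAsFactors = FALSE)
  pairs <- unique(pairs)
  tab <- table(pairs$token)
  vocab <- data.frame(token = names(tab),
                      authorFrac = as.numeric(tab) / nAuthors,
                      stringsAsFactors = FALSE)
  kwTokens <- unique(unlist(strsplit(lexicon$keyword, " ", fixed = TRUE)))
  vocab$retained <- vocab$authorFrac >= minAuthorFrac &
    !(vocab$token %in% kwTokens)
  vocab <- vocab[order(-vocab$authorFrac, vocab$token), , drop = FALSE]
  rownames(vocab) <- NULL
  vocab
}

# Tokenize messages and map to 0-based vocabulary ids; returns a list
# of integer vectors parallel to messages (possibly length 0).
.docs_as_ids <- function(msgs, retainedTokens) {
  toks <- tokenizeText(msgs$text)
  lapply(toks, function(x) {
    ids <- match(x, retainedTokens)
    as.integer(ids[!is.na(ids)] - 1L)
  })
}

#' Fit LDA by collapsed Gibbs sampling
#'
#' Standard collapsed Gibbs sampler over token-topic assignments. The
#' topic-word matrix phi and the marginal topic distribution are
#' averaged over post-burn-in sweeps with beta/alpha smoothing. The
#' sampler uses its own seeded RNG, so a fixed seed reproduces the fit
#' exactly. Empty documents (no in-vocabulary token) are skipped.
#'
#' @param corpus a [MessageCorpus-class].
#' @param vocab vocabulary frame from [buildVocabulary()].
#' @param K number of topics (200 in full-scale runs; smaller for desk
#'   work).
#' @param alpha document-topic concentration (default 50/K).
#' @param beta topic-word concentration (default 0.01).
#' @param nIter total Gibbs sweeps (default 1000).
#' @param burnIn sweeps discarded before averaging (default 200).
#' @param seed sampler seed.
#' @return a [TopicModel-class].
#' @export
fitLda <- function(corpus, vocab, K = 200L, alpha = 50 / K, beta = 0.01,
                   nIter = 1000L, burnIn = 200L, seed = 1L) {
  stopifnot(K >= 2L, nIter > burnIn)
  retained <- vocab$token[vocab$retained]
  V <- length(retained)
  if (V < K)
    warning("vocabulary (", V, " tokens) is smaller than K = ", K)
  msgs <- messages(corpus)
  msgs <- msgs[!is.na(msgs$text), , drop = FALSE]
  docs <- .docs_as_ids(msgs, retained)
  docs <- docs[lengths(docs) > 0L]
  if (!length(docs)) stop("no document has in-vocabulary tokens",
                          call. = FALSE)
  fit <- lda_gibbs_cpp(docs, V, as.integer(K), alpha, beta,
                       as.integer(nIter), as.integer(burnIn),
                       as.integer(seed))
  phi <- fit$phi
  colnames(phi) <- retained
  new("TopicModel", K = as.integer(K), phi = phi,
      topicPrior = as.numeric(fit$ptopic), alpha = alpha, beta = beta,
      logLik = as.numeric(fit$loglik), seed = as.integer(seed))
}

# Posterior over columns given a word: post[v, j] proportional to
# colDist[j, v] * prior[j]; rows normalized. Shared by topic and theme
# loads.
.posterior_given_word <- function(colDist, prior) {
  post <- t(colDist) * rep(prior, each = ncol(colDist))
  rs <- rowSums(post)
  zero <- rs <= 0
  post[zero, ] <- 1 / length(prior)
  post[!zero, ] <- post[!zero, , drop = FALSE] / rs[!zero]
  rownames(post) <- colnames(colDist)
  post
}

# Frequency-weighted mixture of per-word posteriors:
# load[m, j] = sum_w p(w | message m) * post[w, j].
.doc_loads <- function(tokensList, post) {
  out <- matrix(NA_real_, length(tokensList), ncol(post))
  vocabTokens <- rownames(post)
  for (i in seq_along(tokensList)) {
    ids <- match(tokensList[[i]], vocabTokens)
    ids <- ids[!is.na(ids)]
    if (!length(ids)) next
    freq <- table(ids)
    w <- as.numeric(freq) / length(ids)
    out[i, ] <- colSums(post[as.integer(names(freq)), , drop = FALSE] * w)
  }
  out
}

#' Per-message topic distributions
#'
#' p(topic | message) = sum_w p(w | message) p(topic | w), where
#' p(w | message) is the token's relative frequency within the message
#' and p(topic | w) is the Bayes-rule posterior from phi and the
#' marginal topic distribution. Out-of-vocabulary tokens are dropped
#' before normalizing; messages with no in-vocabulary token get an
#' all-`NA` row and are excluded from correlations.
#'
#' @param corpus a [MessageCorpus-class].
#' @param model a [TopicModel-class].
#' @return numeric matrix (messages x K), rownames = message ids; rows
#'   of defined messages sum to 1.
#' @export
messageTopicLoads <- function(corpus, model) {
  stopifnot(is(model, "TopicModel"))
  msgs <- messages(corpus)
  msgs <- msgs[!is.na(msgs$text), , drop = FALSE]
  post <- .posterior_given_word(topicWordDist(model), topicPrior(model))
  loads <- .doc_loads(tokenizeText(msgs$text), post)
  rownames(loads) <- msgs$message_id
  colnames(loads) <- paste0("topic", seq_len(nTopics(model)))
  loads
}

# Pearson r of each column of X against binary y, with two-sided
# p-values from the t distribution (point-biserial correlation).
.pearson_cols <- function(X, y) {
  n <- length(y)
  ybar <- mean(y); sy <- sum((y - ybar)^2)
  Xc <- sweep(X, 2, colMeans(X))
  sx <- colSums(Xc^2)
  r <- as.numeric(crossprod(Xc, y - ybar)) / sqrt(sx * sy)
  r[sx == 0 | sy == 0] <- NA_real_
  tt <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * pt(-abs(tt), df = n - 2)
  p[is.na(r)] <- NA_real_
  list(r = r, p = p)
}

#' Topic-disease correlations with FDR control
#'
#' For every (disease, topic) pair, the Pearson correlation between the
#' topic-load vector and the binary disease label across messages
#' (equivalently the point-biserial correlation), with two-sided
#' p-values. Benjamini-Hochberg adjustment is applied over the full
#' family of tested pairs; pairs with zero variance on either side are
#' `NA` and excluded from the family. Significance is declared when the
#' adjusted p-value falls below `alphaLevel`.
#'
#' @param loads matrix from [messageTopicLoads()] (`NA` rows dropped).
#' @param labels binary matrix messages x diseases, e.g. from
#'   [diseaseLabelMatrix()]; rownames must cover the load rows.
#' @param alphaLevel significance gate on the adjusted p-value
#'   (default 0.001).
#' @return data.frame `disease`, `topic`, `r`, `p`, `p_adj`,
#'   `significant`, sorted by decreasing `|r|`.
#' @export
topicDiseaseCorrelations <- function(loads, labels, alphaLevel = 0.001) {
  keep <- rowSums(is.na(loads)) == 0
  loads <- loads[keep, , drop = FALSE]
  ids <- intersect(rownames(loads), rownames(labels))
  if (length(ids) < 3L)
    stop("need at least 3 messages with defined topic loads",
         call. = FALSE)
  loads <- loads[ids, , drop = FALSE]
  labels <- labels[ids, , drop = FALSE]
  if (!all(labels %in% c(0L, 1L)))
    stop("labels must be binary", call. = FALSE)
  out <- list()
  for (d in colnames(labels)) {
    res <- .pearson_cols(loads, as.numeric(labels[, d]))
    out[[d]] <- data.frame(disease = d, topic = seq_len(ncol(loads)),
                           r = res$r, p = res$p,
                           stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, out)
  tab$p_adj <- NA_real_
  ok <- !is.na(tab$p)
  tab$p_adj[ok] <- p.adjust(tab$p[ok], method = "BH")
  tab$significant <- !is.na(tab$p_adj) & tab$p_adj < alphaLevel
  tab <- tab[order(-abs(tab$r), tab$disease, tab$topic), , drop = FALSE]
  rownames(tab) <- NULL
  tab
}
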