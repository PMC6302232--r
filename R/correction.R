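# Keyword precision correction: annotate a sample of messages per
# keyword, estimate the fraction that genuinely reference the disease
# (w_k), and derive corrected per-disease counts sum_k w_k * n_k.

#' Draw an annotation sample for one keyword
#'
#' Uniform sample without replacement among messages containing the
#' keyword; if fewer than `size` exist, all are taken. When the corpus
#' carries a ground-truth sidecar, labels are auto-filled from it
#' (standing in for manual review); otherwise labels are `NA` and the
#' returned frame can be written out as an annotation CSV, labeled by
#' hand, and read back.
#'
#' @param matches a [KeywordMatches-class].
#' @param corpus the corpus the matches came from (for truth labels and
#'   message text).
#' @param keyword keyword to sample for.
#' @param size target sample size (default 30 messages).
#' @param seed sampling seed.
#' @return data.frame `keyword`, `disease`, `message_id`, `text`,
#'   `label` (logical); zero rows (with a warning) when no message
#'   contains the keyword.
#' @export
sampleForAnnotation <- function(matches, corpus, keyword, size = 30L,
                                seed = 1L) {
  stopifnot(size >= 1L)
  mt <- matchTable(matches)
  mt <- mt[mt$keyword == keyword, , drop = FALSE]
  if (!nrow(mt)) {
    warning("no messages contain keyword '", keyword,
            "'; correction factor undefined")
    return(data.frame(keyword = character(), disease = character(),
                      message_id = character(), text = character(),
                      label = logical(), stringsAsFactors = FALSE))
  }
  disease <- mt$disease[1]
  ids <- unique(mt$message_id)
  take <- if (length(ids) <= size) ids else
    with_seed(seed, sample(ids, size))
  msgs <- messages(corpus)
  truth <- truthData(corpus)
  label <- rep(NA, length(take))
  if (nrow(truth)) {
    tr <- truth[match(take, truth$message_id), , drop = FALSE]
    # relevant iff the planted keyword matches and its use was relevant
    label <- !is.na(tr$keyword) & tr$keyword == keyword &
      !is.na(tr$keyword_relevant) & tr$keyword_relevant
  }
  data.frame(keyword = keyword, disease = disease, message_id = take,
             text = msgs$text[match(take, msgs$message_id)],
             label = label, stringsAsFactors = FALSE)
}

#' Estimate a keyword's correction factor
#'
#' w_k is the fraction of the annotated sample labeled as a genuine
#' reference to the disease: the estimated precision of the keyword.
#'
#' @param sample annotation frame from [sampleForAnnotation()] (labels
#'   must be filled in).
#' @return one-row data.frame `keyword`, `disease`, `wk`, `nLabeled`.
#' @export
estimateCorrectionFactor <- function(sample) {
  if (!nrow(sample))
    stop("empty annotation sample: correction factor undefined",
         call. = FALSE)
  if (any(is.na(sample$label)))
    stop("annotation sample has unlabeled messages", call. = FALSE)
  data.frame(keyword = sample$keyword[1], disease = sample$disease[1],
             wk = mean(sample$label), nLabeled = nrow(sample),
             stringsAsFactors = FALSE)
}

#' Corrected message count for a disease
#'
#' The corrected count is sum_k w_k * n_k over the disease's keywords,
#' the expected number of messages genuinely referencing the disease.
#' The real value is retained; the reported value rounds half-up to an
#' integer. Because each keyword contributes its own n_k, a message
#' containing two keywords of the same disease is counted in both
#' terms; with such lexica the corrected count can exceed the
#' de-duplicated per-disease message count (a warning is raised).
#'
#' @param disease disease name.
#' @param factors named numeric, keyword -> w_k.
#' @param counts named numeric, keyword -> n_k (messages containing the
#'   keyword).
#' @param rawCount de-duplicated per-disease message count (for the
#'   aggregate factor); defaults to `sum(counts)` when not supplied.
#' @return one-row data.frame `disease`, `rawCount`, `correctedCount`
#'   (real), `correctedCountReported` (integer, half-up),
#'   `aggregateFactorPct` (corrected / raw as a percentage).
#' @export
#' @examples
#' correctedMessageCount("demo", c(a = 0.5, b = 1), c(a = 10, b = 20))
correctedMessageCount <- function(disease, factors, counts,
                                  rawCount = NULL) {
  active <- names(counts)[counts > 0]
  missing <- setdiff(active, names(factors))
  if (length(missing))
    stop("no correction factor for keyword(s) with messages: ",
         paste(missing, collapse = ", "), call. = FALSE)
  corrected <- sum(factors[active] * counts[active])
  if (is.null(rawCount)) rawCount <- sum(counts)
  if (rawCount > 0 && corrected > rawCount)
    warning("corrected count exceeds de-duplicated message count for '",
            disease, "' (overlapping keywords of one disease)")
  data.frame(disease = disease,
             rawCount = rawCount,
             correctedCount = corrected,
             correctedCountReported = as.integer(roundHalfUp(corrected)),
             aggregateFactorPct = proportionPct(corrected, rawCount, 1),
             stringsAsFactors = FALSE)
}

#' Per-disease volume table with corrected counts
#'
#' Convenience wrapper running annotation sampling, factor estimation
#' and count correction for every keyword of every disease, producing
#' the standard volume table (message count, aggregate correction
#' factor, corrected count, distinct users).
#'
#' @param matches a [KeywordMatches-class].
#' @param corpus the corresponding corpus (must carry truth, or
#'   `labels` must be supplied).
#' @param sampleSize annotation sample size per keyword (default 30).
#' @param seed base seed; each keyword uses a distinct derived seed.
#' @param labels optional externally annotated frame (rows as produced
#'   by [sampleForAnnotation()]) overriding truth-based labels.
#' @return list with `factors` (per-keyword w_k) and `table`
#'   (per-disease: `disease`, `rawCount`, `correctedCount`,
#'   `correctedCountReported`, `aggregateFactorPct`, `users`).
#' @export
correctionTable <- function(matches, corpus, sampleSize = 30L, seed = 1L,
                            labels = NULL) {
  kc <- keywordCounts(matches)
  factors <- list()
  for (i in seq_len(nrow(kc))) {
    if (kc$n[i] == 0) next
    kwd <- kc$keyword[i]
    samp <- if (!is.null(labels)) {
      labels[labels$keyword == kwd, , drop = FALSE]
    } else {
      sampleForAnnotation(matches, corpus, kwd, size = sampleSize,
                          seed = seed + i)
    }
    factors[[length(factors) + 1L]] <- estimateCorrectionFactor(samp)
  }
  factors <- if (length(factors)) do.call(rbind, factors) else
    data.frame(keyword = character(), disease = character(),
               wk = numeric(), nLabeled = integer())
  dc <- diseaseCounts(matches)
  mt <- matchTable(matches)
  msgs <- messages(corpus)
  rows <- list()
  for (d in dc$disease[dc$n > 0]) {
    dk <- kc[kc$disease == d, , drop = FALSE]
    w <- setNames(factors$wk[match(dk$keyword, factors$keyword)],
                  dk$keyword)
    w <- w[!is.na(w)]
    cnt <- setNames(dk$n, dk$keyword)
    row <- correctedMessageCount(d, w, cnt,
                                 rawCount = dc$n[dc$disease == d])
    ids <- unique(mt$message_id[mt$disease == d])
    row$users <- length(unique(msgs$author_id[match(ids, msgs$message_id)]))
    rows[[length(rows) + 1L]] <- row
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  list(factors = factors, table = tab)
}
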