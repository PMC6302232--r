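# Tokenization and keyword-lexicon filtering. Matching is intentionally
# simple and transparent: lowercase token runs against pre-tokenized
# keyword phrases, longest phrase wins.

#' Tokenize message text
#'
#' Unicode is NFKC-normalized, URLs are replaced by the sentinel token
#' `<url>`, text is lowercased, and tokens are runs of letters/digits
#' (internal apostrophes kept, so "can't" survives); `#hashtags` and
#' `@mentions` are kept as single tokens. Everything else is stripped.
#'
#' @param text character vector.
#' @return list of character token vectors (empty vector for empty or
#'   `NA` text).
#' @export
#' @examples
#' tokenizeText("Breast Cancer awareness!!")[[1]]
#' tokenizeText("#copd http://x.co flare")[[1]]
tokenizeText <- function(text) {
  text[is.na(text)] <- ""
  text <- stringi::stri_trans_nfkc(text)
  text <- stringi::stri_replace_all_regex(
    text, "(?:https?://|www\\.)\\S+", " \uE000 ")
  text <- stringi::stri_trans_tolower(text)
  toks <- stringi::stri_extract_all_regex(
    text, "[#@][a-z0-9_]+|[a-z0-9]+(?:'[a-z0-9]+)*|\uE000",
    omit_no_match = TRUE)
  lapply(toks, function(x) { x[x == "\uE000"] <- "<url>"; x })
}

# Pre-tokenize a lexicon into per-disease phrase lists ordered
# longest-first (ties keep lexicon order).
.compile_lexicon <- function(lexicon) {
  stopifnot(all(c("disease", "keyword") %in% names(lexicon)))
  split_rows <- split(seq_len(nrow(lexicon)), lexicon$disease)
  # keep first-appearance disease order
  split_rows <- split_rows[unique(lexicon$disease)]
  lapply(split_rows, function(idx) {
    phrases <- lexicon$keyword[idx]
    toks <- strsplit(phrases, " ", fixed = TRUE)
    ord <- order(-lengths(toks), seq_along(toks))
    list(keyword = phrases[ord], tokens = toks[ord])
  })
}

#' Match lexicon keywords against a token sequence
#'
#' Scans the tokens once per disease, left to right. At each position
#' the longest matching phrase wins (ties broken by lexicon order), and
#' matched tokens are consumed, so a token run matches at most one
#' keyword per disease. Offsets are 0-based token indices of the phrase
#' start.
#'
#' @param tokens character vector, as produced by [tokenizeText()].
#' @param lexicon data.frame with `disease`, `keyword` columns (or the
#'   compiled form produced internally).
#' @return data.frame with columns `disease`, `keyword`, `offset`.
#' @export
#' @examples
#' lex <- data.frame(disease = "asthma", keyword = "asthma")
#' matchKeywords(c("my", "asthma", "inhaler"), lex)
matchKeywords <- function(tokens, lexicon) {
  compiled <- if (is.data.frame(lexicon)) .compile_lexicon(lexicon) else lexicon
  out <- list()
  n <- length(tokens)
  for (disease in names(compiled)) {
    entry <- compiled[[disease]]
    i <- 1L
    while (i <= n) {
      hit <- 0L
      for (p in seq_along(entry$tokens)) {
        len <- length(entry$tokens[[p]])
        if (i + len - 1L <= n &&
            identical(tokens[i:(i + len - 1L)], entry$tokens[[p]])) {
          hit <- p
          break
        }
      }
      if (hit) {
        out[[length(out) + 1L]] <- data.frame(
          disease = disease, keyword = entry$keyword[hit],
          offset = i - 1L, stringsAsFactors = FALSE)
        i <- i + length(entry$tokens[[hit]])
      } else {
        i <- i + 1L
      }
    }
  }
  if (!length(out))
    return(data.frame(disease = character(), keyword = character(),
                      offset = integer(), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Filter a corpus to messages containing disease keywords
#'
#' Tokenizes every message and records all keyword matches. The
#' per-keyword side table n_k counts messages containing keyword k (not
#' occurrences); the per-disease table de-duplicates multiple keyword
#' hits within one message, while a message mentioning two diseases
#' counts once toward each. Unreadable records (`NA` text) are skipped
#' with a warning and counted.
#'
#' @param corpus a [MessageCorpus-class].
#' @param lexicon data.frame with `disease`, `keyword` columns.
#' @param dedupe drop exact duplicate texts before matching (off by
#'   default: reposts are counted like any other message).
#' @return a [KeywordMatches-class].
#' @export
filterCorpus <- function(corpus, lexicon, dedupe = FALSE) {
  stopifnot(is(corpus, "MessageCorpus"))
  msgs <- messages(corpus)
  skipped <- sum(is.na(msgs$text))
  if (skipped)
    warning(skipped, " unreadable message record(s) skipped")
  msgs <- msgs[!is.na(msgs$text), , drop = FALSE]
  if (dedupe) msgs <- msgs[!duplicated(msgs$text), , drop = FALSE]

  compiled <- .compile_lexicon(lexicon)
  tokens <- tokenizeText(msgs$text)
  hits <- vector("list", nrow(msgs))
  for (i in seq_len(nrow(msgs))) {
    m <- matchKeywords(tokens[[i]], compiled)
    if (nrow(m)) {
      m$message_id <- msgs$message_id[i]
      hits[[i]] <- m
    }
  }
  hits <- hits[!vapply(hits, is.null, logical(1))]
  matches <- if (length(hits)) {
    res <- do.call(rbind, hits)
    res[c("message_id", "disease", "keyword", "offset")]
  } else {
    data.frame(message_id = character(), disease = character(),
               keyword = character(), offset = integer(),
               stringsAsFactors = FALSE)
  }

  # n_k: messages (not occurrences) containing each keyword
  kwCounts <- lexicon[!duplicated(lexicon[c("disease", "keyword")]),
                      c("disease", "keyword")]
  if (nrow(matches)) {
    uniq <- unique(matches[c("message_id", "disease", "keyword")])
    tab <- table(paste(uniq$disease, uniq$keyword, sep = "\r"))
    kwCounts$n <- as.integer(tab[paste(kwCounts$disease, kwCounts$keyword,
                                       sep = "\r")])
    kwCounts$n[is.na(kwCounts$n)] <- 0L
    uniqD <- unique(matches[c("message_id", "disease")])
    dTab <- table(uniqD$disease)
    dCounts <- data.frame(disease = names(dTab),
                          n = as.integer(dTab), stringsAsFactors = FALSE)
  } else {
    kwCounts$n <- 0L
    dCounts <- data.frame(disease = unique(lexicon$disease), n = 0L,
                          stringsAsFactors = FALSE)
  }
  rownames(kwCounts) <- NULL
  new("KeywordMatches", matches = matches, keywordCounts = kwCounts,
      diseaseCounts = dCounts, nMessages = nrow(msgs),
      nSkipped = as.integer(skipped))
}

#' Matched message ids
#'
#' @param matches a [KeywordMatches-class].
#' @return character vector of message ids with at least one match.
#' @export
matchedIds <- function(matches) {
  unique(matchTable(matches)$message_id)
}

#' Binary disease-label matrix
#'
#' For each message and disease, 1 if the message contains at least one
#' keyword of that disease. This is the binary label correlated against
#' topic loads and used for theme statistics.
#'
#' @param matches a [KeywordMatches-class].
#' @param messageIds row universe (defaults to matched messages only;
#'   pass all corpus ids to include keyword-free messages as zeros).
#' @return integer matrix, messages x diseases, dimnames set.
#' @export
diseaseLabelMatrix <- function(matches, messageIds = matchedIds(matches)) {
  diseases <- diseaseCounts(matches)$disease
  lab <- matrix(0L, length(messageIds), length(diseases),
                dimnames = list(messageIds, diseases))
  mt <- matchTable(matches)
  mt <- mt[mt$message_id %in% messageIds, , drop = FALSE]
  if (nrow(mt)) lab[cbind(mt$message_id, mt$disease)] <- 1L
  lab
}
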