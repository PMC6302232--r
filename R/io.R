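# Serialization: corpora as UTF-8 JSON-lines (one message per line,
# truth as a parallel sidecar keyed by message_id); gazetteers and
# claims as headed CSV; lexica as CSV or YAML.

#' Write a corpus (and its truth sidecar) as JSON-lines
#'
#' One message object per line; absent fields are omitted from the JSON
#' rather than written as null. Output is byte-stable for a given
#' corpus.
#'
#' @param corpus a [MessageCorpus-class].
#' @param path output file for messages.
#' @param truthPath optional output file for the truth sidecar.
#' @return `path`, invisibly.
#' @export
writeCorpus <- function(corpus, path, truthPath = NULL) {
  stopifnot(is(corpus, "MessageCorpus"))
  .write_jsonl(messages(corpus), path)
  if (!is.null(truthPath)) .write_jsonl(truthData(corpus), truthPath)
  invisible(path)
}

.write_jsonl <- function(df, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  for (i in seq_len(nrow(df))) {
    rec <- as.list(df[i, , drop = FALSE])
    rec <- rec[!vapply(rec, function(x) is.na(x), logical(1))]
    line <- jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA)
    writeLines(line, con, useBytes = TRUE)
  }
  invisible(path)
}

#' Read a JSON-lines corpus
#'
#' @param path messages file written by [writeCorpus()] (or any
#'   compatible JSON-lines source).
#' @param truthPath optional truth sidecar file.
#' @return a [MessageCorpus-class].
#' @export
readCorpus <- function(path, truthPath = NULL) {
  msgs <- .read_jsonl(path,
                      template = list(message_id = NA_character_,
                                      author_id = NA_character_,
                                      timestamp = NA_character_,
                                      text = NA_character_,
                                      latitude = NA_real_,
                                      longitude = NA_real_,
                                      location_field = NA_character_))
  truth <- if (is.null(truthPath)) {
    .empty_truth()
  } else {
    .read_jsonl(truthPath,
                template = list(message_id = NA_character_,
                                county = NA_character_,
                                disease = NA_character_,
                                keyword = NA_character_,
                                keyword_relevant = NA,
                                theme = NA_character_,
                                topic = NA_integer_))
  }
  new("MessageCorpus", messages = msgs, truth = truth)
}

.read_jsonl <- function(path, template) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  rows <- lapply(lines, function(l) {
    rec <- jsonlite::fromJSON(l, simplifyVector = TRUE)
    out <- template
    for (nm in names(rec)) if (nm %in% names(out)) {
      val <- rec[[nm]]
      out[[nm]] <- if (is.null(val)) out[[nm]] else val
    }
    as.data.frame(out, stringsAsFactors = FALSE)
  })
  if (!length(rows))
    return(as.data.frame(template, stringsAsFactors = FALSE)[0, , drop = FALSE])
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Read a disease keyword lexicon
#'
#' Accepts either a two-column CSV (`disease`, `keyword`) or a YAML map
#' of disease name to keyword list. Keywords are lowercased phrases of
#' one to four tokens; duplicates within a disease are dropped.
#'
#' @param path CSV or YAML file.
#' @return data.frame with columns `disease`, `keyword`.
#' @export
readLexicon <- function(path) {
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    lst <- yaml::read_yaml(path)
    lex <- data.frame(
      disease = rep(names(lst), lengths(lst)),
      keyword = unlist(lst, use.names = FALSE),
      stringsAsFactors = FALSE)
  } else {
    lex <- read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  }
  if (!all(c("disease", "keyword") %in% names(lex)))
    stop("lexicon must provide 'disease' and 'keyword' columns",
         call. = FALSE)
  lex$keyword <- tolower(trimws(lex$keyword))
  lex <- lex[!duplicated(lex[c("disease", "keyword")]), c("disease", "keyword")]
  if (!nrow(lex)) stop("lexicon is empty", call. = FALSE)
  rownames(lex) <- NULL
  lex
}

#' The bundled 14-disease keyword lexicon
#'
#' A compact consumer-health-style keyword list covering breast, skin,
#' lung, pancreatic, ovarian and prostate cancer, lymphoma, leukemia,
#' asthma, COPD, diabetes, heart disease, hypertension and stroke. It is
#' an editable starting point, not an authoritative vocabulary; users
#' with curated lexica should load their own via [readLexicon()].
#'
#' @return data.frame with columns `disease`, `keyword`.
#' @export
defaultLexicon <- function() {
  readLexicon(system.file("extdata", "default_lexicon.csv",
                          package = "infodemics", mustWork = TRUE))
}

#' Common-word exclusion list for bare place names
#'
#' Place names that are also common English or Spanish nouns, verbs or
#' adjectives (e.g. "reading", "mobile") are never mapped from a bare
#' location field, however concentrated their population. The bundled
#' list is an editable fixture.
#'
#' @param path optional path to a one-word-per-line replacement list.
#' @return lowercase character vector.
#' @export
defaultExclusionWords <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "exclusion_words.txt",
                        package = "infodemics", mustWork = TRUE)
  words <- readLines(path, encoding = "UTF-8")
  words <- tolower(trimws(words))
  words[nzchar(words) & !startsWith(words, "#")]
}

#' Read and write gazetteer / claims CSV files
#'
#' @param path CSV file.
#' @param x data.frame to write.
#' @return the data.frame (readers) or `path` invisibly (writers).
#' @name tabular-io
NULL

#' @rdname tabular-io
#' @export
readGazetteer <- function(path) {
  gaz <- read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  need <- c("place", "state", "county", "population")
  if (!all(need %in% names(gaz)))
    stop("gazetteer must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  gaz
}

#' @rdname tabular-io
#' @export
writeGazetteer <- function(x, path) {
  write.csv(x, path, row.names = FALSE)
  invisible(path)
}

#' @rdname tabular-io
#' @export
readClaims <- function(path) {
  cl <- read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  need <- c("patient_id", "county", "disease")
  if (!all(need %in% names(cl)))
    stop("claims must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  cl
}

#' @rdname tabular-io
#' @export
writeClaims <- function(x, path) {
  write.csv(x, path, row.names = FALSE)
  invisible(path)
}
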