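#' @name accessors
#' @title Accessors for infodemics classes
#'
#' @description Accessor generics for the package's S4 containers. Use
#' these rather than reaching into slots with `@`.
#'
#' @param object an infodemics S4 object.
#' @return the corresponding component (see each method's class
#'   documentation for column descriptions).
NULL

#' @rdname accessors
#' @export
setGeneric("messages", function(object) standardGeneric("messages"))

#' @rdname accessors
#' @export
setGeneric("truthData", function(object) standardGeneric("truthData"))

#' @rdname accessors
#' @export
setGeneric("matchTable", function(object) standardGeneric("matchTable"))

#' @rdname accessors
#' @export
setGeneric("keywordCounts", function(object) standardGeneric("keywordCounts"))

#' @rdname accessors
#' @export
setGeneric("diseaseCounts", function(object) standardGeneric("diseaseCounts"))

#' @rdname accessors
#' @export
setGeneric("nTopics", function(object) standardGeneric("nTopics"))

#' @rdname accessors
#' @export
setGeneric("topicWordDist", function(object) standardGeneric("topicWordDist"))

#' @rdname accessors
#' @export
setGeneric("topicPrior", function(object) standardGeneric("topicPrior"))

#' @rdname accessors
#' @export
setGeneric("vocabularyTokens", function(object) standardGeneric("vocabularyTokens"))

#' @rdname accessors
#' @export
setGeneric("nThemes", function(object) standardGeneric("nThemes"))

#' @rdname accessors
#' @export
setGeneric("themeNames", function(object) standardGeneric("themeNames"))

#' @rdname accessors
#' @export
setGeneric("themeGivenWord", function(object) standardGeneric("themeGivenWord"))

#' @rdname accessors
#' @export
setGeneric("countyTable", function(object) standardGeneric("countyTable"))

#' @rdname accessors
#' @export
setGeneric("stateTable", function(object) standardGeneric("stateTable"))

#' @rdname accessors
#' @export
setMethod("messages", "MessageCorpus", function(object) object@messages)

#' @rdname accessors
#' @export
setMethod("truthData", "MessageCorpus", function(object) object@truth)

#' @rdname accessors
#' @export
setMethod("matchTable", "KeywordMatches", function(object) object@matches)

#' @rdname accessors
#' @export
setMethod("keywordCounts", "KeywordMatches", function(object) object@keywordCounts)

#' @rdname accessors
#' @export
setMethod("diseaseCounts", "KeywordMatches", function(object) object@diseaseCounts)

#' @rdname accessors
#' @export
setMethod("nTopics", "TopicModel", function(object) object@K)

#' @rdname accessors
#' @export
setMethod("topicWordDist", "TopicModel", function(object) object@phi)

#' @rdname accessors
#' @export
setMethod("topicPrior", "TopicModel", function(object) object@topicPrior)

#' @rdname accessors
#' @export
setMethod("vocabularyTokens", "TopicModel", function(object) colnames(object@phi))

#' @rdname accessors
#' @export
setMethod("nThemes", "ThemeModel", function(object) ncol(object@W))

#' @rdname accessors
#' @export
setMethod("themeNames", "ThemeModel", function(object) object@themeNames)

#' @rdname accessors
#' @export
setMethod("themeGivenWord", "ThemeModel", function(object) object@pThemeGivenWord)

#' @rdname accessors
#' @export
setMethod("countyTable", "PrevalenceTable", function(object) object@county)

#' @rdname accessors
#' @export
setMethod("stateTable", "PrevalenceTable", function(object) object@state)

setMethod("show", "GeneratorConfig", function(object) {
  cat("GeneratorConfig:", object@nMessages, "messages,",
      object@nUsers, "authors,", nrow(object@counties), "counties\n")
  cat("  diseases:", paste(unique(object@keywords$disease), collapse = ", "), "\n")
  cat("  themes:", length(object@themeNames),
      " topics:", object@nTopics, " vocabulary:", object@vocabSize, "\n")
  cat("  seed:", object@seed, "\n")
})

setMethod("show", "MessageCorpus", function(object) {
  cat("MessageCorpus with", nrow(object@messages), "messages from",
      length(unique(object@messages$author_id)), "authors\n")
  if (nrow(object@truth)) cat("  ground-truth sidecar present\n")
})

setMethod("show", "KeywordMatches", function(object) {
  cat("KeywordMatches:", nrow(object@matches), "matches in",
      length(unique(object@matches$message_id)), "of",
      object@nMessages, "messages\n")
  cat("  diseases:", nrow(object@diseaseCounts),
      " keywords:", nrow(object@keywordCounts), "\n")
  if (object@nSkipped) cat("  skipped records:", object@nSkipped, "\n")
})

setMethod("show", "TopicModel", function(object) {
  cat("TopicModel:", object@K, "topics over",
      ncol(object@phi), "tokens (alpha =", format(object@alpha),
      ", beta =", format(object@beta), ")\n")
})

setMethod("show", "ThemeModel", function(object) {
  cat("ThemeModel:", ncol(object@W), "themes over",
      nrow(object@W), "topics\n")
  cat("  themes:", paste(object@themeNames, collapse = ", "), "\n")
})

setMethod("show", "PrevalenceTable", function(object) {
  cat("PrevalenceTable:", length(unique(object@county$county)), "counties x",
      length(unique(object@county$disease)), "diseases\n")
})
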