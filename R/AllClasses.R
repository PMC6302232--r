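#' Configuration for the synthetic corpus generator
#'
#' Describes the generative world the simulator draws from: a county map
#' with populations, a disease keyword table with true per-keyword
#' relevance rates (the planted correction factors), and a
#' theme -> topic -> word text hierarchy. Messages are generated by
#' sampling an author (which fixes the county), deciding whether the
#' message carries a disease keyword and whether that use is genuinely
#' about the disease, sampling a theme from a (possibly disease-biased)
#' theme prior, a topic from the theme, and words from the topic.
#'
#' @slot nUsers number of distinct authors.
#' @slot nMessages number of messages to emit.
#' @slot counties data.frame with columns `county`, `population`,
#'   `lonMin`, `lonMax`, `latMin`, `latMax` (rectangular county extents
#'   used both to place coordinates and as boundary fixtures).
#' @slot keywords data.frame with columns `disease`, `keyword`,
#'   `relevance`: the true probability that a use of the keyword refers
#'   to the disease.
#' @slot themeNames character vector of theme labels.
#' @slot nTopics total number of topics, partitioned evenly across themes.
#' @slot vocabSize topical vocabulary size, partitioned evenly across
#'   themes so that topics within a theme share a word block.
#' @slot themeTopicConc Dirichlet concentration of each theme's
#'   distribution over its own topics.
#' @slot topicWordConc Dirichlet concentration of each topic's
#'   distribution over its theme's word block.
#' @slot diseaseThemeBias disease x theme matrix of multiplicative
#'   weights applied to the theme prior of messages truly about the
#'   disease (1 = no bias).
#' @slot pKeyword probability that a message carries an injected keyword.
#' @slot geoNoise named numeric `c(coordinates=, location_field=, none=)`
#'   summing to 1: how each message exposes location information.
#' @slot msgLenRange integer `c(min, max)` message length in tokens.
#' @slot seed integer seed; identical seeds give byte-identical output.
#' @seealso [generatorConfig()], [simulateCorpus()]
#' @export
setClass("GeneratorConfig",
  slots = c(
    nUsers = "integer",
    nMessages = "integer",
    counties = "data.frame",
    keywords = "data.frame",
    themeNames = "character",
    nTopics = "integer",
    vocabSize = "integer",
    themeTopicConc = "numeric",
    topicWordConc = "numeric",
    diseaseThemeBias = "matrix",
    pKeyword = "numeric",
    geoNoise = "numeric",
    msgLenRange = "integer",
    seed = "integer"
  )
)

setValidity("GeneratorConfig", function(object) {
  msg <- character()
  if (object@nUsers < 1L) msg <- c(msg, "nUsers must be >= 1")
  if (object@nMessages < 0L) msg <- c(msg, "nMessages must be >= 0")
  cn <- c("county", "population", "lonMin", "lonMax", "latMin", "latMax")
  if (!all(cn %in% names(object@counties)))
    msg <- c(msg, paste("counties must have columns:", paste(cn, collapse = ", ")))
  else if (any(object@counties$population <= 0))
    msg <- c(msg, "county populations must be positive")
  kn <- c("disease", "keyword", "relevance")
  if (!all(kn %in% names(object@keywords)))
    msg <- c(msg, "keywords must have columns disease, keyword, relevance")
  else if (any(object@keywords$relevance < 0 | object@keywords$relevance > 1))
    msg <- c(msg, "keyword relevance ('keyword_relevance') must lie in [0, 1]")
  if (object@pKeyword < 0 || object@pKeyword > 1)
    msg <- c(msg, "pKeyword must lie in [0, 1]")
  gn <- c("coordinates", "location_field", "none")
  if (!identical(sort(names(object@geoNoise)), sort(gn)))
    msg <- c(msg, "geoNoise must be named coordinates/location_field/none")
  else {
    if (any(object@geoNoise < 0 | object@geoNoise > 1))
      msg <- c(msg, "geoNoise fractions must lie in [0, 1]")
    if (abs(sum(object@geoNoise) - 1) > 1e-8)
      msg <- c(msg, "geoNoise fractions must sum to 1")
  }
  if (any(object@diseaseThemeBias <= 0))
    msg <- c(msg, "diseaseThemeBias weights must be positive")
  if (object@nTopics %% length(object@themeNames) != 0L)
    msg <- c(msg, "nTopics must be a multiple of the number of themes")
  if (object@vocabSize %% length(object@themeNames) != 0L)
    msg <- c(msg, "vocabSize must be a multiple of the number of themes")
  if (length(object@msgLenRange) != 2L ||
      object@msgLenRange[1] < 1L ||
      object@msgLenRange[2] < object@msgLenRange[1])
    msg <- c(msg, "msgLenRange must be c(min, max) with 1 <= min <= max")
  if (length(msg)) msg else TRUE
})

#' A corpus of short social-media messages
#'
#' Container for message records and, for synthetic corpora, a parallel
#' ground-truth table (the "sidecar") keyed by `message_id`. The truth
#' table records the author's county, which disease (if any) the message
#' is genuinely about, the injected keyword and whether its use was
#' relevant, and the generating theme and topic. Truth is stored beside
#' the messages, never inside the text, so downstream filtering cannot
#' see it.
#'
#' @slot messages data.frame with columns `message_id`, `author_id`,
#'   `timestamp` (ISO-8601), `text`, `latitude`, `longitude` (NA when
#'   absent; present or absent together), `location_field` (NA when
#'   absent).
#' @slot truth zero-row data.frame for real corpora; for synthetic
#'   corpora, columns `message_id`, `county`, `disease`, `keyword`,
#'   `keyword_relevant`, `theme`, `topic`.
#' @seealso [simulateCorpus()], [readCorpus()], [writeCorpus()]
#' @export
setClass("MessageCorpus",
  slots = c(messages = "data.frame", truth = "data.frame")
)

setValidity("MessageCorpus", function(object) {
  msg <- character()
  m <- object@messages
  need <- c("message_id", "author_id", "timestamp", "text",
            "latitude", "longitude", "location_field")
  if (!all(need %in% names(m)))
    msg <- c(msg, paste("messages must have columns:", paste(need, collapse = ", ")))
  else {
    if (anyDuplicated(m$message_id)) msg <- c(msg, "message_id must be unique")
    if (any(!is.na(m$text) & !nzchar(m$text))) msg <- c(msg, "text must be non-empty")
    if (any(is.na(m$latitude) != is.na(m$longitude)))
      msg <- c(msg, "latitude and longitude must be present or absent together")
  }
  if (nrow(object@truth) &&
      !all(c("message_id", "county") %in% names(object@truth)))
    msg <- c(msg, "truth must have message_id and county columns")
  if (length(msg)) msg else TRUE
})

#' Keyword matches over a filtered corpus
#'
#' Result of [filterCorpus()]: every maximal keyword-phrase match, plus
#' the per-keyword side table n_k (number of messages containing keyword
#' k; a message with several hits of the same keyword counts once) and
#' the de-duplicated per-disease message counts.
#'
#' @slot matches data.frame `message_id`, `disease`, `keyword`, `offset`
#'   (0-based token offset of the phrase start).
#' @slot keywordCounts data.frame `disease`, `keyword`, `n` covering
#'   every lexicon keyword (zeros included).
#' @slot diseaseCounts data.frame `disease`, `n` (messages mentioning
#'   the disease at least once; a message naming two diseases counts
#'   once toward each).
#' @slot nMessages number of corpus messages scanned.
#' @slot nSkipped unreadable records skipped with a warning.
#' @export
setClass("KeywordMatches",
  slots = c(
    matches = "data.frame",
    keywordCounts = "data.frame",
    diseaseCounts = "data.frame",
    nMessages = "integer",
    nSkipped = "integer"
  )
)

setValidity("KeywordMatches", function(object) {
  msg <- character()
  if (nrow(object@matches) && any(object@matches$offset < 0))
    msg <- c(msg, "offsets must be non-negative token indices")
  if (nrow(object@keywordCounts) && any(object@keywordCounts$n < 0))
    msg <- c(msg, "keyword counts must be non-negative")
  if (length(msg)) msg else TRUE
})

#' A fitted topic model
#'
#' Latent Dirichlet allocation fitted by collapsed Gibbs sampling. `phi`
#' holds the topic-word distributions (one row per topic, columns named
#' by the vocabulary) averaged over post-burn-in sweeps with Dirichlet
#' smoothing; `topicPrior` is the marginal topic distribution estimated
#' the same way.
#'
#' @slot K number of topics.
#' @slot phi K x V matrix; each row a distribution over the vocabulary.
#' @slot topicPrior length-K simplex, the corpus-level p(topic).
#' @slot alpha,beta Dirichlet concentrations (document-topic, topic-word).
#' @slot logLik joint log p(w, z) recorded at every Gibbs sweep.
#' @slot seed sampler seed.
#' @seealso [fitLda()], [messageTopicLoads()]
#' @export
setClass("TopicModel",
  slots = c(
    K = "integer", phi = "matrix", topicPrior = "numeric",
    alpha = "numeric", beta = "numeric", logLik = "numeric",
    seed = "integer"
  )
)

setValidity("TopicModel", function(object) {
  msg <- character()
  if (nrow(object@phi) != object@K) msg <- c(msg, "phi must have K rows")
  if (any(abs(rowSums(object@phi) - 1) > 1e-9))
    msg <- c(msg, "each row of phi must sum to 1")
  if (abs(sum(object@topicPrior) - 1) > 1e-9)
    msg <- c(msg, "topicPrior must sum to 1")
  if (is.null(colnames(object@phi)))
    msg <- c(msg, "phi columns must be named by vocabulary tokens")
  if (length(msg)) msg else TRUE
})

#' A fitted theme model
#'
#' Themes are clusters of topics obtained by nonnegative matrix
#' factorization of the topic-word matrix, phi ~ W H with W (topic x
#' theme) and H (theme x word) nonnegative. Row-normalizing H gives
#' p(word | theme); the theme prior is proportional to the column mass
#' of W; Bayes' rule then yields p(theme | word), the quantity used to
#' compute per-message theme distributions.
#'
#' @slot W K x T nonnegative topic-to-theme weights.
#' @slot H T x V nonnegative theme-to-word weights (columns named).
#' @slot pWordGivenTheme T x V; rows sum to 1.
#' @slot pThemeGivenWord V x T; rows sum to 1.
#' @slot themePrior length-T simplex.
#' @slot themeNames labels for the T themes (semantic names such as
#'   "Awareness" are manual configuration, not model output).
#' @slot seed initialization seed.
#' @seealso [fitThemes()], [messageThemeLoads()]
#' @export
setClass("ThemeModel",
  slots = c(
    W = "matrix", H = "matrix",
    pWordGivenTheme = "matrix", pThemeGivenWord = "matrix",
    themePrior = "numeric", themeNames = "character", seed = "integer"
  )
)

setValidity("ThemeModel", function(object) {
  msg <- character()
  if (any(object@W < 0) || any(object@H < 0))
    msg <- c(msg, "W and H must be nonnegative")
  if (ncol(object@W) != length(object@themeNames))
    msg <- c(msg, "themeNames must have one entry per theme")
  if (nrow(object@pWordGivenTheme) &&
      any(abs(rowSums(object@pWordGivenTheme) - 1) > 1e-8))
    msg <- c(msg, "p(word|theme) rows must sum to 1")
  if (nrow(object@pThemeGivenWord) &&
      any(abs(rowSums(object@pThemeGivenWord) - 1) > 1e-8))
    msg <- c(msg, "p(theme|word) rows must sum to 1")
  if (length(msg)) msg else TRUE
})

#' Claims-based prevalence per county and statewide
#'
#' County prevalence is the number of unique patients in the county with
#' at least one claim for the disease, divided by county population. Two
#' state summaries are kept: the unweighted mean of county prevalences,
#' and the pooled share (statewide unique patients over statewide
#' population); both are standard and they differ whenever county
#' populations differ, so neither is silently preferred.
#'
#' @slot county data.frame `county`, `disease`, `patients`, `population`,
#'   `prevalence`.
#' @slot state data.frame `disease`, `meanCountyPrevalence`,
#'   `pooledPatients`, `statePopulation`, `pooledShare`.
#' @seealso [countyPrevalence()], [statePrevalence()]
#' @export
setClass("PrevalenceTable",
  slots = c(county = "data.frame", state = "data.frame")
)

setValidity("PrevalenceTable", function(object) {
  msg <- character()
  cty <- object@county
  if (nrow(cty) && any(cty$prevalence < 0))
    msg <- c(msg, "prevalence must be >= 0")
  if (length(msg)) msg else TRUE
})
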