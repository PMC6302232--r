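# Synthetic world: a small state of rectangular counties, a handful of
# diseases with keywords of varying specificity, and a theme -> topic ->
# word text hierarchy with planted, recoverable structure.

.default_counties <- function() {
  data.frame(
    county = c("Alder", "Birch", "Cedar", "Dogwood", "Elm"),
    population = c(20000L, 12000L, 8000L, 5000L, 3000L),
    lonMin = c(-78.0, -77.2, -76.4, -78.0, -77.2),
    lonMax = c(-77.2, -76.4, -75.6, -77.2, -76.4),
    latMin = c(40.0, 40.0, 40.0, 40.6, 40.6),
    latMax = c(40.6, 40.6, 40.6, 41.2, 41.2),
    stringsAsFactors = FALSE
  )
}

# Keyword specificity defaults mirror the ambiguity spectrum seen in
# consumer health language: cancer terms are nearly always literal,
# "stroke" is mostly metaphorical (golf/heat/paint stroke), and "heart
# attack"/"blood pressure" sit in between.
.default_keywords <- function() {
  data.frame(
    disease = c("breast cancer", "breast cancer", "asthma", "asthma",
                "diabetes", "stroke", "heart disease", "heart disease",
                "hypertension", "hypertension"),
    keyword = c("breast cancer", "mammogram", "asthma", "inhaler",
                "diabetes", "stroke", "heart disease", "heart attack",
                "hypertension", "blood pressure"),
    relevance = c(1.0, 0.95, 0.93, 0.85, 0.97, 0.15, 0.95, 0.60,
                  0.98, 0.80),
    stringsAsFactors = FALSE
  )
}

.default_theme_bias <- function(diseases, themes) {
  bias <- matrix(1, length(diseases), length(themes),
                 dimnames = list(diseases, themes))
  set_if <- function(d, t, w) {
    if (d %in% diseases && t %in% themes) bias[d, t] <<- w
  }
  set_if("breast cancer", "Awareness", 3)
  set_if("asthma", "Personal Experience", 3)
  set_if("heart disease", "Risk Factor", 3)
  set_if("hypertension", "Risk Factor", 2)
  set_if("diabetes", "Personal Experience", 1.5)
  set_if("stroke", "News", 2)
  bias
}

#' Build a synthetic-corpus generator configuration
#'
#' All defaults describe the package's reference simulation world: five
#' counties of unequal population, six diseases whose keywords span the
#' specificity spectrum (from always-literal cancer terms to the mostly
#' metaphorical "stroke" at 15% relevance), four themes with three
#' topics each, and a 240-token topical vocabulary split into one word
#' block per theme so that topics within a theme overlap in vocabulary
#' while themes stay separable.
#'
#' @param nUsers,nMessages corpus size (authors, messages).
#' @param counties,keywords,themeNames,diseaseThemeBias world structure;
#'   see [GeneratorConfig-class] for the required columns.
#' @param nTopics,vocabSize,themeTopicConc,topicWordConc text hierarchy
#'   sizes and Dirichlet concentrations.
#' @param pKeyword probability a message carries an injected keyword.
#' @param geoNoise named fractions `coordinates`, `location_field`,
#'   `none`, summing to 1.
#' @param msgLenRange token-count range per message. Message length is
#'   bounded rather than character-limited; the platform's historical
#'   140-character cap is honored only loosely.
#' @param seed integer seed for all generator randomness.
#' @return a validated [GeneratorConfig-class] object.
#' @export
#' @examples
#' cfg <- generatorConfig(nMessages = 50L, seed = 7L)
#' corpus <- simulateCorpus(cfg)
#' corpus
generatorConfig <- function(nUsers = 400L,
                            nMessages = 2000L,
                            counties = .default_counties(),
                            keywords = .default_keywords(),
                            themeNames = c("Awareness", "Personal Experience",
                                           "Risk Factor", "News"),
                            nTopics = 12L,
                            vocabSize = 240L,
                            themeTopicConc = 1.0,
                            topicWordConc = 0.3,
                            diseaseThemeBias = NULL,
                            pKeyword = 0.45,
                            geoNoise = c(coordinates = 0.25,
                                         location_field = 0.55,
                                         none = 0.20),
                            msgLenRange = c(5L, 25L),
                            seed = 1L) {
  diseases <- unique(keywords$disease)
  if (is.null(diseaseThemeBias))
    diseaseThemeBias <- .default_theme_bias(diseases, themeNames)
  check_prob(keywords$relevance, "keyword_relevance")
  check_prob(pKeyword, "pKeyword")
  new("GeneratorConfig",
      nUsers = as.integer(nUsers), nMessages = as.integer(nMessages),
      counties = counties, keywords = keywords, themeNames = themeNames,
      nTopics = as.integer(nTopics), vocabSize = as.integer(vocabSize),
      themeTopicConc = themeTopicConc, topicWordConc = topicWordConc,
      diseaseThemeBias = diseaseThemeBias, pKeyword = pKeyword,
      geoNoise = geoNoise, msgLenRange = as.integer(msgLenRange),
      seed = as.integer(seed))
}

.main_city <- function(county) paste0(county, "ville")

# Empty messages / truth frames with the canonical column set.
.empty_messages <- function() {
  data.frame(message_id = character(), author_id = character(),
             timestamp = character(), text = character(),
             latitude = numeric(), longitude = numeric(),
             location_field = character(), stringsAsFactors = FALSE)
}

.empty_truth <- function() {
  data.frame(message_id = character(), county = character(),
             disease = character(), keyword = character(),
             keyword_relevant = logical(), theme = character(),
             topic = integer(), stringsAsFactors = FALSE)
}

#' Generate a synthetic message corpus with ground truth
#'
#' Draws `nMessages` messages under the configured generative model.
#' Each message: an author is sampled (the author fixes the county); with
#' probability `pKeyword` a disease keyword is injected and its relevance
#' flag drawn from the keyword's true relevance rate; a theme is sampled
#' from the theme prior, multiplied by the disease-theme bias when the
#' message is genuinely about a disease; a topic is drawn from the
#' theme and tokens from the topic; surface noise (capitalization,
#' punctuation, URLs, hashtags) is added; geodata are attached per
#' `geoNoise`. The full generation record is stored in the truth
#' sidecar, never in the text.
#'
#' Identical configurations (including seed) produce byte-identical
#' corpora.
#'
#' @param config a [GeneratorConfig-class].
#' @return a [MessageCorpus-class] with a populated truth slot.
#' @export
simulateCorpus <- function(config) {
  validObject(config)
  with_seed(config@seed, .simulate_corpus(config))
}

.simulate_corpus <- function(config) {
  n <- config@nMessages
  if (n == 0L)
    return(new("MessageCorpus", messages = .empty_messages(),
               truth = .empty_truth()))

  nT <- length(config@themeNames)
  K <- config@nTopics
  V <- config@vocabSize
  perTheme <- K %/% nT
  blockSize <- V %/% nT
  vocabWords <- sprintf("word%04d", seq_len(V))
  topicTheme <- rep(seq_len(nT), each = perTheme)

  # theme -> topic distributions (support restricted to own topics)
  thetaTheme <- matrix(0, nT, K)
  for (t in seq_len(nT)) {
    own <- which(topicTheme == t)
    thetaTheme[t, own] <- rdirichlet1(rep(config@themeTopicConc, perTheme))
  }
  # topic -> word distributions (support restricted to the theme's block)
  phiTrue <- matrix(0, K, V)
  for (k in seq_len(K)) {
    blk <- ((topicTheme[k] - 1L) * blockSize + 1L):(topicTheme[k] * blockSize)
    phiTrue[k, blk] <- rdirichlet1(rep(config@topicWordConc, blockSize))
  }

  counties <- config@counties
  authorCounty <- sample(counties$county, config@nUsers, replace = TRUE,
                         prob = counties$population)
  authorIds <- sprintf("u%04d", seq_len(config@nUsers))

  kw <- config@keywords
  aIdx <- sample.int(config@nUsers, n, replace = TRUE)
  hasKw <- runif(n) < config@pKeyword
  kwIdx <- sample.int(nrow(kw), n, replace = TRUE)
  relevant <- hasKw & (runif(n) < kw$relevance[kwIdx])
  geoMode <- sample(names(config@geoNoise), n, replace = TRUE,
                    prob = config@geoNoise)
  tsec <- runif(n, as.numeric(as.POSIXct("2012-01-01", tz = "UTC")),
                as.numeric(as.POSIXct("2015-12-31 23:59:59", tz = "UTC")))
  timestamps <- format(as.POSIXct(floor(tsec), origin = "1970-01-01",
                                  tz = "UTC"), "%Y-%m-%dT%H:%M:%SZ")

  lenMin <- config@msgLenRange[1]; lenMax <- config@msgLenRange[2]
  junkLoc <- c("planet earth", "somewhere out there", "the moon", "wherever")

  text <- character(n); lat <- rep(NA_real_, n); lon <- rep(NA_real_, n)
  locField <- rep(NA_character_, n)
  themeId <- integer(n); topicId <- integer(n)

  for (i in seq_len(n)) {
    prior <- rep(1 / nT, nT)
    if (relevant[i]) {
      prior <- prior * config@diseaseThemeBias[kw$disease[kwIdx[i]], ]
      prior <- prior / sum(prior)
    }
    th <- sample.int(nT, 1L, prob = prior)
    tp <- sample.int(K, 1L, prob = thetaTheme[th, ])
    themeId[i] <- th; topicId[i] <- tp

    len <- if (lenMin == lenMax) lenMin else
      sample.int(lenMax - lenMin + 1L, 1L) + lenMin - 1L
    tokens <- vocabWords[sample.int(V, len, replace = TRUE,
                                    prob = phiTrue[tp, ])]
    # surface noise first, so an injected keyword phrase stays contiguous;
    # case and punctuation noise are undone by tokenization
    if (runif(1) < 0.08) {
      at <- sample.int(length(tokens) + 1L, 1L) - 1L
      tokens <- append(tokens, sprintf("https://t.ex/%04x",
                                       sample.int(65535L, 1L)), after = at)
    }
    if (!hasKw[i] && runif(1) < 0.05) {
      j <- sample.int(length(tokens), 1L)
      tokens[j] <- paste0("#", tokens[j])
    }
    if (hasKw[i]) {
      kwTokens <- strsplit(kw$keyword[kwIdx[i]], " ", fixed = TRUE)[[1]]
      at <- sample.int(length(tokens) + 1L, 1L) - 1L
      tokens <- append(tokens, kwTokens, after = at)
    }
    if (runif(1) < 0.30)
      tokens[1] <- paste0(toupper(substr(tokens[1], 1, 1)),
                          substr(tokens[1], 2, nchar(tokens[1])))
    txt <- paste(tokens, collapse = " ")
    if (runif(1) < 0.15) txt <- paste0(txt, "!!")
    text[i] <- txt

    cty <- authorCounty[aIdx[i]]
    crow <- counties[counties$county == cty, ]
    if (geoMode[i] == "coordinates") {
      lat[i] <- round(runif(1, crow$latMin, crow$latMax), 5)
      lon[i] <- round(runif(1, crow$lonMin, crow$lonMax), 5)
    } else if (geoMode[i] == "location_field") {
      u <- runif(1)
      locField[i] <-
        if (u < 0.60) paste0(.main_city(cty), ", PA")
        else if (u < 0.80) .main_city(cty)
        else if (u < 0.90) "Fairview"
        else junkLoc[sample.int(length(junkLoc), 1L)]
    }
  }

  msgs <- data.frame(
    message_id = sprintf("m%06d", seq_len(n)),
    author_id = authorIds[aIdx],
    timestamp = timestamps,
    text = text,
    latitude = lat, longitude = lon,
    location_field = locField,
    stringsAsFactors = FALSE
  )
  truth <- data.frame(
    message_id = msgs$message_id,
    county = authorCounty[aIdx],
    disease = ifelse(relevant, kw$disease[kwIdx], NA_character_),
    keyword = ifelse(hasKw, kw$keyword[kwIdx], NA_character_),
    keyword_relevant = ifelse(hasKw, relevant, NA),
    theme = config@themeNames[themeId],
    topic = topicId,
    stringsAsFactors = FALSE
  )
  new("MessageCorpus", messages = msgs, truth = truth)
}

#' Generate a synthetic place gazetteer
#'
#' Deterministic offline stand-in for a geocoding service: one main city
#' and one secondary place per county, a small same-named out-of-state
#' twin for each main city (so the 90% population-concentration rule is
#' exercised non-trivially), a deliberately ambiguous "Fairview" split
#' across several counties, and a fully concentrated place ("Reading")
#' whose name collides with a common English word and must therefore be
#' ignored under the exclusion-list rule.
#'
#' @param config a [GeneratorConfig-class].
#' @return data.frame with columns `place`, `state`, `county`,
#'   `population`.
#' @export
simulateGazetteer <- function(config) {
  validObject(config)
  counties <- config@counties
  rows <- list()
  for (i in seq_len(nrow(counties))) {
    cty <- counties$county[i]; pop <- counties$population[i]
    rows[[length(rows) + 1L]] <- data.frame(
      place = .main_city(cty), state = "PA", county = cty,
      population = as.integer(round(0.55 * pop)), stringsAsFactors = FALSE)
    rows[[length(rows) + 1L]] <- data.frame(
      place = paste(cty, "springs"), state = "PA", county = cty,
      population = as.integer(round(0.25 * pop)), stringsAsFactors = FALSE)
    rows[[length(rows) + 1L]] <- data.frame(
      place = .main_city(cty), state = "OH", county = paste(cty, "OH"),
      population = as.integer(round(0.02 * pop)) + 1L,
      stringsAsFactors = FALSE)
  }
  nAmb <- min(3L, nrow(counties))
  for (i in seq_len(nAmb)) {
    rows[[length(rows) + 1L]] <- data.frame(
      place = "Fairview", state = c("PA", "NY", "OH")[i],
      county = counties$county[i],
      population = c(1000L, 900L, 800L)[i], stringsAsFactors = FALSE)
  }
  rows[[length(rows) + 1L]] <- data.frame(
    place = "Reading", state = "PA", county = counties$county[min(2L, nrow(counties))],
    population = 2000L, stringsAsFactors = FALSE)
  do.call(rbind, rows)
}

#' County boundary fixtures for the synthetic world
#'
#' Returns each county's extent as a closed polygon (here rectangles;
#' [countyFromCoordinates()] accepts arbitrary simple polygons, so real
#' county shapes can be supplied instead).
#'
#' @param config a [GeneratorConfig-class].
#' @return named list of matrices with columns `lon`, `lat`.
#' @export
simulateBoundaries <- function(config) {
  validObject(config)
  counties <- config@counties
  out <- lapply(seq_len(nrow(counties)), function(i) {
    r <- counties[i, ]
    m <- cbind(lon = c(r$lonMin, r$lonMax, r$lonMax, r$lonMin, r$lonMin),
               lat = c(r$latMin, r$latMin, r$latMax, r$latMax, r$latMin))
    m
  })
  names(out) <- counties$county
  out
}

#' Build a uniform prevalence-truth matrix
#'
#' Expands per-disease rates into the (county x disease) probability
#' matrix consumed by [simulateClaims()], using the same rate in every
#' county.
#'
#' @param config a [GeneratorConfig-class].
#' @param rates named numeric vector of per-disease probabilities.
#' @return counties x diseases matrix of probabilities.
#' @export
uniformPrevalenceTruth <- function(config, rates) {
  check_prob(rates, "prevalence rates")
  matrix(rep(rates, each = nrow(config@counties)),
         nrow = nrow(config@counties),
         dimnames = list(config@counties$county, names(rates)))
}

#' Generate synthetic claims records
#'
#' Every synthetic resident of county `c` acquires at least one claim for
#' disease `d` with probability `prevalenceTruth[c, d]`; claim-positive
#' patients may hold several claims for the same disease (duplicates are
#' drawn deliberately, so unique-patient de-duplication downstream is
#' exercised).
#'
#' @param config a [GeneratorConfig-class].
#' @param prevalenceTruth counties x diseases probability matrix (row
#'   names must be configured counties), or a data.frame with columns
#'   `county`, `disease`, `prob`.
#' @param seed claims-stream seed (default derived from the config seed).
#' @return data.frame with columns `patient_id`, `county`, `disease`.
#' @export
simulateClaims <- function(config, prevalenceTruth,
                           seed = config@seed + 1L) {
  validObject(config)
  if (is.data.frame(prevalenceTruth)) {
    cn <- unique(prevalenceTruth$county)
    dn <- unique(prevalenceTruth$disease)
    m <- matrix(0, length(cn), length(dn), dimnames = list(cn, dn))
    m[cbind(prevalenceTruth$county, prevalenceTruth$disease)] <-
      prevalenceTruth$prob
    prevalenceTruth <- m
  }
  check_prob(prevalenceTruth, "prevalence_truth")
  unknown <- setdiff(rownames(prevalenceTruth), config@counties$county)
  if (length(unknown))
    stop("prevalence_truth names counties absent from the configuration: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  with_seed(seed, {
    out <- list()
    for (cty in rownames(prevalenceTruth)) {
      pop <- config@counties$population[config@counties$county == cty]
      for (d in colnames(prevalenceTruth)) {
        p <- prevalenceTruth[cty, d]
        if (p <= 0) next
        pos <- which(runif(pop) < p)
        if (!length(pos)) next
        nClaims <- 1L + rpois(length(pos), 0.4)
        out[[length(out) + 1L]] <- data.frame(
          patient_id = rep(sprintf("%s-p%05d", cty, pos), nClaims),
          county = cty, disease = d, stringsAsFactors = FALSE)
      }
    }
    if (!length(out))
      return(data.frame(patient_id = character(), county = character(),
                        disease = character(), stringsAsFactors = FALSE))
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res
  })
}
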