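# End-to-end orchestration: simulate (optional) -> filter -> geolocate
# -> correct -> topics -> themes -> prevalence -> reports. Every stage
# writes its artifact; a JSON manifest records seeds, sizes and file
# checksums so identical configurations can be verified byte-for-byte.

#' Message-volume share versus prevalence share
#'
#' For each disease, the corrected message count as a share of all
#' corrected messages, side by side with the claims pooled prevalence
#' share (statewide patients over statewide population). Percentages
#' round half-up to two decimals. Diseases present on only one side
#' are excluded with a warning.
#'
#' @param corrected data.frame with `disease`,
#'   `correctedCountReported` and optionally `users` (e.g.
#'   `correctionTable()$table`).
#' @param prevalence a [PrevalenceTable-class], or a data.frame with
#'   `disease` and `pooledShare`.
#' @return data.frame `disease`, `correctedCount`, `messageSharePct`,
#'   `users`, `prevalenceSharePct`.
#' @export
volumeShareTable <- function(corrected, prevalence) {
  state <- if (is(prevalence, "PrevalenceTable")) stateTable(prevalence)
           else prevalence
  common <- intersect(corrected$disease, state$disease)
  dropped <- setdiff(union(corrected$disease, state$disease), common)
  if (length(dropped))
    warning("disease(s) missing on one side, excluded: ",
            paste(dropped, collapse = ", "))
  corrected <- corrected[corrected$disease %in% common, , drop = FALSE]
  total <- sum(corrected$correctedCountReported)
  data.frame(
    disease = corrected$disease,
    correctedCount = corrected$correctedCountReported,
    messageSharePct = proportionPct(corrected$correctedCountReported, total),
    users = if ("users" %in% names(corrected)) corrected$users else NA_integer_,
    prevalenceSharePct = roundHalfUp(
      100 * state$pooledShare[match(corrected$disease, state$disease)], 2),
    stringsAsFactors = FALSE)
}

#' Share of keyword messages that do not reference the disease
#'
#' (raw - relevant) / raw as a percentage to two decimals: the
#' complement of the aggregate correction factor, e.g. the fraction of
#' "stroke" messages that are heat strokes, golf strokes and metaphors.
#'
#' @param raw messages containing the disease's keywords.
#' @param relevant messages genuinely referencing the disease.
#' @return percentage (`NA` when `raw` is zero).
#' @export
#' @examples
#' nonreferenceShare(53858, 8142)  # 84.88
nonreferenceShare <- function(raw, relevant) {
  stopifnot(all(relevant <= raw))
  proportionPct(raw - relevant, raw)
}

.pipeline_defaults <- function() {
  list(
    seed = 1L,
    generator = list(n_users = 400L, n_messages = 2000L),
    correction = list(sample_size = 30L),
    topics = list(k = 10L, alpha = NULL, beta = 0.01,
                  iterations = 400L, burn_in = 100L,
                  min_author_frac = 0.05),
    themes = list(t = 4L, labels = NULL),
    prevalence = list(rates = list(
      "breast cancer" = 0.024, "asthma" = 0.085, "diabetes" = 0.17,
      "stroke" = 0.03, "heart disease" = 0.19, "hypertension" = 0.36)),
    lexicon = NULL
  )
}

.merge_config <- function(defaults, user) {
  for (nm in names(user)) {
    if (is.list(defaults[[nm]]) && is.list(user[[nm]]))
      defaults[[nm]] <- .merge_config(defaults[[nm]], user[[nm]])
    else defaults[[nm]] <- user[[nm]]
  }
  defaults
}

#' Run the full pipeline
#'
#' Validates the configuration (failing fast, before any output is
#' written), simulates the synthetic world, filters, geolocates,
#' estimates correction factors, fits topics and themes, computes
#' prevalence, and writes every stage artifact plus a JSON run
#' manifest into `outdir`. Re-running with the same configuration and
#' seed reproduces byte-identical CSV artifacts.
#'
#' @param config path to a YAML configuration, or an equivalent named
#'   list; unspecified entries fall back to the bundled demo defaults.
#' @param outdir output directory (created; must be empty or absent
#'   unless `overwrite`).
#' @param overwrite allow writing into an existing directory.
#' @return invisibly, the manifest list.
#' @export
runPipeline <- function(config = list(), outdir, overwrite = FALSE) {
  if (is.character(config)) {
    if (!file.exists(config))
      stop("configuration file not found: ", config, call. = FALSE)
    config <- yaml::read_yaml(config)
  }
  cfg <- .merge_config(.pipeline_defaults(), config)

  # fail-fast validation before any artifact is written
  if (!is.null(cfg$lexicon) && !file.exists(cfg$lexicon))
    stop("lexicon file not found: ", cfg$lexicon, call. = FALSE)
  if (cfg$topics$k < 2L) stop("topics.k must be >= 2", call. = FALSE)
  rates <- unlist(cfg$prevalence$rates)
  check_prob(rates, "prevalence.rates")

  if (dir.exists(outdir) && length(dir(outdir)) && !overwrite)
    stop("output directory exists and is not empty: ", outdir,
         call. = FALSE)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  outfile <- function(name) file.path(outdir, name)
  artifacts <- character()
  put <- function(df, name) {
    write.csv(df, outfile(name), row.names = FALSE)
    artifacts <<- c(artifacts, name)
  }

  seed <- as.integer(cfg$seed)
  gen <- generatorConfig(nUsers = as.integer(cfg$generator$n_users),
                         nMessages = as.integer(cfg$generator$n_messages),
                         seed = seed)

  message("* simulating corpus, gazetteer, claims")
  corpus <- simulateCorpus(gen)
  gazetteer <- simulateGazetteer(gen)
  boundaries <- simulateBoundaries(gen)
  claims <- simulateClaims(gen, uniformPrevalenceTruth(gen, rates))
  writeCorpus(corpus, outfile("corpus.jsonl"), outfile("truth.jsonl"))
  artifacts <- c(artifacts, "corpus.jsonl", "truth.jsonl")
  put(gazetteer, "gazetteer.csv")
  put(claims, "claims.csv")

  lexicon <- if (is.null(cfg$lexicon))
    gen@keywords[c("disease", "keyword")] else readLexicon(cfg$lexicon)

  message("* filtering against keyword lexicon")
  matches <- filterCorpus(corpus, lexicon)
  put(keywordCounts(matches), "keyword_counts.csv")
  put(diseaseCounts(matches), "disease_counts.csv")
  put(matchTable(matches), "matches.csv")

  message("* resolving counties")
  assignments <- resolveLocations(corpus, gazetteer, boundaries)
  put(assignments, "county_assignments.csv")

  message("* estimating correction factors")
  corr <- correctionTable(matches, corpus,
                          sampleSize = as.integer(cfg$correction$sample_size),
                          seed = seed + 1000L)
  put(corr$factors, "correction_factors.csv")
  put(corr$table, "corrected_counts.csv")

  message("* fitting topics (K = ", cfg$topics$k, ")")
  vocab <- buildVocabulary(corpus, lexicon,
                           minAuthorFrac = cfg$topics$min_author_frac)
  put(vocab, "vocabulary.csv")
  K <- as.integer(cfg$topics$k)
  alpha <- if (is.null(cfg$topics$alpha)) 50 / K else cfg$topics$alpha
  model <- fitLda(corpus, vocab, K = K, alpha = alpha,
                  beta = cfg$topics$beta,
                  nIter = as.integer(cfg$topics$iterations),
                  burnIn = as.integer(cfg$topics$burn_in),
                  seed = seed + 2000L)
  phiOut <- data.frame(topic = seq_len(K), topicWordDist(model),
                       check.names = FALSE)
  put(phiOut, "topic_word.csv")

  loads <- messageTopicLoads(corpus, model)
  labels <- diseaseLabelMatrix(matches, messageIds = rownames(loads))
  correlations <- topicDiseaseCorrelations(loads, labels)
  put(correlations, "topic_correlations.csv")

  message("* clustering topics into themes (T = ", cfg$themes$t, ")")
  themeLabels <- if (!is.null(cfg$themes$labels))
    as.character(cfg$themes$labels) else NULL
  themes <- fitThemes(model, T = as.integer(cfg$themes$t),
                      themeLabels = themeLabels, seed = seed + 3000L)
  put(data.frame(topic = seq_len(K), themes@W, check.names = FALSE),
      "theme_topic_weights.csv")
  put(data.frame(theme = themeNames(themes), themes@H,
                 check.names = FALSE), "theme_word.csv")
  tl <- messageThemeLoads(corpus, themes)
  stats <- themeGivenDisease(tl$assigned, labels,
                             themeLevels = themeNames(themes))
  stats <- pmiDiseaseTheme(stats)
  put(stats, "theme_stats.csv")

  message("* computing prevalence")
  prev <- countyPrevalence(claims, setNames(gen@counties$population,
                                            gen@counties$county))
  put(countyTable(prev), "prevalence_county.csv")
  put(stateTable(prev), "prevalence_state.csv")

  message("* volume-versus-prevalence report")
  shares <- volumeShareTable(corr$table, prev)
  put(shares, "volume_share.csv")

  manifest <- list(
    package = "infodemics",
    version = as.character(utils::packageVersion("infodemics")),
    seed = seed,
    config = cfg,
    sizes = list(messages = nrow(messages(corpus)),
                 matched = length(matchedIds(matches)),
                 claims = nrow(claims),
                 vocabulary = sum(vocab$retained),
                 topics = K, themes = as.integer(cfg$themes$t)),
    checksums = as.list(tools::md5sum(
      file.path(outdir, sort(artifacts))))
  )
  names(manifest$checksums) <- sort(artifacts)
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, pretty = TRUE,
                              digits = NA),
             outfile("manifest.json"))
  invisible(manifest)
}
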