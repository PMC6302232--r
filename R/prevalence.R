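# Claims-based prevalence. Disease coding is a pluggable lookup: claims
# arrive already labeled with a disease name (a toy code table can be
# applied upstream by the caller); the statistics below only count
# unique patients.

#' County-level claims prevalence
#'
#' Unique patients per (county, disease) — a patient with many claims
#' for one disease counts once — divided by county population. Every
#' configured county appears for every disease seen in the claims, with
#' zero patients where no claim exists. Two state summaries are
#' computed at the same time: the unweighted mean of county prevalences
#' and the pooled share (statewide unique patients over statewide
#' population).
#'
#' @param claims data.frame `patient_id`, `county`, `disease`.
#' @param populations named numeric (county -> population) or
#'   data.frame with columns `county`, `population`.
#' @return a [PrevalenceTable-class].
#' @export
countyPrevalence <- function(claims, populations) {
  if (is.data.frame(populations))
    populations <- setNames(populations$population, populations$county)
  unknown <- setdiff(unique(claims$county), names(populations))
  if (length(unknown))
    stop("claims reference counties without a population: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  diseases <- sort(unique(claims$disease))
  counties <- names(populations)
  uniq <- unique(claims[c("patient_id", "disease", "county")])
  grid <- expand.grid(county = counties, disease = diseases,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  key <- paste(uniq$county, uniq$disease, sep = "\r")
  tab <- table(key)
  grid$patients <- as.integer(tab[paste(grid$county, grid$disease,
                                        sep = "\r")])
  grid$patients[is.na(grid$patients)] <- 0L
  grid$population <- as.numeric(populations[grid$county])
  grid$prevalence <- grid$patients / grid$population

  statePop <- sum(populations)
  stateRows <- lapply(diseases, function(d) {
    sub <- grid[grid$disease == d, , drop = FALSE]
    pooled <- length(unique(uniq$patient_id[uniq$disease == d]))
    data.frame(disease = d,
               meanCountyPrevalence = mean(sub$prevalence),
               pooledPatients = pooled,
               statePopulation = statePop,
               pooledShare = pooled / statePop,
               stringsAsFactors = FALSE)
  })
  new("PrevalenceTable", county = grid,
      state = do.call(rbind, stateRows))
}

#' State-level prevalence summaries
#'
#' Returns the per-disease state summary of a [PrevalenceTable-class]:
#' the unweighted arithmetic mean of county prevalences (the defined
#' state prevalence) together with the pooled share (statewide unique
#' patients over statewide population), since headline percentages are
#' conventionally quoted against the statewide denominator. The two
#' agree exactly when all county populations are equal.
#'
#' @param table a [PrevalenceTable-class].
#' @return data.frame `disease`, `meanCountyPrevalence`,
#'   `pooledPatients`, `statePopulation`, `pooledShare`.
#' @export
statePrevalence <- function(table) {
  stopifnot(is(table, "PrevalenceTable"))
  stateTable(table)
}
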