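# County assignment: coordinates first (point-in-polygon against
# boundary fixtures), then the free-text profile location under the
# population-concentration rule.

# Ray-casting point-in-polygon; poly is a matrix with columns lon, lat.
# Points on an edge count as inside (adequate for coarse fixtures).
.point_in_poly <- function(px, py, poly) {
  n <- nrow(poly)
  if (poly[1, 1] == poly[n, 1] && poly[1, 2] == poly[n, 2]) n <- n - 1L
  inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    if ((yi > py) != (yj > py)) {
      xcross <- xi + (py - yi) / (yj - yi) * (xj - xi)
      if (px < xcross) inside <- !inside
      else if (px == xcross) return(TRUE)
    }
    j <- i
  }
  inside
}

#' Map coordinates to a county
#'
#' Point-in-polygon lookup against boundary fixtures (named list of
#' polygons with `lon`, `lat` columns, e.g. from
#' [simulateBoundaries()]). Points outside every polygon are unmapped.
#'
#' @param lat,lon numeric vectors of decimal degrees (finite).
#' @param boundaries named list of polygon matrices.
#' @return character vector of county names, `NA` where unmapped.
#' @export
countyFromCoordinates <- function(lat, lon, boundaries) {
  if (any(!is.finite(lat)) || any(!is.finite(lon)))
    stop("coordinates must be finite", call. = FALSE)
  if (length(lat) != length(lon))
    stop("latitude and longitude lengths differ", call. = FALSE)
  vapply(seq_along(lat), function(i) {
    for (cty in names(boundaries)) {
      if (.point_in_poly(lon[i], lat[i], boundaries[[cty]])) return(cty)
    }
    NA_character_
  }, character(1))
}

.norm_place <- function(x) {
  x <- stringi::stri_trans_nfkc(x)
  x <- stringi::stri_trans_tolower(x)
  x <- stringi::stri_replace_all_regex(x, "[^a-z0-9,\\s]", " ")
  trimws(stringi::stri_replace_all_regex(x, "\\s+", " "))
}

.norm_state <- function(x) {
  x <- trimws(tolower(x))
  full <- tolower(datasets::state.name)
  hit <- match(x, full)
  out <- ifelse(is.na(hit), toupper(x), datasets::state.abb[hit])
  out
}

# Concentration rule shared by the bare-city and bare-county paths:
# map iff the most populous candidate holds >= `threshold` of the total
# population over all same-named candidates.
.concentrated <- function(candidates, popCol, threshold) {
  tot <- sum(candidates[[popCol]])
  if (tot <= 0) return(NA_integer_)
  best <- which.max(candidates[[popCol]])
  if (candidates[[popCol]][best] / tot >= threshold) best else NA_integer_
}

# Returns list(county =, rule = "city_rule"/"county_rule"/NA)
.locate_field <- function(location, gazetteer, exclusionWords,
                          threshold = 0.9) {
  unmapped <- list(county = NA_character_, rule = NA_character_)
  if (is.na(location) || !nzchar(trimws(location))) return(unmapped)
  loc <- .norm_place(location)
  if (!nzchar(loc)) return(unmapped)
  gplace <- .norm_place(gazetteer$place)

  if (grepl(",", loc, fixed = TRUE)) {
    parts <- trimws(strsplit(loc, ",", fixed = TRUE)[[1]])
    if (length(parts) >= 2 && nzchar(parts[1]) && nzchar(parts[2])) {
      st <- .norm_state(parts[2])
      hit <- which(gplace == parts[1] & toupper(gazetteer$state) == st)
      if (length(hit) == 1L)
        return(list(county = gazetteer$county[hit], rule = "city_rule"))
      if (length(hit) > 1L) {
        best <- hit[which.max(gazetteer$population[hit])]
        return(list(county = gazetteer$county[best], rule = "city_rule"))
      }
    }
    return(unmapped)
  }

  # bare city name: concentration rule + common-word exclusion
  if (!(loc %in% exclusionWords)) {
    cand <- gazetteer[gplace == loc, , drop = FALSE]
    if (nrow(cand)) {
      best <- .concentrated(cand, "population", threshold)
      if (!is.na(best))
        return(list(county = cand$county[best], rule = "city_rule"))
      return(unmapped)
    }
  } else {
    return(unmapped)
  }

  # bare county name (optionally suffixed "... county"); county
  # population approximated by the sum of its gazetteer places
  cname <- sub(" county$", "", loc)
  if (cname %in% exclusionWords) return(unmapped)
  byCounty <- stats::aggregate(population ~ county, gazetteer, sum)
  cand <- byCounty[.norm_place(byCounty$county) == cname, , drop = FALSE]
  if (nrow(cand)) {
    best <- .concentrated(cand, "population", threshold)
    if (!is.na(best))
      return(list(county = cand$county[best], rule = "county_rule"))
  }
  unmapped
}

#' Map a free-text location field to a county
#'
#' Applies, in order: explicit "city, state" lookup; the bare-city
#' population-concentration rule (mapped iff one place holds at least
#' `threshold` of the total population across all same-named places and
#' the name is not a common word on the exclusion list); and the same
#' rule for bare county names.
#'
#' @param location character vector of raw location strings.
#' @param gazetteer data.frame `place`, `state`, `county`, `population`.
#' @param exclusionWords lowercase common words never treated as places
#'   (default [defaultExclusionWords()]).
#' @param threshold population concentration needed to map a bare name
#'   (default 0.9, i.e. "at least 90%").
#' @return character vector of counties, `NA` where unmapped.
#' @export
#' @examples
#' gaz <- data.frame(place = c("Chicago", "Chicago"),
#'                   state = c("IL", "WI"),
#'                   county = c("Cook", "Door"),
#'                   population = c(2700000, 1000))
#' countyFromLocationField("Chicago", gaz, exclusionWords = character())
countyFromLocationField <- function(location, gazetteer,
                                    exclusionWords = defaultExclusionWords(),
                                    threshold = 0.9) {
  vapply(location, function(l)
    .locate_field(l, gazetteer, exclusionWords, threshold)$county,
    character(1), USE.NAMES = FALSE)
}

#' Assign every corpus message to a county
#'
#' Coordinates take priority over the location field; messages with
#' neither, or whose information resolves nowhere, are unmapped. The
#' assignment is a pure function of (message, gazetteer, boundaries).
#'
#' @param corpus a [MessageCorpus-class].
#' @param gazetteer data.frame `place`, `state`, `county`, `population`.
#' @param boundaries named list of county polygons.
#' @param exclusionWords see [countyFromLocationField()].
#' @param threshold concentration threshold for bare names.
#' @return data.frame `message_id`, `county` (`NA` when unmapped),
#'   `method` (one of `coordinates`, `city_rule`, `county_rule`,
#'   `unmapped`).
#' @export
resolveLocations <- function(corpus, gazetteer, boundaries,
                             exclusionWords = defaultExclusionWords(),
                             threshold = 0.9) {
  stopifnot(is(corpus, "MessageCorpus"))
  msgs <- messages(corpus)
  n <- nrow(msgs)
  county <- rep(NA_character_, n)
  method <- rep("unmapped", n)
  hasCoord <- !is.na(msgs$latitude) & !is.na(msgs$longitude)
  if (any(hasCoord)) {
    res <- countyFromCoordinates(msgs$latitude[hasCoord],
                                 msgs$longitude[hasCoord], boundaries)
    county[hasCoord] <- res
    method[hasCoord] <- ifelse(is.na(res), "unmapped", "coordinates")
  }
  needField <- !hasCoord & !is.na(msgs$location_field)
  for (i in which(needField)) {
    r <- .locate_field(msgs$location_field[i], gazetteer, exclusionWords,
                       threshold)
    if (!is.na(r$county)) {
      county[i] <- r$county
      method[i] <- r$rule
    }
  }
  data.frame(message_id = msgs$message_id, county = county,
             method = method, stringsAsFactors = FALSE)
}
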