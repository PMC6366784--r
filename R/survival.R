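# Likelihood of survival-establishment: standardized habitat suitability at
# the arrival port multiplied by a discharge-season score, averaged per
# port, year, pathway and species.

#' Season-of-discharge score
#'
#' Temperate species (those most likely to be transported) reproduce and
#' recruit in the warmer seasons, so propagules released in warm water are
#' more likely to survive. Northern-hemisphere calendar seasons by month:
#' winter (Dec-Feb) scores 1, spring (Mar-May) and autumn (Sep-Nov) score 2,
#' summer (Jun-Aug) scores 3.
#'
#' @param date `Date` vector.
#' @return integer scores in `{1, 2, 3}`.
#' @export
season_score <- function(date) {
  m <- as.integer(format(as.Date(date), "%m"))
  ifelse(m %in% c(12L, 1L, 2L), 1L, ifelse(m %in% 6:8, 3L, 2L))
}

#' Likelihood of survival-establishment for one discharge event
#'
#' The product of standardized habitat suitability at the arrival port and
#' the season-of-discharge score.
#'
#' @param suitability_std standardized suitability in \[0, 1\].
#' @param season integer season score in `{1, 2, 3}`.
#' @return value in \[0, 3\] (vectorized).
#' @export
survival_likelihood <- function(suitability_std, season) {
  if (any(suitability_std < 0 | suitability_std > 1, na.rm = TRUE))
    stop("standardized suitability must lie in [0, 1]", call. = FALSE)
  if (!all(season %in% 1:3))
    stop("season score must be in {1, 2, 3}", call. = FALSE)
  suitability_std * season
}

#' Per-event and aggregated survival-establishment scores
#'
#' Looks up each species' standardized suitability at every arrival port,
#' scores the discharge season of every vessel arrival, and averages the
#' per-event products per (port, year, pathway, species).
#'
#' @param records completed `ballast_records`.
#' @param ports a `port_table` holding the arrival ports' coordinates.
#' @param surfaces list of standardized `suitability_surface` objects (see
#'   [standardize_suitability()]), one per assessed species.
#' @param radius_km nearest-valid-cell search radius for port lookups
#'   (default 50 km).
#' @return list with `events` (one row per vessel arrival x species:
#'   `species`, `port`, `year`, `pathway`, `discharge_date`,
#'   `suitability_std`, `season_score`, `value`) and `by_key` (mean `value`
#'   per port, year, pathway, species).
#' @export
survival_scores <- function(records, ports, surfaces, radius_km = 50) {
  v <- vessel_table(records)
  port_ids <- unique(v$arrival_port)
  idx <- match(port_ids, ports$port_id)
  if (anyNA(idx))
    stop("lookup error: arrival port(s) not in port table: ",
         paste(port_ids[is.na(idx)], collapse = ", "), call. = FALSE)
  events <- do.call(rbind, lapply(surfaces, function(surf) {
    suit <- vapply(seq_along(port_ids), function(j)
      suitability_at(surf, ports$lon[idx[j]], ports$lat[idx[j]],
                     radius_km = radius_km, label = port_ids[j]),
      numeric(1))
    names(suit) <- port_ids
    data.frame(species = surf$species_id, port = v$arrival_port,
               year = v$arrival_year, pathway = v$pathway,
               discharge_date = v$discharge_date,
               suitability_std = unname(suit[v$arrival_port]),
               season_score = season_score(v$discharge_date),
               stringsAsFactors = FALSE)
  }))
  rownames(events) <- NULL
  events$value <- survival_likelihood(events$suitability_std,
                                      events$season_score)
  by_key <- agg_by(events, "value", c("port", "year", "pathway", "species"),
                   mean)
  list(events = events, by_key = by_key)
}
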