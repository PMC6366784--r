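# Likelihood of arrival: exchange-corrected discharged volume weighted by a
# transit-time score, restricted to ballast sources inside the assessed
# species' presence range, normalized so the highest value in the run is 1.

#' Ballast-water-exchange correction factor
#'
#' Exchange removes most of the originally entrained organisms; reported
#' efficacy is about 90% for saline/brackish sources and 99% for freshwater
#' sources. The discharged volume is therefore multiplied by 0.1 (marine or
#' brackish source) or 0.01 (freshwater source) when exchange was performed,
#' and left uncorrected otherwise.
#'
#' @param exchange_performed logical.
#' @param source_class salinity class of the pre-exchange source:
#'   `"fresh"`, `"brackish"` or `"marine"` (see [classify_salinity()]).
#'   `NA` is treated as marine (the weaker, conservative correction).
#' @return factor in `{1, 0.1, 0.01}` (vectorized).
#' @export
bwe_correction_factor <- function(exchange_performed, source_class) {
  n <- max(length(exchange_performed), length(source_class))
  exchange_performed <- rep_len(exchange_performed, n)
  source_class <- rep_len(source_class, n)
  bad <- !is.na(source_class) & !(source_class %in% c("fresh", "brackish", "marine"))
  if (any(bad))
    stop("invalid salinity class: ", paste(unique(source_class[bad]), collapse = ", "),
         call. = FALSE)
  ifelse(!exchange_performed, 1,
         ifelse(!is.na(source_class) & source_class == "fresh", 0.01, 0.1))
}

#' Transit time in whole days
#'
#' Days between ballast uptake at the source port and discharge at the
#' arrival port (ballast water age).
#'
#' @param uptake,discharge `Date` vectors.
#' @return integer day counts, `>= 0`.
#' @export
transit_days <- function(uptake, discharge) {
  d <- as.integer(as.Date(discharge) - as.Date(uptake))
  if (any(d < 0, na.rm = TRUE))
    stop("chronology error: uptake date after discharge date", call. = FALSE)
  d
}

#' Transit-time score for a species
#'
#' Shorter transits leave more viable propagules. Scores 1 (low) to 3 (high):
#' high when the transit is shorter than the species' average larval-stage
#' duration (midpoint of the typical range), moderate between the average and
#' the maximum larval duration, and low when the transit outlasts the maximum
#' known larval stage.
#'
#' @param days transit time in whole days (vectorized).
#' @param species a `species_profile`.
#' @return integer scores in `{1, 2, 3}`.
#' @export
transit_score <- function(days, species) {
  avg <- avg_larval_days(species)
  ifelse(days < avg, 3L, ifelse(days <= species$larval_max_days, 2L, 1L))
}

#' Is a ballast source inside a species' presence range?
#'
#' A source counts only if the species is known to be present there (native
#' or non-native range): either the port id is in the species' presence set,
#' or the port's coordinates fall inside one of its presence polygons.
#'
#' @param port_id source port identifier (vectorized).
#' @param species a `species_profile`.
#' @param ports a `port_table` used to resolve coordinates for the polygon
#'   test.
#' @return logical vector.
#' @export
port_in_range <- function(port_id, species, ports) {
  out <- port_id %in% species$presence_ports
  todo <- which(!out & !is.na(port_id))
  if (length(todo) && length(species$presence_polygons)) {
    idx <- match(port_id[todo], ports$port_id)
    if (anyNA(idx))
      stop("lookup error: unknown port id(s): ",
           paste(unique(port_id[todo][is.na(idx)]), collapse = ", "),
           call. = FALSE)
    pts <- cbind(ports$lon[idx], ports$lat[idx])
    inside <- rep(FALSE, length(todo))
    for (poly in species$presence_polygons)
      inside <- inside | mgcv::in.out(poly, pts)
    out[todo] <- inside
  }
  out
}

#' @rdname port_in_range
#' @param contribution one tank row of a completed `ballast_records` object
#'   (a data frame row with a `source_port` column).
#' @export
source_in_range <- function(contribution, species, ports) {
  port_in_range(contribution$source_port, species, ports)
}

# Per-tank in-range corrected volume for one species. The exchange correction
# splits a coastal-exchanged tank between its pre-exchange source (weight =
# correction factor) and the exchange location (weight = 1 - factor), since
# coastal exchange replaces most of the tank with water taken up at the
# exchange site; mid-ocean exchange locations are open ocean and earn no
# presence credit.
tank_in_range_volume <- function(tanks, species, ports) {
  performed <- tanks$exchange_type != "none"
  f <- bwe_correction_factor(performed, classify_salinity(tanks$source_salinity_ppt))
  src_in <- port_in_range(tanks$source_port, species, ports)
  vol <- tanks$tank_volume_mt * f * src_in
  coastal <- performed & tanks$exchange_type == "coastal" &
    !is.na(tanks$exchange_location)
  if (any(coastal)) {
    ex_in <- port_in_range(tanks$exchange_location[coastal], species, ports)
    vol[coastal] <- vol[coastal] +
      tanks$tank_volume_mt[coastal] * (1 - f[coastal]) * ex_in
  }
  vol
}

# Corrected (exchange-discounted) discharge volume per tank row, with no
# species filter; used by the shipping summaries.
corrected_volume <- function(records) {
  has_tank <- !is.na(records$tank_id)
  out <- numeric(nrow(records))
  if (!any(has_tank)) return(out)
  tanks <- records[has_tank, , drop = FALSE]
  performed <- tanks$exchange_type != "none"
  if (anyNA(performed))
    stop("exchange type unknown; run complete_records() first", call. = FALSE)
  f <- bwe_correction_factor(performed,
                             classify_salinity(tanks$source_salinity_ppt))
  out[has_tank] <- tanks$tank_volume_mt * f
  out
}

#' Raw likelihood of arrival for one vessel arrival
#'
#' Sum over the vessel's tank contributions whose source lies inside the
#' species' presence range of (discharged volume x exchange correction
#' factor) x transit-time score. Zero when no contribution passes the
#' presence filter.
#'
#' @param record the tank rows of one vessel arrival (completed
#'   `ballast_records` subset).
#' @param species a `species_profile`.
#' @param ports a `port_table`.
#' @return nonnegative scalar (metric-ton-weighted score).
#' @export
arrival_raw <- function(record, species, ports) {
  tanks <- record[!is.na(record$tank_id), , drop = FALSE]
  if (nrow(tanks) == 0L) return(0)
  vol <- tank_in_range_volume(tanks, species, ports)
  score <- transit_score(transit_days(tanks$uptake_date, tanks$discharge_date),
                         species)
  sum(vol * score)
}

#' Normalize a set of nonnegative values by its maximum
#'
#' Scales so the highest value is exactly 1; an all-zero (or empty) set maps
#' to itself.
#'
#' @param values numeric vector, `>= 0`.
#' @return vector of the same length in \[0, 1\].
#' @export
normalize_max <- function(values) {
  if (length(values) == 0L) return(values)
  m <- max(values, na.rm = TRUE)
  if (!is.finite(m) || m <= 0) return(values * 0)
  values / m
}

#' Per-vessel arrival scores for a species set
#'
#' Computes the raw likelihood of arrival for every vessel arrival and
#' species, and a single normalization pass over all per-vessel raw values in
#' the run (across species, ports, years and pathways) so the highest scoring
#' vessel-species combination is 1.
#'
#' @param records completed `ballast_records`.
#' @param species list of `species_profile` objects.
#' @param ports a `port_table`.
#' @return data frame with one row per vessel arrival x species: `vessel_id`,
#'   `species`, `port`, `year`, `pathway`, `corrected_volume_mt` (in-range,
#'   exchange-corrected), `transit_days` (shortest contributing), then
#'   `transit_score` (highest contributing), `raw` and `normalized`.
#' @export
arrival_scores <- function(records, species, ports) {
  v <- vessel_table(records)
  key_rec <- paste(records$vessel_id, records$arrival_port,
                   records$discharge_date, records$pathway, sep = "\r")
  key_v <- paste(v$vessel_id, v$arrival_port, v$discharge_date, v$pathway,
                 sep = "\r")
  idx <- split(seq_len(nrow(records)), key_rec)
  out <- do.call(rbind, lapply(species, function(sp) {
    res <- data.frame(vessel_id = v$vessel_id, species = sp$species_id,
                      port = v$arrival_port, year = v$arrival_year,
                      pathway = v$pathway, corrected_volume_mt = 0,
                      transit_days = NA_integer_, transit_score = NA_integer_,
                      raw = 0, stringsAsFactors = FALSE)
    for (i in seq_len(nrow(v))) {
      rows <- idx[[key_v[i]]]
      tanks <- records[rows, , drop = FALSE]
      tanks <- tanks[!is.na(tanks$tank_id), , drop = FALSE]
      if (nrow(tanks) == 0L) next
      vol <- tank_in_range_volume(tanks, sp, ports)
      td <- transit_days(tanks$uptake_date, tanks$discharge_date)
      sc <- transit_score(td, sp)
      res$corrected_volume_mt[i] <- sum(vol)
      res$transit_days[i] <- min(td)
      res$transit_score[i] <- max(sc)
      res$raw[i] <- sum(vol * sc)
    }
    res
  }))
  rownames(out) <- NULL
  out$normalized <- normalize_max(out$raw)
  out
}

#' Aggregate per-vessel arrival values per port, year, pathway and species
#'
#' @param scores data frame from [arrival_scores()] (or any table with the
#'   key columns and a value column).
#' @param mode `"mean_per_vessel"` (mean of per-vessel values within each
#'   key) or `"cumulative_annual"` (sum within each key, reflecting total
#'   volumes discharged at a port over a year).
#' @param value_col column to aggregate (default `"normalized"` for the
#'   per-vessel mode; use `"raw"` for the cumulative mode, which is
#'   normalized after summing).
#' @return data frame keyed by `port`, `year`, `pathway`, `species` with the
#'   aggregated `value`.
#' @export
aggregate_arrival <- function(scores, mode = c("mean_per_vessel",
                                               "cumulative_annual"),
                              value_col = NULL) {
  mode <- match.arg(mode)
  if (is.null(value_col))
    value_col <- if (mode == "mean_per_vessel") "normalized" else "raw"
  fun <- if (mode == "mean_per_vessel") mean else sum
  agg_by(scores, value_col, c("port", "year", "pathway", "species"), fun)
}
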