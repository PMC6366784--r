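# Consequence of occurrence: four-category impact rubric summed per species,
# multiplied by the receiving port's habitat-sensitivity score, min-max
# normalized across all species and ports in the run.

#' Total impact score of a species
#'
#' Sum of the four consequence-rubric categories (changes in biodiversity,
#' interspecific interactions, habitat, trophic interactions), each ranked
#' low to high (1 to 3).
#'
#' @param species a `species_profile`.
#' @return integer in \[4, 12\].
#' @export
impact_total <- function(species) {
  scores <- c(species$impact_biodiversity, species$impact_interactions,
              species$impact_habitat, species$impact_trophic)
  if (!all(scores %in% 1:3))
    stop("impact scores must be integers in {1, 2, 3}", call. = FALSE)
  sum(scores)
}

#' Habitat-sensitivity score of a port
#'
#' Counts the sensitivity variables the port overlaps (ecologically and
#' biologically significant areas, overlapping species, high biological
#' importance, hot spots): one variable (or none) is low sensitivity (1),
#' two to three moderate (2), all four high (3).
#'
#' @param port one row of a `port_table` (or any list with the four logical
#'   overlap columns).
#' @return integer score in `{1, 2, 3}` (vectorized over port rows).
#' @export
sensitivity_score <- function(port) {
  n <- as.integer(port$ebsa) + as.integer(port$overlapping_species) +
    as.integer(port$biological_importance) + as.integer(port$hotspot)
  ifelse(n >= 4L, 3L, ifelse(n >= 2L, 2L, 1L))
}

# Min-max rescaling to [0, 1]; a constant set maps to all 1 when nonzero
# (every observation is at the shared maximum) and all 0 when zero.
minmax_norm <- function(x) {
  if (length(x) == 0L) return(x)
  lo <- min(x); hi <- max(x)
  if (hi == lo) {
    if (hi == 0) return(x * 0)
    return(rep(1, length(x)))
  }
  (x - lo) / (hi - lo)
}

#' Consequence-of-occurrence scores
#'
#' For every species x port pair: raw consequence = total impact score x
#' habitat-sensitivity score, then min-max normalized over all pairs in the
#' run so species and ports share a single 0-1 scale.
#'
#' @param species list of `species_profile` objects.
#' @param ports a `port_table` (only ports of interest, e.g. arrival ports).
#' @return data frame with `species`, `port`, `impact_total`,
#'   `sensitivity_score`, `raw` and `normalized`.
#' @export
consequence_scores <- function(species, ports) {
  if (length(species) == 0L || nrow(ports) == 0L)
    stop("need at least one species and one port", call. = FALSE)
  sens <- sensitivity_score(ports)
  out <- do.call(rbind, lapply(species, function(sp)
    data.frame(species = sp$species_id, port = ports$port_id,
               impact_total = impact_total(sp), sensitivity_score = sens,
               raw = impact_total(sp) * sens, stringsAsFactors = FALSE)))
  rownames(out) <- NULL
  out$normalized <- minmax_norm(out$raw)
  out
}
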