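# Risk synthesis: establishment = arrival x survival-establishment (min-max
# normalized across the run), overall risk = establishment x consequence,
# gradient risk-matrix classification, and ordinal uncertainty propagation.

#' Establishment likelihood per port, year, pathway and species
#'
#' Per-key product of the aggregated likelihood of arrival and likelihood of
#' survival-establishment, then min-max normalized over all keys and species
#' in the run (so species remain comparable on one 0-1 scale).
#'
#' @param arrival keyed table (`port`, `year`, `pathway`, `species`,
#'   `value`) of aggregated arrival likelihoods.
#' @param survival keyed table of aggregated survival-establishment values
#'   with the same keys.
#' @return keyed table with `product` (pre-normalization) and `value`
#'   (normalized establishment).
#' @export
establishment <- function(arrival, survival) {
  keys <- c("port", "year", "pathway", "species")
  ka <- do.call(paste, c(arrival[keys], sep = "\r"))
  ks <- do.call(paste, c(survival[keys], sep = "\r"))
  j <- match(ka, ks)
  if (anyNA(j) || length(ka) != length(ks))
    stop("alignment error: arrival and survival tables have mismatched keys",
         call. = FALSE)
  out <- arrival[keys]
  out$product <- arrival$value * survival$value[j]
  out$value <- minmax_norm(out$product)
  out
}

#' Overall risk
#'
#' Product of (normalized) establishment and consequence of occurrence.
#'
#' @param establishment,consequence values in \[0, 1\] (vectorized).
#' @return values in \[0, 1\].
#' @export
overall_risk <- function(establishment, consequence) {
  if (any(establishment < 0 | establishment > 1 |
            consequence < 0 | consequence > 1, na.rm = TRUE))
    stop("establishment and consequence must lie in [0, 1]", call. = FALSE)
  establishment * consequence
}

#' Classify a likelihood-consequence pair on the gradient risk matrix
#'
#' The risk matrix is continuous (a gradient), but low/moderate/high bands
#' are reported using product thresholds at 1/9 and 4/9: the corners of a
#' 3x3 likelihood-consequence grid with axis cuts at 1/3 and 2/3.
#'
#' @param establishment,consequence values in \[0, 1\] (vectorized).
#' @param thresholds length-2 increasing vector of product cuts
#'   (default `c(1/9, 4/9)`).
#' @return character vector in `c("low", "moderate", "high")`.
#' @export
categorize <- function(establishment, consequence, thresholds = c(1/9, 4/9)) {
  stopifnot(length(thresholds) == 2L, thresholds[1] < thresholds[2])
  p <- overall_risk(establishment, consequence)
  ifelse(p >= thresholds[2], "high",
         ifelse(p >= thresholds[1], "moderate", "low"))
}

#' Uncertainty grades for the four assessment components
#'
#' @param arrival,survival,impact,sensitivity qualitative grades
#'   (`"low"`, `"moderate"`, `"high"`) for the likelihood-of-arrival data,
#'   the habitat-suitability modelling, the impact scoring and the
#'   habitat-sensitivity scoring. Defaults reflect a typical assessment:
#'   shipping records need completion assumptions (moderate), the other
#'   three components rest on substantial published information (low).
#' @return object of class `uncertainty_ledger`.
#' @export
uncertainty_ledger <- function(arrival = "moderate", survival = "low",
                               impact = "low", sensitivity = "low") {
  structure(list(arrival = as.character(as_level3(arrival, "arrival")),
                 survival = as.character(as_level3(survival, "survival")),
                 impact = as.character(as_level3(impact, "impact")),
                 sensitivity = as.character(as_level3(sensitivity, "sensitivity"))),
            class = "uncertainty_ledger")
}

#' Join qualitative uncertainty levels
#'
#' The overall grade is the highest grade among the inputs (the join on the
#' ordinal lattice low < moderate < high); associative, commutative and
#' idempotent.
#'
#' @param ... character levels.
#' @return single character level.
#' @export
uncertainty_join <- function(...) {
  x <- as_level3(c(...), "uncertainty level")
  as.character(max(x))
}

#' Propagate component uncertainty to stage and overall grades
#'
#' Overall uncertainty equals the highest uncertainty attached to any
#' variable used in the analysis; stage grades are reported the same way for
#' the establishment components (arrival, survival) and the consequence
#' components (impact, sensitivity).
#'
#' @param ledger an `uncertainty_ledger`.
#' @return list with `establishment`, `consequence` and `overall` grades.
#' @export
combine_uncertainty <- function(ledger) {
  stopifnot(inherits(ledger, "uncertainty_ledger"))
  list(establishment = uncertainty_join(ledger$arrival, ledger$survival),
       consequence = uncertainty_join(ledger$impact, ledger$sensitivity),
       overall = uncertainty_join(ledger$arrival, ledger$survival,
                                  ledger$impact, ledger$sensitivity))
}

#' Risk-matrix dataset for one pathway and aggregation mode
#'
#' Extracts the cells for a pathway/mode as a plottable table (x =
#' establishment, y = consequence, label = port-year), sorted by overall
#' risk descending with ties broken by port then year.
#'
#' @param cells risk-cell table (see [assess_risk()]).
#' @param pathway `"domestic"` or `"international"`.
#' @param mode `"per_vessel"` or `"cumulative_annual"`.
#' @param species optional species id filter.
#' @return data frame with `label`, `establishment`, `consequence`,
#'   `overall`, `category` (empty, without error, if nothing matches).
#' @export
build_matrix <- function(cells, pathway, mode, species = NULL) {
  sel <- cells$pathway == pathway & cells$mode == mode
  if (!is.null(species)) sel <- sel & cells$species %in% species
  m <- cells[sel, , drop = FALSE]
  m <- m[order(-m$overall, m$port, m$year), , drop = FALSE]
  out <- data.frame(label = paste(m$port, m$year),
                    species = m$species, establishment = m$establishment,
                    consequence = m$consequence, overall = m$overall,
                    category = m$category, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Relative ecological risk assessment of ballast-water discharges
#'
#' End-to-end driver. For every assessed species it computes per-vessel
#' likelihood of arrival (exchange-corrected in-range volume x transit
#' score, one normalization pass over the whole run), likelihood of
#' survival-establishment (standardized habitat suitability at the arrival
#' port x season score), establishment (their per-key product, min-max
#' normalized across species), consequence of occurrence (impact rubric x
#' habitat sensitivity, min-max normalized across species and ports), and
#' overall risk (establishment x consequence) per port, year, pathway and
#' species, in two aggregation modes: mean per vessel and cumulative annual
#' (total volumes discharged at a port over a year, normalized after
#' summing).
#'
#' @param records a `ballast_records` object; completed automatically (see
#'   [complete_records()]) if any field is missing.
#' @param ports a `port_table` covering arrival ports (with overlap flags)
#'   and any source ports needed for polygon presence tests.
#' @param species list of `species_profile` objects.
#' @param surfaces list of `suitability_surface` objects named/identified by
#'   species; standardized internally across species.
#' @param voluntary_bwe vessel ids known to perform voluntary coastal
#'   exchange (used during record completion).
#' @param uncertainty an `uncertainty_ledger`.
#' @param thresholds risk-category product cuts, passed to [categorize()].
#' @param radius_km suitability lookup fallback radius (km).
#' @return object of class `risk_assessment`: a list with `cells` (the risk
#'   table: `port`, `year`, `species`, `pathway`, `mode`, `establishment`,
#'   `consequence`, `overall`, `category`, `uncertainty`), the intermediate
#'   `arrival`, `survival`, `consequence` tables, the completed `records`,
#'   and the propagated `uncertainty` grades.
#' @export
assess_risk <- function(records, ports, species, surfaces,
                        voluntary_bwe = character(0),
                        uncertainty = uncertainty_ledger(),
                        thresholds = c(1/9, 4/9), radius_km = 50) {
  stopifnot(inherits(records, "ballast_records"), inherits(ports, "port_table"))
  if (length(species) == 0L) stop("no species supplied", call. = FALSE)
  records <- complete_records(records, voluntary_bwe = voluntary_bwe)
  surfaces <- standardize_suitability(surfaces)

  arr <- arrival_scores(records, species, ports)
  surv <- survival_scores(records, ports, surfaces, radius_km = radius_km)
  cons <- consequence_scores(species,
                             ports[ports$port_id %in% records$arrival_port, ,
                                   drop = FALSE])

  modes <- c(per_vessel = "mean_per_vessel",
             cumulative_annual = "cumulative_annual")
  cells <- do.call(rbind, lapply(names(modes), function(mode_name) {
    agg <- aggregate_arrival(arr, modes[[mode_name]])
    if (modes[[mode_name]] == "cumulative_annual")
      agg$value <- normalize_max(agg$value)
    est <- establishment(agg, surv$by_key)
    j <- match(paste(est$species, est$port, sep = "\r"),
               paste(cons$species, cons$port, sep = "\r"))
    data.frame(port = est$port, year = est$year, species = est$species,
               pathway = est$pathway, mode = mode_name,
               establishment = est$value, consequence = cons$normalized[j],
               stringsAsFactors = FALSE)
  }))
  cells$overall <- overall_risk(cells$establishment, cells$consequence)
  cells$category <- categorize(cells$establishment, cells$consequence,
                               thresholds = thresholds)
  unc <- combine_uncertainty(uncertainty)
  cells$uncertainty <- unc$overall
  cells <- cells[order(cells$mode, cells$pathway, cells$species, cells$port,
                       cells$year), , drop = FALSE]
  rownames(cells) <- NULL

  structure(list(cells = cells, arrival = arr, survival = surv,
                 consequence = cons, records = records,
                 uncertainty = unc, ledger = uncertainty,
                 thresholds = thresholds,
                 suitability_global_max = attr(surfaces, "global_max")),
            class = "risk_assessment")
}

#' @export
print.risk_assessment <- function(x, ...) {
  cat("Relative ecological risk assessment (ballast water pathway)\n")
  cat(sprintf("  %d risk cells: %d ports, years %s-%s, %d species\n",
              nrow(x$cells), length(unique(x$cells$port)),
              min(x$cells$year), max(x$cells$year),
              length(unique(x$cells$species))))
  tab <- table(factor(x$cells$category, levels = .levels3), x$cells$mode)
  cat("  categories by mode:\n")
  print(tab)
  cat(sprintf("  overall uncertainty: %s\n", x$uncertainty$overall))
  invisible(x)
}

#' @export
summary.risk_assessment <- function(object, ...) {
  cells <- object$cells
  top <- do.call(rbind, lapply(split(cells, list(cells$mode, cells$pathway),
                                     drop = TRUE), function(g)
    g[which.max(g$overall), , drop = FALSE]))
  rownames(top) <- NULL
  out <- list(n_cells = nrow(cells), top_cells = top,
              category_table = table(factor(cells$category, levels = .levels3),
                                     cells$pathway, cells$mode),
              uncertainty = object$uncertainty)
  class(out) <- "summary.risk_assessment"
  out
}

#' @export
print.summary.risk_assessment <- function(x, ...) {
  cat(sprintf("Risk assessment summary (%d cells)\n", x$n_cells))
  cat("Highest-risk cell per pathway and mode:\n")
  print(x$top_cells[, c("port", "year", "species", "pathway", "mode",
                        "establishment", "consequence", "overall",
                        "category")], digits = 3)
  cat(sprintf("Uncertainty: establishment %s, consequence %s, overall %s\n",
              x$uncertainty$establishment, x$uncertainty$consequence,
              x$uncertainty$overall))
  invisible(x)
}

#' @export
as.data.frame.risk_assessment <- function(x, ...) x$cells

#' Plot a gradient risk matrix
#'
#' Establishment (x) against consequence of occurrence (y) on a continuous
#' low-to-high gradient background, with category bands at the configured
#' product thresholds and one labelled point per port-year.
#'
#' @param x a `risk_assessment`.
#' @param pathway,mode,species cell selection (see [build_matrix()]).
#' @param labels draw port-year labels (default `TRUE`).
#' @param ... passed to [graphics::points()].
#' @return the plotted matrix data, invisibly.
#' @export
plot.risk_assessment <- function(x, pathway = "domestic",
                                 mode = "cumulative_annual", species = NULL,
                                 labels = TRUE, ...) {
  m <- build_matrix(x$cells, pathway, mode, species)
  n <- 101
  g <- seq(0, 1, length.out = n)
  prod_grid <- outer(g, g)
  pal <- grDevices::colorRampPalette(c("#2ca02c", "#ffdf00", "#d62728"))(64)
  graphics::image(g, g, prod_grid, col = pal, useRaster = TRUE,
                  xlab = "Establishment (normalized)",
                  ylab = "Consequence of occurrence (normalized)",
                  main = sprintf("Overall risk: %s, %s", pathway, mode))
  for (th in x$thresholds)
    graphics::contour(g, g, prod_grid, levels = th, add = TRUE, lty = 2,
                      drawlabels = FALSE)
  if (nrow(m)) {
    graphics::points(m$establishment, m$consequence, pch = 21, bg = "white",
                     ...)
    if (labels)
      graphics::text(m$establishment, m$consequence, m$label, pos = 3,
                     cex = 0.6)
  }
  invisible(m)
}

#' Export assessment tables as CSV files
#'
#' Writes `arrival_scores.csv`, `survival_scores.csv`,
#' `consequence_scores.csv` and `risk_cells.csv` into a directory.
#'
#' @param x a `risk_assessment`.
#' @param dir output directory (created if needed).
#' @return the directory path, invisibly.
#' @export
export_results <- function(x, dir) {
  stopifnot(inherits(x, "risk_assessment"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(x$arrival, file.path(dir, "arrival_scores.csv"),
                   row.names = FALSE)
  utils::write.csv(x$survival$events, file.path(dir, "survival_scores.csv"),
                   row.names = FALSE)
  utils::write.csv(x$consequence, file.path(dir, "consequence_scores.csv"),
                   row.names = FALSE)
  utils::write.csv(x$cells, file.path(dir, "risk_cells.csv"),
                   row.names = FALSE)
  invisible(dir)
}
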