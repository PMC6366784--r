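# Shipping summaries: arrivals, dischargers, mean (+/- SD) corrected ballast
# water discharged per vessel, and annual/port totals, in the layout of the
# standard transit-summary table.

# One row per vessel arrival with its corrected (exchange-discounted)
# discharge volume; no species filter.
corrected_vessel_table <- function(records) {
  cv <- corrected_volume(records)
  key <- paste(records$vessel_id, records$arrival_port,
               records$discharge_date, records$pathway, sep = "\r")
  idx <- split(seq_len(nrow(records)), key)
  first <- vapply(idx, `[`, 1L, FUN.VALUE = integer(1))
  v <- as.data.frame(records)[first, c("vessel_id", "pathway", "arrival_port",
                                       "arrival_year")]
  v$corrected_mt <- vapply(idx, function(i) sum(cv[i]), numeric(1))
  rownames(v) <- NULL
  v
}

#' Port-year shipping summary
#'
#' Arrivals, dischargers and corrected-discharge statistics for every
#' (arrival port, year, pathway) present in the records. Mean and SD are
#' computed over discharging vessels only; the SD is the population SD
#' (n denominator). Port-years with arrivals but no discharge report zeros.
#'
#' @param records completed `ballast_records`.
#' @param port,year,pathway optional filters; with all three given the
#'   result is the single matching summary row.
#' @return data frame with `port`, `year`, `pathway`, `n_arrivals`,
#'   `n_dischargers`, `mean_discharge_mt`, `sd_discharge_mt`,
#'   `total_discharge_mt`. Values are unrounded; apply [round_half_up()]
#'   (one decimal) for tabular display.
#' @export
summarize_port_year <- function(records, port = NULL, year = NULL,
                                pathway = NULL) {
  v <- corrected_vessel_table(records)
  if (!is.null(port)) v <- v[v$arrival_port %in% port, , drop = FALSE]
  if (!is.null(year)) v <- v[v$arrival_year %in% year, , drop = FALSE]
  if (!is.null(pathway)) v <- v[v$pathway %in% pathway, , drop = FALSE]
  key <- interaction(v$arrival_port, v$arrival_year, v$pathway, drop = TRUE,
                     lex.order = TRUE)
  idx <- split(seq_len(nrow(v)), key)
  out <- do.call(rbind, lapply(idx, function(i) {
    disc <- v$corrected_mt[i][v$corrected_mt[i] > 0]
    data.frame(port = v$arrival_port[i[1]], year = v$arrival_year[i[1]],
               pathway = v$pathway[i[1]], n_arrivals = length(i),
               n_dischargers = length(disc),
               mean_discharge_mt = if (length(disc)) mean(disc) else 0,
               sd_discharge_mt = if (length(disc)) pop_sd(disc) else 0,
               total_discharge_mt = sum(disc), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out[order(out$pathway, out$port, out$year), , drop = FALSE]
}

#' Port-level summary across years
#'
#' Collapses one port's year rows: mean arrivals (and dischargers) per year,
#' pooled mean corrected discharge per discharging vessel (grand total
#' divided by total dischargers; zero when no vessel discharged), and the
#' grand total. The grand total is the exact sum of the year totals;
#' rounding is applied only at display time.
#'
#' @param port_years the [summarize_port_year()] rows for one port and
#'   pathway.
#' @param vessel_volumes optional vector of the port's per-vessel corrected
#'   discharges, used for the pooled (population) SD; `NA` otherwise.
#' @return single-row data frame with `port`, `pathway`,
#'   `mean_arrivals_per_year`, `mean_dischargers_per_year`,
#'   `pooled_mean_mt`, `pooled_sd_mt`, `mean_per_arrival_mt`,
#'   `total_discharge_mt`.
#' @export
summarize_port <- function(port_years, vessel_volumes = NULL) {
  stopifnot(nrow(port_years) >= 1L,
            length(unique(port_years$port)) == 1L,
            length(unique(port_years$pathway)) == 1L)
  total <- sum(port_years$total_discharge_mt)
  n_disc <- sum(port_years$n_dischargers)
  n_arr <- sum(port_years$n_arrivals)
  pooled_sd <- NA_real_
  if (!is.null(vessel_volumes)) {
    disc <- vessel_volumes[vessel_volumes > 0]
    pooled_sd <- if (length(disc)) pop_sd(disc) else 0
  }
  data.frame(port = port_years$port[1], pathway = port_years$pathway[1],
             mean_arrivals_per_year = mean(port_years$n_arrivals),
             mean_dischargers_per_year = mean(port_years$n_dischargers),
             pooled_mean_mt = if (n_disc > 0) total / n_disc else 0,
             pooled_sd_mt = pooled_sd,
             mean_per_arrival_mt = if (n_arr > 0) total / n_arr else 0,
             total_discharge_mt = total, stringsAsFactors = FALSE)
}

#' Full shipping summary (year rows plus port rows)
#'
#' @param records completed `ballast_records`.
#' @return list with `port_year` (see [summarize_port_year()]) and `port`
#'   (one [summarize_port()] row per port and pathway, with pooled SDs
#'   computed from the per-vessel corrected discharges).
#' @export
discharge_summary <- function(records) {
  py <- summarize_port_year(records)
  v <- corrected_vessel_table(records)
  port <- do.call(rbind, lapply(
    split(py, interaction(py$port, py$pathway, drop = TRUE)), function(g) {
      vols <- v$corrected_mt[v$arrival_port == g$port[1] &
                               v$pathway == g$pathway[1]]
      summarize_port(g, vessel_volumes = vols)
    }))
  rownames(port) <- NULL
  port <- port[order(port$pathway, port$port), , drop = FALSE]
  list(port_year = py, port = port)
}

#' Display-rounded shipping summary table
#'
#' Applies the tabular rounding convention (one decimal, halves away from
#' zero) to a summary produced by [discharge_summary()].
#'
#' @param summary list from [discharge_summary()].
#' @return list of two rounded data frames.
#' @export
format_discharge_summary <- function(summary) {
  py <- summary$port_year
  for (cc in c("mean_discharge_mt", "sd_discharge_mt", "total_discharge_mt"))
    py[[cc]] <- round_half_up(py[[cc]], 1)
  pt <- summary$port
  for (cc in c("mean_arrivals_per_year", "mean_dischargers_per_year",
               "pooled_mean_mt", "pooled_sd_mt", "mean_per_arrival_mt",
               "total_discharge_mt"))
    pt[[cc]] <- round_half_up(pt[[cc]], 1)
  list(port_year = py, port = pt)
}
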