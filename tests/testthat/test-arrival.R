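# Likelihood of arrival: correction factors, transit scores, presence
# filtering, the per-vessel raw score and its normalization/aggregation.

test_that("exchange correction factors follow the published efficacy rates", {
  expect_equal(bwe_correction_factor(TRUE, "marine"), 0.1)
  expect_equal(bwe_correction_factor(TRUE, "brackish"), 0.1)
  expect_equal(bwe_correction_factor(TRUE, "fresh"), 0.01)
  expect_equal(bwe_correction_factor(FALSE, "fresh"), 1)
  expect_equal(bwe_correction_factor(FALSE, "marine"), 1)
  # unknown source salinity falls back to the weaker (saline) correction
  expect_equal(bwe_correction_factor(TRUE, NA), 0.1)
  expect_error(bwe_correction_factor(TRUE, "salty"), "invalid salinity")
})

test_that("transit time is a whole-day difference and must be chronological", {
  expect_equal(transit_days(as.Date("2005-07-01"), as.Date("2005-07-08")), 7L)
  expect_equal(transit_days(as.Date("2005-07-01"), as.Date("2005-07-01")), 0L)
  expect_error(transit_days(as.Date("2005-07-08"), as.Date("2005-07-01")),
               "chronology")
})

test_that("transit scores bracket the larval-duration window", {
  sp <- mini_species()  # 28-49 d, midpoint 38.5
  expect_equal(transit_score(20, sp), 3L)
  expect_equal(transit_score(37, sp), 3L)   # whole domestic transit span is 'high'
  expect_equal(transit_score(45, sp), 2L)
  expect_equal(transit_score(49, sp), 2L)   # at the maximum: still moderate
  expect_equal(transit_score(50, sp), 1L)
  expect_equal(transit_score(60, sp), 1L)
})

test_that("presence membership works by port set and by polygon", {
  ports <- mini_ports()
  sp <- mini_species(presence = "SRC_IN")
  expect_true(port_in_range("SRC_IN", sp, ports))
  expect_false(port_in_range("SRC_OUT", sp, ports))
  # polygon around SRC_IN (-60, 47)
  poly <- cbind(c(-65, -55, -55, -65), c(45, 45, 50, 50))
  sp2 <- mini_species(presence = character(0), polys = list(poly))
  expect_true(port_in_range("SRC_IN", sp2, ports))
  expect_false(port_in_range("ARR1", sp2, ports))
  expect_error(port_in_range("NOWHERE", sp2, ports), "lookup error")
})

test_that("raw arrival likelihood multiplies volume, correction and score", {
  ports <- mini_ports()
  sp <- mini_species()
  # 1000 MT, no exchange, in range, 10-d transit (score 3)
  r1 <- complete_records(recs(rec_row()))
  expect_equal(arrival_raw(r1, sp, ports), 3000)
  # mid-ocean exchange, marine source, 45-d transit (score 2): 1000*0.1*2
  r2 <- complete_records(recs(rec_row(uptake_date = "2005-07-01",
                                      exchange_type = "mid_ocean")))
  expect_equal(arrival_raw(r2, sp, ports), 200)
  # out-of-range source contributes nothing
  r3 <- complete_records(recs(rec_row(source_port = "SRC_OUT")))
  expect_equal(arrival_raw(r3, sp, ports), 0)
  # no-discharge arrival scores zero
  r4 <- complete_records(recs(rec_row(tank_id = NA, source_port = NA,
                                      uptake_date = NA, tank_volume_mt = NA,
                                      source_salinity_ppt = NA,
                                      exchange_type = NA)))
  expect_equal(arrival_raw(r4, sp, ports), 0)
})

test_that("coastal exchange credits the exchange site with the swapped volume", {
  ports <- mini_ports()
  # fresh source out of range, coastal exchange at an in-range site:
  # f = 0.01, so 0.99 of the tank is attributed to the exchange location
  sp <- mini_species(presence = "XLOC")
  r <- complete_records(recs(rec_row(source_port = "SRC_OUT",
                                     source_salinity_ppt = 2,
                                     exchange_type = "coastal",
                                     exchange_location = "XLOC")))
  expect_equal(arrival_raw(r, sp, ports), 1000 * 0.99 * 3)
  # both source and exchange site in range: weights sum to the full volume
  sp2 <- mini_species(presence = c("SRC_OUT", "XLOC"))
  expect_equal(arrival_raw(r, sp2, ports), 1000 * 3)
  # mid-ocean exchange never earns presence credit
  r2 <- complete_records(recs(rec_row(source_port = "SRC_OUT",
                                      source_salinity_ppt = 2,
                                      exchange_type = "mid_ocean",
                                      exchange_location = "XLOC")))
  expect_equal(arrival_raw(r2, sp, ports), 0)
})

test_that("toggling exchange divides contributions by exactly 10 or 100", {
  ports <- mini_ports()
  sp <- mini_species()
  base <- complete_records(recs(rec_row()))
  marine <- complete_records(recs(rec_row(exchange_type = "mid_ocean")))
  expect_equal(arrival_raw(base, sp, ports) / arrival_raw(marine, sp, ports), 10)
  fresh0 <- complete_records(recs(rec_row(source_salinity_ppt = 2)))
  fresh1 <- complete_records(recs(rec_row(source_salinity_ppt = 2,
                                          exchange_type = "mid_ocean")))
  expect_equal(arrival_raw(fresh0, sp, ports) / arrival_raw(fresh1, sp, ports),
               100)
})

test_that("arrival_raw equals an independent triple-loop oracle", {
  ports <- mini_ports()
  sp <- mini_species()
  oracle <- function(records, species, ports) {
    total <- 0
    for (i in seq_len(nrow(records))) {
      row <- records[i, ]
      if (is.na(row$tank_id)) next
      present <- row$source_port %in% species$presence_ports
      f <- 1
      if (row$exchange_type != "none") {
        f <- if (!is.na(row$source_salinity_ppt) &&
                 row$source_salinity_ppt <= 5) 0.01 else 0.1
      }
      days <- as.integer(row$discharge_date - row$uptake_date)
      s <- if (days < (species$larval_min_days + species$larval_max_days) / 2) 3
           else if (days <= species$larval_max_days) 2 else 1
      v <- row$tank_volume_mt * f * as.numeric(present)
      if (row$exchange_type == "coastal" && !is.na(row$exchange_location))
        v <- v + row$tank_volume_mt * (1 - f) *
          (row$exchange_location %in% species$presence_ports)
      total <- total + v * s
    }
    total
  }
  set.seed(42)
  for (rep in 1:20) {
    n <- sample(1:5, 1)
    rows <- lapply(seq_len(n), function(i)
      rec_row(vessel_id = "V1",
              source_port = sample(c("SRC_IN", "SRC_OUT"), 1),
              tank_id = sprintf("T%d", i),
              uptake_date = as.character(as.Date("2005-08-15") -
                                           sample(0:60, 1)),
              tank_volume_mt = round(stats::runif(1, 1, 5000), 1),
              source_salinity_ppt = round(stats::runif(1, 0, 35), 1),
              exchange_type = sample(c("none", "mid_ocean", "coastal"), 1),
              exchange_location = sample(c("SRC_IN", "XLOC", NA), 1)))
    rows <- lapply(rows, function(r) {
      if (r$exchange_type == "none") r$exchange_location <- NA
      r
    })
    r <- complete_records(do.call(recs, rows))
    expect_equal(arrival_raw(r, sp, ports), oracle(r, sp, ports))
  }
})

test_that("normalization divides by the maximum and tolerates degeneracy", {
  expect_equal(normalize_max(c(2, 4, 8)), c(0.25, 0.5, 1))
  expect_equal(normalize_max(c(0, 0)), c(0, 0))
  expect_equal(normalize_max(5), 1)
  expect_equal(normalize_max(numeric(0)), numeric(0))
})

test_that("raw likelihood scales with volume and is unchanged after normalization", {
  ports <- mini_ports()
  sp <- mini_species()
  set.seed(7)
  rows <- lapply(1:6, function(i)
    rec_row(vessel_id = sprintf("V%d", i),
            tank_volume_mt = round(stats::runif(1, 10, 4000), 1),
            uptake_date = as.character(as.Date("2005-08-15") - sample(5:60, 1)),
            source_port = sample(c("SRC_IN", "SRC_OUT"), 1)))
  r1 <- complete_records(do.call(recs, rows))
  r2 <- r1; r2$tank_volume_mt <- r2$tank_volume_mt * 2
  a1 <- arrival_scores(r1, list(sp), ports)
  a2 <- arrival_scores(r2, list(sp), ports)
  expect_equal(a2$raw, 2 * a1$raw)
  expect_equal(a2$normalized, a1$normalized)
})

test_that("raw likelihood is monotone in tank volume and transit score", {
  ports <- mini_ports()
  sp <- mini_species()
  base <- complete_records(recs(rec_row(uptake_date = "2005-07-01")))  # score 2
  more_vol <- complete_records(recs(rec_row(uptake_date = "2005-07-01",
                                            tank_volume_mt = 1500)))
  faster <- complete_records(recs(rec_row(uptake_date = "2005-08-05")))  # score 3
  expect_gte(arrival_raw(more_vol, sp, ports), arrival_raw(base, sp, ports))
  expect_gte(arrival_raw(faster, sp, ports), arrival_raw(base, sp, ports))
})

test_that("aggregation modes are the within-key mean and sum", {
  scores <- data.frame(port = "ARR1", year = 2005, pathway = "domestic",
                       species = "sp1", vessel_id = c("V1", "V2"),
                       raw = c(100, 300), normalized = c(0.25, 0.75))
  m <- aggregate_arrival(scores, "mean_per_vessel", value_col = "raw")
  s <- aggregate_arrival(scores, "cumulative_annual", value_col = "raw")
  expect_equal(m$value, 200)
  expect_equal(s$value, 400)
  # cumulative >= per-vessel mean for any nonnegative per-vessel set
  set.seed(13)
  for (rep in 1:25) {
    x <- stats::runif(sample(1:8, 1), 0, 100)
    df <- data.frame(port = "p", year = 1, pathway = "domestic",
                     species = "s", raw = x, normalized = x)
    expect_gte(aggregate_arrival(df, "cumulative_annual", "raw")$value,
               aggregate_arrival(df, "mean_per_vessel", "raw")$value)
  }
})
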