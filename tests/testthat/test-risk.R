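# Risk synthesis: establishment normalization, overall risk, category bands,
# uncertainty propagation, matrix export and end-to-end monotonicity.

keyed <- function(value, port = paste0("p", seq_along(value))) {
  data.frame(port = port, year = 2005L, pathway = "domestic", species = "s",
             value = value, stringsAsFactors = FALSE)
}

test_that("establishment is the per-key product, min-max normalized", {
  est <- establishment(keyed(c(0, 5, 10)), keyed(c(1, 1, 1)))
  expect_equal(est$value, c(0, 0.5, 1))
  # zero arrival forces zero establishment
  est2 <- establishment(keyed(c(0, 2, 4)), keyed(c(3, 3, 3)))
  expect_equal(est2$value[1], 0)
  # all-equal nonzero products normalize to 1
  est3 <- establishment(keyed(c(2, 2)), keyed(c(1, 1)))
  expect_equal(est3$value, c(1, 1))
  expect_error(establishment(keyed(c(1, 2)), keyed(c(1, 2), port = c("p1", "zz"))),
               "alignment error")
})

test_that("overall risk is the product and respects its bounds", {
  expect_equal(overall_risk(0, 0.9), 0)
  expect_equal(overall_risk(1, 1), 1)
  expect_equal(overall_risk(c(0.5, 0.2), c(0.4, 0.9)), c(0.2, 0.18))
  expect_error(overall_risk(1.2, 0.5), "\\[0, 1\\]")
})

test_that("category bands cut the product at 1/9 and 4/9", {
  expect_equal(categorize(0.9, 0.9), "high")
  expect_equal(categorize(0.2, 0.2), "low")
  expect_equal(categorize(0.5, 0.5), "moderate")
  expect_equal(categorize(1/3, 1/3), "moderate")  # boundary: 1/9 inclusive
  expect_equal(categorize(2/3, 2/3), "high")      # boundary: 4/9 inclusive
  # monotone along the diagonal ray
  t <- seq(0, 1, by = 0.01)
  cat_idx <- match(categorize(t, t), c("low", "moderate", "high"))
  expect_true(all(diff(cat_idx) >= 0))
  # thresholds are configurable
  expect_equal(categorize(0.5, 0.5, thresholds = c(0.3, 0.9)), "low")
})

test_that("uncertainty combination is a join on the ordinal lattice", {
  lv <- c("low", "moderate", "high")
  for (a in lv) for (b in lv) {
    expect_equal(uncertainty_join(a, b), uncertainty_join(b, a))
    expect_equal(uncertainty_join(a, a), a)
    for (cc in lv)
      expect_equal(uncertainty_join(uncertainty_join(a, b), cc),
                   uncertainty_join(a, uncertainty_join(b, cc)))
  }
  expect_error(uncertainty_join("low", "unknown"), "invalid")
})

test_that("component uncertainty propagates to stage and overall grades", {
  # moderate arrival data, everything else well documented
  u <- combine_uncertainty(uncertainty_ledger("moderate", "low", "low", "low"))
  expect_equal(u$establishment, "moderate")
  expect_equal(u$consequence, "low")
  expect_equal(u$overall, "moderate")
  expect_equal(combine_uncertainty(uncertainty_ledger("low", "low", "low",
                                                      "low"))$overall, "low")
  expect_equal(combine_uncertainty(uncertainty_ledger("low", "low", "high",
                                                      "low"))$overall, "high")
})

test_that("risk-matrix datasets sort by overall risk with stable tie-breaks", {
  cells <- data.frame(
    port = c("B", "A", "C"), year = c(2006L, 2005L, 2007L),
    species = "s", pathway = "domestic", mode = "per_vessel",
    establishment = c(0.5, 0.5, 0.9), consequence = c(0.4, 0.4, 0.9),
    overall = c(0.2, 0.2, 0.81), category = c("moderate", "moderate", "high"),
    stringsAsFactors = FALSE)
  m <- build_matrix(cells, "domestic", "per_vessel")
  expect_equal(nrow(m), 3L)
  expect_equal(m$label, c("C 2007", "A 2005", "B 2006"))  # tie: A before B
  empty <- build_matrix(cells, "international", "per_vessel")
  expect_equal(nrow(empty), 0L)
})

# A small deterministic scenario for end-to-end checks: two arrival ports,
# three vessels (one out-of-range anchor), two species, uniform surfaces.
scenario <- function() {
  rows <- rbind(
    rec_row("V1", arrival_port = "ARR1", tank_volume_mt = 1000,
            uptake_date = "2005-08-05"),
    rec_row("V2", arrival_port = "ARR1", tank_volume_mt = 500,
            uptake_date = "2005-07-01"),
    rec_row("V3", arrival_port = "ARR2", tank_volume_mt = 800,
            source_port = "SRC_OUT"))
  list(records = ballast_records(rows), ports = mini_ports(),
       species = list(sp1 = mini_species("sp1"),
                      sp2 = mini_species("sp2", min_d = 14, max_d = 21,
                                         impacts = c(3, 3, 3, 3))),
       surfaces = list(sp1 = uniform_surface(0.5, "sp1"),
                       sp2 = uniform_surface(0.8, "sp2")))
}

test_that("the driver produces coherent risk cells", {
  sc <- scenario()
  ra <- assess_risk(sc$records, sc$ports, sc$species, sc$surfaces)
  cells <- ra$cells
  expect_s3_class(ra, "risk_assessment")
  expect_true(all(cells$establishment >= 0 & cells$establishment <= 1))
  expect_true(all(cells$consequence >= 0 & cells$consequence <= 1))
  expect_equal(cells$overall, cells$establishment * cells$consequence)
  expect_true(all(cells$category %in% c("low", "moderate", "high")))
  expect_equal(unique(cells$uncertainty), "moderate")
  # the out-of-range port-year has zero establishment for both species
  arr2 <- cells[cells$port == "ARR2", ]
  expect_true(all(arr2$establishment == 0))
  expect_true(all(arr2$overall == 0))
  # per-mode normalization: some cell attains establishment 1 in each mode
  for (md in unique(cells$mode))
    expect_equal(max(cells$establishment[cells$mode == md]), 1)
  # methods run
  expect_output(print(ra), "risk assessment")
  expect_output(print(summary(ra)), "Highest-risk")
  expect_s3_class(as.data.frame(ra), "data.frame")
})

test_that("overall risk is monotone under single-factor improvements", {
  # Relative (normalized) risk of one cell can only be expected to rise when
  # the normalization anchors are pinned elsewhere, so the scenario keeps a
  # dominant unperturbed cell (V2 at ARR2, both species) and a zero cell
  # (ARR2 in 2006). The perturbed cell is ARR1 x sp1.
  mk <- function() {
    rows <- rbind(
      rec_row("V1", arrival_port = "ARR1", tank_volume_mt = 1000,
              discharge_date = "2005-04-15", uptake_date = "2005-03-01"),
      rec_row("V2", arrival_port = "ARR2", tank_volume_mt = 6000,
              uptake_date = "2005-08-05"),
      rec_row("V3", arrival_port = "ARR2", discharge_date = "2006-08-15",
              uptake_date = "2006-08-05", source_port = "SRC_OUT"))
    list(records = ballast_records(rows), ports = mini_ports(),
         species = list(sp1 = mini_species("sp1"),
                        sp2 = mini_species("sp2", min_d = 14, max_d = 21,
                                           impacts = c(3, 3, 3, 3))),
         surfaces = list(sp1 = uniform_surface(0.5, "sp1"),
                         sp2 = uniform_surface(0.8, "sp2")))
  }
  sc <- mk()
  base <- assess_risk(sc$records, sc$ports, sc$species, sc$surfaces)
  target <- function(ra)
    ra$cells[ra$cells$port == "ARR1" & ra$cells$species == "sp1" &
               ra$cells$year == 2005 &
               ra$cells$mode == "cumulative_annual", "overall"]

  # more volume in the in-range tank
  up <- mk(); up$records$tank_volume_mt[1] <- 2000
  expect_gte(target(assess_risk(up$records, up$ports, up$species,
                                up$surfaces)), target(base))
  # shorter transit (45 d, moderate score -> 10 d, high score)
  up <- mk(); up$records$uptake_date[1] <- as.Date("2005-04-05")
  expect_gte(target(assess_risk(up$records, up$ports, up$species,
                                up$surfaces)), target(base))
  # higher suitability for the target species
  up <- mk(); up$surfaces$sp1 <- uniform_surface(0.7, "sp1")
  expect_gte(target(assess_risk(up$records, up$ports, up$species,
                                up$surfaces)), target(base))
  # warmer discharge season (spring -> summer, transit preserved)
  up <- mk()
  up$records$discharge_date[1] <- as.Date("2005-07-15")
  up$records$uptake_date[1] <- as.Date("2005-05-31")
  expect_gte(target(assess_risk(up$records, up$ports, up$species,
                                up$surfaces)), target(base))
  # higher impact score for the target species
  up <- mk(); up$species$sp1$impact_trophic <- 3L
  expect_gte(target(assess_risk(up$records, up$ports, up$species,
                                up$surfaces)), target(base))
  # higher habitat sensitivity at the target port
  up <- mk()
  up$ports$biological_importance[up$ports$port_id == "ARR2"] <- TRUE
  up$ports$hotspot[up$ports$port_id == "ARR2"] <- TRUE
  ra2 <- assess_risk(up$records, up$ports, up$species, up$surfaces)
  expect_gte(ra2$cells[ra2$cells$port == "ARR2" & ra2$cells$species == "sp1" &
                         ra2$cells$year == 2005 &
                         ra2$cells$mode == "cumulative_annual", "overall"],
             base$cells[base$cells$port == "ARR2" &
                          base$cells$species == "sp1" &
                          base$cells$year == 2005 &
                          base$cells$mode == "cumulative_annual", "overall"])
})

test_that("plot and export methods produce their artifacts", {
  sc <- scenario()
  ra <- assess_risk(sc$records, sc$ports, sc$species, sc$surfaces)
  path <- withr::local_tempfile(fileext = ".png")
  grDevices::png(path, width = 400, height = 400)
  m <- plot(ra, pathway = "domestic", mode = "cumulative_annual")
  grDevices::dev.off()
  expect_true(file.exists(path))
  expect_true(nrow(m) > 0)
  dir <- withr::local_tempdir()
  export_results(ra, dir)
  expect_setequal(list.files(dir),
                  c("arrival_scores.csv", "survival_scores.csv",
                    "consequence_scores.csv", "risk_cells.csv"))
})
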