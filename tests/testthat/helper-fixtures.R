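# Shared in-code fixtures: a minimal port table, record-row builder and
# uniform suitability surfaces.

mini_ports <- function() {
  port_table(data.frame(
    port_id = c("ARR1", "ARR2", "SRC_IN", "SRC_OUT", "XLOC"),
    name = c("Arrival one", "Arrival two", "Source inside range",
             "Source outside range", "Coastal exchange site"),
    lat = c(60, 62, 47, 50, 48),
    lon = c(-70, -68, -60, -5, -55),
    ecoregion = c("arctic", "arctic", "temperate", "temperate", "temperate"),
    ebsa = c(TRUE, TRUE, FALSE, FALSE, FALSE),
    overlapping_species = c(TRUE, TRUE, FALSE, FALSE, FALSE),
    biological_importance = c(TRUE, FALSE, FALSE, FALSE, FALSE),
    hotspot = c(TRUE, FALSE, FALSE, FALSE, FALSE),
    stringsAsFactors = FALSE))
}

# periwinkle-like defaults: 4-7 week larval stage, presence at SRC_IN
mini_species <- function(id = "sp1", min_d = 28, max_d = 49,
                         presence = "SRC_IN", polys = list(),
                         impacts = c(2, 2, 3, 2)) {
  species_profile(id, larval_min_days = min_d, larval_max_days = max_d,
                  impact_biodiversity = impacts[1],
                  impact_interactions = impacts[2],
                  impact_habitat = impacts[3], impact_trophic = impacts[4],
                  presence_ports = presence, presence_polygons = polys)
}

# one tank row with overridable fields
rec_row <- function(vessel_id = "V1", pathway = "domestic",
                    arrival_port = "ARR1", discharge_date = "2005-08-15",
                    last_port_of_call = "SRC_IN", volume_on_board_mt = NA,
                    tank_id = "T1", source_port = "SRC_IN",
                    uptake_date = "2005-08-05", tank_volume_mt = 1000,
                    source_salinity_ppt = 30, exchange_type = "none",
                    exchange_location = NA) {
  data.frame(vessel_id = vessel_id, pathway = pathway,
             arrival_port = arrival_port, discharge_date = discharge_date,
             last_port_of_call = last_port_of_call,
             volume_on_board_mt = volume_on_board_mt, tank_id = tank_id,
             source_port = source_port, uptake_date = uptake_date,
             tank_volume_mt = tank_volume_mt,
             source_salinity_ppt = source_salinity_ppt,
             exchange_type = exchange_type,
             exchange_location = exchange_location, stringsAsFactors = FALSE)
}

recs <- function(...) ballast_records(rbind(...))

# constant surface covering the mini arrival ports (lon -75..-65, lat 58..64)
uniform_surface <- function(value, species_id = "sp1") {
  suitability_surface(species_id, matrix(value, nrow = 6, ncol = 10),
                      xll = -75, yll = 58, cellsize = 1)
}
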