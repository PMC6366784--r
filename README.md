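# ballastrisk

Relative ecological risk assessment of marine species introductions via
ballast water discharge.

## The problem

Ships move coastal organisms around the world in ballast tanks. For a port
system that has not yet been invaded — the motivating case is the Canadian
Arctic, whose 35 ports are seeing rapidly growing traffic as sea ice
retreats — managers want to know *which ports, years, species and shipping
pathways carry the most risk*, before any introduction happens.
`ballastrisk` is for invasion ecologists and risk assessors who have
tank-level ballast reporting data, species trait profiles and habitat
suitability surfaces, and need a transparent, reproducible, species-level
relative risk assessment.

## The model

Overall risk per port, year, species and pathway (domestic vs
international), in per-vessel and cumulative-annual modes:

```
establishment = arrival x survival-establishment   (each then min-max normalized
overall risk  = establishment x consequence         across the whole run)
```

with

* **arrival** (per vessel) = sum over tanks of
  `volume x BWE correction x transit score`, counting only tanks whose
  ballast source lies in the species' presence range. The ballast-water-
  exchange (BWE) correction is 0.1 for saline/brackish sources, 0.01 for
  freshwater sources, 1 when no exchange was performed. The transit score
  is 3/2/1 as the ballast-water age falls below the species' average larval
  duration, within the larval window, or beyond its maximum.
* **survival-establishment** = habitat suitability at the arrival port
  (standardized across species by the single maximum modelled value) x a
  season score (winter 1, spring/autumn 2, summer 3).
* **consequence** = summed four-category impact rubric (4-12) x port
  habitat-sensitivity score (1-3 from overlapped sensitivity variables).

Reporting gaps are completed by the standard assumptions (last port of
call, pathway-default exchange, volume on board, pathway-mean transit),
each fill flagged. Qualitative uncertainty grades propagate by the maximum.
Everything is *relative*: scores are comparable only within one run.

## Worked example

```r
library(ballastrisk)

b  <- generate_bundle(sim_config(seed = 1))      # synthetic study-scale inputs
ra <- assess_risk(b$records, b$ports, b$species, b$surfaces,
                  voluntary_bwe = b$voluntary_bwe)
summary(ra)
```

```
Risk assessment summary (510 cells)
Highest-risk cell per pathway and mode:
  port year                    species       pathway              mode
1  P02 2007               mya_arenaria      domestic cumulative_annual
2  P01 2008 paralithodes_camtschaticus      domestic        per_vessel
3  P01 2006 paralithodes_camtschaticus international cumulative_annual
4  P05 2008 paralithodes_camtschaticus international        per_vessel
  establishment consequence overall category
1        1.0000       0.375  0.3750 moderate
2        0.3850       1.000  0.3850 moderate
3        0.0152       1.000  0.0152      low
4        0.0434       0.542  0.0235      low
Uncertainty: establishment moderate, consequence low, overall moderate
```

Each row is the highest-risk port-year for a pathway/mode: `establishment`
is the normalized likelihood the species arrives and survives there that
year, `consequence` the normalized impact-times-sensitivity of that port
for that species, `overall` their product, banded low/moderate/high at
product cuts 1/9 and 4/9. Domestic discharges dominate because they are
un-exchanged and originate within the species' ranges;
`plot(ra, pathway = "domestic", mode = "cumulative_annual")` draws the
gradient risk matrix.

The reporting side works from records alone. On the package's reference
fleet — synthesized to match the published 2005-2014 Canadian Arctic
per-port discharge summary — the port of Churchill comes out as:

```r
s <- discharge_summary(reference_fleet())
format_discharge_summary(s)$port[s$port$port == "Churchill", ]
```

```
        port       pathway mean_arrivals_per_year mean_dischargers_per_year
4  Churchill      domestic                    3.6                       3.6
13 Churchill international                   16.1                      15.1
   pooled_mean_mt pooled_sd_mt mean_per_arrival_mt total_discharge_mt
4          5705.3       4378.8              5705.3           102694.8
13          955.7        187.0               896.5           115643.0
```

i.e. 3.6 domestic arrivals per year averaging 5 705.3 MT of corrected
ballast per discharging vessel (102 694.8 MT in total), against 16.1
international arrivals averaging only 955.7 MT per discharging vessel
(896.5 per arrival, as some international arrivals do not discharge) —
mid-ocean exchange discounts international discharges by 10-100x.

## Layout

* `R/` — record I/O and completion, arrival, survival, consequence, risk
  synthesis, reporting, synthetic-data generators
* `tests/testthat/` — unit, property and acceptance tests
* `vignettes/ballast-risk-methods.Rmd` — the methods vignette: model,
  assumptions, parameter choices, generator calibration, limitations
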