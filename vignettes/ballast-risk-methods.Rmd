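---
title: "Methods: relative ecological risk of ballast-water-mediated introductions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: relative ecological risk of ballast-water-mediated introductions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ballastrisk)
```

## The model

`ballastrisk` implements a species-level relative ecological risk assessment
for marine invasions via ballast water discharge. Risk is the combination of
the likelihood of an event and its consequence:

* **Establishment** (the likelihood side) is the product of
  * the *likelihood of arrival* — for each vessel arrival, the sum over its
    ballast tanks of discharged volume × an exchange correction factor × a
    transit-time score, restricted to tanks whose ballast source lies in the
    assessed species' presence range, then normalized so the highest value
    in the run is 1; and
  * the *likelihood of survival-establishment* — habitat suitability at the
    arrival port (standardized across species by the single maximum
    modelled value in the study region) × a season-of-discharge score.
* **Consequence of occurrence** is the product of a species' summed
  four-category impact rubric (changes in biodiversity, interspecific
  interactions, habitat, trophic interactions; each scored 1–3, so totals
  span 4–12) and the receiving port's habitat-sensitivity score (1–3,
  from the count of overlapped sensitivity variables: significant areas,
  overlapping species, high biological importance, hot spots).
* **Overall risk** = establishment × consequence, per port, year, species
  and pathway (domestic vs international), in two aggregation modes:
  *mean per vessel* and *cumulative annual* (based on the total volumes
  discharged at a port over a year).

Both establishment and consequence are min–max normalized across all
species, ports, years and pathways in the run before being multiplied, so
every number the package reports is **relative to the assessed set**: adding
or removing a species or port changes the scale, by design.

The assessment deliberately stops at first arrival: secondary spread,
hull fouling, ballast sediments and economic/social impacts are out of
scope, and habitat-suitability surfaces are consumed as input (from any
species distribution model producing values in [0, 1]), never fitted here.

## Parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| Exchange correction | 0.1 saline/brackish, 0.01 fresh | — | published exchange efficacies of ~90% / ~99% zooplankton removal |
| Salinity classes | fresh [0, 5], brackish (5, 18], marine (18, ∞) | ppt | half-open partition consistent with the conventional 0–5 / 5.1–18 / >18.1 anchors |
| Transit score | 3 below the average larval duration, 2 up to the maximum, 1 beyond | — | faster transits deliver more viable propagules |
| Average larval duration | midpoint of the typical range | days | the typical range is what species accounts publish; the midpoint makes 5–37-day transits uniformly "high" for a 4–7-week larva |
| Season score | winter 1, spring/autumn 2, summer 3 | — | temperate propagules survive best in warm water; months, not solstices, define the seasons |
| Suitability fallback radius | 50 | km | ports sit on coastlines where model grids are frequently masked; the nearest valid cell within the radius is used |
| Risk-category cuts | 1/9 and 4/9 on the product | — | corners of a 3×3 likelihood–consequence grid with axis cuts at 1/3 and 2/3; configurable via `thresholds` |

## Completion of reporting gaps

Ballast reports are incomplete in practice. `complete_records()` applies,
and flags, the standard assumptions: a missing tank source is the last port
of call; a missing exchange type is mid-ocean exchange for international
vessels and no management for domestic vessels (coastal exchange for
vessels known to exchange voluntarily); a known discharge with no volume
uses the ballast volume on board (the remainder after observed tanks, split
equally across the missing tanks); a missing uptake date is imputed from
the mean transit time of the same pathway, because the domestic (5–37 d)
and international (5–135 d) fleets have disjoint transit regimes. The
operation is idempotent, and every filled field carries an imputation flag.

When an exchanged tank has no recorded source salinity the saline/brackish
factor (0.1) is used rather than the freshwater one: assuming the weaker
correction is the conservative choice.

## Coastal exchange as a second source

Coastal exchange replaces most of a tank with water taken up at the
exchange site. The package therefore treats the exchange location of a
coastal-exchanged tank as a second candidate source: the pre-exchange
source keeps weight equal to the correction factor and the exchange site
carries the complement. A domestic vessel that loads fresh water outside a
species' range and exchanges inside it consequently *gains* arrival
likelihood — the management action can increase risk. Mid-ocean exchange
sites are open ocean, are never in a benthic species' presence range, and
earn no such credit, so the behaviour reduces to the plain correction
factors for international traffic.

## Normalization choices

Three distinct normalizations are used, on purpose:

1. arrival: divide by the maximum (zero stays zero; "1 is the highest");
2. suitability: divide all species' surfaces by the single global maximum
   valid-cell value (the operative study region is the union of the grids
   supplied);
3. establishment and consequence: min–max across all keys and species.

Per-vessel arrival values are normalized once, before any averaging; the
cumulative-annual mode sums raw (unnormalized) per-vessel values within a
port-year and normalizes the sums, reflecting total discharged volumes.
Degenerate cases are pinned: an all-zero set normalizes to zeros, an
all-equal nonzero set min–max-normalizes to all 1, and an empty group
reports 0, not `NA`.

Because all outputs are relative, overall risk is monotone in volume,
transit score, suitability, season, impact and sensitivity only *given
fixed normalization anchors*: improving one factor of one cell can lower
another cell's relative rank, and can even lower the same cell's value when
the change benefits a competing species more. The test suite pins the
anchors (a dominant unperturbed cell and a zero cell) when asserting
monotonicity end-to-end.

## Uncertainty

Each of the four components (arrival data, suitability modelling, impact
scoring, sensitivity scoring) carries a qualitative grade, low < moderate <
high. Grades combine by the maximum (a join on the ordinal lattice —
associative, commutative, idempotent), reported per stage and overall. The
default ledger grades arrival moderate (completion assumptions) and the
rest low, which propagates to a moderate overall grade. Uncertainty
annotates the risk cells; it never alters the scores.

## The synthetic-data generator

`sim_config()` defaults encode the study conditions of the 2005–2014
Canadian Arctic ballast-reporting dataset: 75 domestic and 178
international vessels over ten years and 35 arrival ports; vessel-level
missingness of tank-specific sources (47/75 domestic, 68/178
international), uptake dates (51/75, 46/178) and exchange type (15/75,
5/178); volume missingness among discharging vessels (11 of ~70 domestic,
38 of ~126 international, i.e. conditional on the ~93.3% / ~70.8% discharge
rates); transit times uniform on 5–37 d and 5–135 d; discharges
concentrated in the open-water season (70% summer, 5% winter — Arctic
traffic is ice-constrained); tank volumes log-normal (meanlog 7.5, sdlog
1.2, giving the long right tail seen in per-vessel discharge data, with
medians near 1 800 MT). Each generator component draws from its own seeded
stream, so regenerating ports does not perturb the fleet.

What the generator does *not* emulate: real voyage routing, port-to-port
correlation of sources, within-vessel correlation of tank histories, or
true coastlines (surfaces are smooth random fields, optionally masked).
Passing tests on synthetic data therefore demonstrate the pipeline's
arithmetic and its statistical calibration, not predictive validity on
real shipping data.

The deterministic `reference_fleet()` is different in kind: it synthesizes
per-vessel records that exactly reproduce every per-year (arrivals,
dischargers, total) cell of the published 2005–2014 per-port summary
(`reference_summary()`). Where individual volumes are indeterminate the
year total is split equally across that year's dischargers, so per-year
means are reproduced but printed SDs are generally not — except where a
port-year had a single vessel, which pins the summary's SD convention to
the population (n-denominator) form: the two single-vessel years at
Kuujjuaraapik (6.9 and 3384 MT) pool to SD 1688.55 → printed 1688.6,
whereas the sample SD would be 2387.9.

Two published inconsistencies are handled explicitly: the domestic
Deception Bay pooled per-vessel mean divides by arrivals (47) rather than
dischargers (44), so the package reports the dischargers-denominator value
and exposes the per-arrival value alongside; and one international
Deception Bay year prints a mean of 0.54 MT with a total of 0.5 MT for a
single discharger — the fixture uses the vessel volume 0.54, whose total
reproduces the printed cell at display precision.

## Numerical conventions

Internal arithmetic is never rounded; `round_half_up()` (one decimal,
halves away from zero) is applied only at display time, matching how such
summary tables are printed. Dates are calendar dates; transits are whole
days. Ties in risk-matrix ordering break by port then year. Problem sizes
in the test suite are the study's own (253 vessels, 35 ports, 3 species)
plus a 10 000-vessel fleet for parameter-recovery checks.

## A worked run

```{r example, eval = FALSE}
b <- generate_bundle(sim_config(seed = 1))
ra <- assess_risk(b$records, b$ports, b$species, b$surfaces,
                  voluntary_bwe = b$voluntary_bwe)
summary(ra)
plot(ra, pathway = "domestic", mode = "cumulative_annual")
export_results(ra, "risk_output")
```

## Known limitations

* Relative scores cannot be compared across runs with different species or
  port sets.
* Suitability input is limited to ESRI ASCII grids in geographic
  coordinates; one value per port (with nearest-valid fallback) stands in
  for any neighbourhood statistic.
* The transit score is ordinal; no in-tank mortality kinetics or organism
  counts are modelled.
* Presence ranges are binary (port set and/or polygons); no abundance
  weighting at the source.
* The per-contribution transit score is used directly; no per-vessel
  summary score is imposed even where several tanks disagree.
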