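Package: ballastrisk
Title: Relative Ecological Risk Assessment of Ballast-Water-Mediated Species Introductions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for species-level relative ecological risk assessment of marine
    invasions via ballast water discharge. Computes per-vessel and cumulative-annual
    likelihood of arrival from tank-level discharge records (ballast-water-exchange
    correction factors, transit-time scores, species presence filtering), likelihood
    of survival-establishment from habitat-suitability surfaces and discharge season,
    consequence of occurrence from a four-category impact rubric and port habitat
    sensitivity, and combines them on likelihood-consequence risk matrices with
    ordinal uncertainty propagation. Includes seeded generators for synthetic
    shipping traffic, ports, species profiles and suitability surfaces.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: geosphere, mgcv, stats, utils, grDevices, graphics, yaml
Suggests: testthat (>= 3.0.0), jsonlite, withr, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
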