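Package: uavaed
Title: Virtual Drone AED Delivery Simulation for Out-of-Hospital Cardiac Arrest
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulates a city-wide drone (UAV) automated external
    defibrillator delivery program for out-of-hospital cardiac arrest and
    compares it against the ground ambulance baseline. Provides a seeded
    synthetic-data generator (terrain and building rasters, hourly weather
    series, OHCA cohorts with Utstein covariates and log-normal EMS time
    intervals), the cohort inclusion/exclusion cascade, kernel-density and
    inverse-distance-weighted risk mapping on a 50 m lattice, genetic
    algorithm siting of drone stations under a 3 km coverage radius, flight
    time models for Euclidean and obstacle-aware block pathways, weather and
    visibility dispatch gating for four drone capability scenarios with fleet
    availability tracking, and paired statistical comparison of
    call-to-AED-attach outcomes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    ggplot2,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
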