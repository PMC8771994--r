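Package: coldroute
Title: Cold-Chain Delivery Route Optimization for Health Supply Chains
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Plans single-day delivery routes for cold-chain and ambient
    health products (vaccines, syringes, medicines) from a distribution
    warehouse to health facilities. Reads a seven-sheet input workbook
    (parameters, products, center capacities, demand, vehicles, distance
    matrix, road conditions), validates it, and minimizes a user-weighted,
    normalized combination of total transit time and spoilage risk from
    road and vehicle conditions, subject to vehicle capacity, road
    accessibility, a daily time window, exactly-once visits, and even use
    of the available fleet. Routes are constructed with a recalculated
    two-index priority rule and improved by an anytime depth-first
    branch-and-bound under a time budget; a brute-force exact solver,
    a seeded synthetic instance generator, emergency-scenario transforms,
    and a command-line interface are included. Writes route schedules with
    departure times, capacity utilization, fuel and per-diem costs, and
    per-facility product quantities.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    Rcpp,
    readxl,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
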