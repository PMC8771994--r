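#' Specification for the synthetic instance generator
#'
#' @param seed integer; the generator is fully deterministic given the
#'   seed (identical seeds give byte-identical workbooks).
#' @param n_facilities number of delivery facilities, 1-50 (the tool's
#'   recommended operating envelope; the depot is generated in addition).
#' @param n_vehicles number of vehicles, 1-5.
#' @param area_km side of the square area facilities are scattered over
#'   (default 60 km: a district-scale distribution area whose worst
#'   round trip fits the default 10-hour window even on rough dirt roads).
#' @param demand_intensity mean units requested per product per facility
#'   (default 20; draws are Poisson).
#' @param road_class_mix probabilities of the four passable road classes
#'   in vocabulary order (default 0.35, 0.30, 0.20, 0.15: mostly paved
#'   with a rough-road tail).
#' @param block_probability chance that a facility-facility road is
#'   "Not accessible" (default 0.05). Roads touching the depot are always
#'   passable: the distribution warehouse sits on an arterial road, which
#'   also guarantees every generated instance is solvable.
#' @return a `generator_spec` list.
#' @export
generator_spec <- function(seed = 1, n_facilities = 10, n_vehicles = 2,
                           area_km = 60, demand_intensity = 20,
                           road_class_mix = c(0.35, 0.30, 0.20, 0.15),
                           block_probability = 0.05) {
  stopifnot(n_facilities >= 1, n_facilities <= 50,
            n_vehicles >= 1, n_vehicles <= 5,
            area_km > 0, demand_intensity >= 0,
            length(road_class_mix) == 4, all(road_class_mix >= 0),
            sum(road_class_mix) > 0,
            block_probability >= 0, block_probability < 1)
  structure(list(seed = as.integer(seed), n_facilities = as.integer(n_facilities),
                 n_vehicles = as.integer(n_vehicles), area_km = area_km,
                 demand_intensity = demand_intensity,
                 road_class_mix = road_class_mix / sum(road_class_mix),
                 block_probability = block_probability),
            class = "generator_spec")
}

with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Generate a synthetic routing instance
#'
#' Draws a deterministic random instance: facilities placed uniformly in
#' a square area with road distances equal to beeline distance times a
#' 1.3 road-wiggle factor; a product catalogue always containing at least
#' one cold-chain and one ambient product; Poisson demands; a fleet whose
#' cold and ambient capacities are sized to the largest single-facility
#' load (a realistic fleet can always carry its largest drop); and a road
#' network with a mix of surface classes and optional blocked legs
#' between facilities (depot legs stay passable). The same seed always
#' produces the identical instance.
#'
#' @param spec a [generator_spec()].
#' @return a `route_instance`.
#' @export
generate_instance <- function(spec = generator_spec()) {
  stopifnot(inherits(spec, "generator_spec"))
  with_seed(spec$seed, {
    n <- spec$n_facilities
    fac <- c("Warehouse", sprintf("Facility %02d", seq_len(n)))

    cold_pool <- c("Measles vaccine", "Pentavalent vaccine", "BCG vaccine")
    amb_pool <- c("Syringes 5ml", "ORS sachets", "Amoxicillin")
    n_cold <- sample(1:2, 1)
    n_amb <- sample(1:2, 1)
    prods <- data.frame(
      product = c(cold_pool[seq_len(n_cold)], amb_pool[seq_len(n_amb)]),
      requires_cold = c(rep(TRUE, n_cold), rep(FALSE, n_amb)),
      unit_volume = round(runif(n_cold + n_amb, 0.5, 3), 2),
      stringsAsFactors = FALSE)

    demand <- matrix(rpois(length(fac) * nrow(prods), spec$demand_intensity),
                     nrow = length(fac),
                     dimnames = list(fac, prods$product))
    demand["Warehouse", ] <- 0  # the depot's stock is on site
    if (sum(demand) == 0) demand[2, 1] <- 1  # keep the visit set non-empty

    fac_df <- data.frame(
      facility = fac,
      cold_capacity = round(runif(length(fac), 100, 600)),
      ambient_capacity = round(runif(length(fac), 300, 2000)),
      stringsAsFactors = FALSE)

    # fleet sized to the largest single-facility load
    loads <- vapply(fac[-1], function(f) {
      qty <- demand[f, ]
      c(sum(qty * prods$unit_volume * prods$requires_cold),
        sum(qty * prods$unit_volume * !prods$requires_cold))
    }, numeric(2))
    max_cold <- max(loads[1, ], 1)
    max_amb <- max(loads[2, ], 1)
    veh <- data.frame(
      vehicle = sprintf("Vehicle %s", LETTERS[seq_len(spec$n_vehicles)]),
      available = TRUE,
      condition = sample(VEHICLE_CONDITIONS, spec$n_vehicles, replace = TRUE),
      cold_capacity = ceiling(max_cold * runif(spec$n_vehicles, 1.3, 2.2)),
      ambient_capacity = ceiling(max_amb * runif(spec$n_vehicles, 1.3, 2.2)),
      fuel_consumption = round(runif(spec$n_vehicles, 0.10, 0.30), 2),
      crew_size = 2L,
      stringsAsFactors = FALSE)

    xy <- cbind(runif(length(fac), 0, spec$area_km),
                runif(length(fac), 0, spec$area_km))
    dd <- round(as.matrix(stats::dist(xy)) * 1.3, 1)
    dimnames(dd) <- list(fac, fac)

    passable <- ROAD_CLASSES[1:4]
    rc <- matrix("Fully paved", length(fac), length(fac),
                 dimnames = list(fac, fac))
    for (i in seq_along(fac)) {
      for (j in seq_along(fac)) {
        if (j <= i) next
        cls <- sample(passable, 1, prob = spec$road_class_mix)
        if (i > 1 && runif(1) < spec$block_probability) cls <- "Not accessible"
        rc[i, j] <- cls
        rc[j, i] <- cls
      }
    }

    make_instance(
      parameters = list(depot_name = "Warehouse", start_time = "08:00",
                        return_time = "18:00", weight_time = 5,
                        time_budget_seconds = 120,
                        service_hours_per_stop = 0.25,
                        fuel_price = 1.5, per_diem_rate = 25),
      products = prods, facilities = fac_df, demand = demand,
      vehicles = veh,
      network = list(distance = dd, road_class = rc))
  })
}
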