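# Small deterministic instances built in code, shared across test files.

# Three facilities on partially paved roads (speed 60 km/h, risk factor 1),
# one Good vehicle: leg arithmetic stays readable by hand.
tiny_instance <- function(weight_time = 5, service = 0,
                          demand_a = c(10, 5)) {
  fac <- c("Depot", "Center A", "Center B", "Center C")
  dd <- matrix(c(0, 40, 30, 20,
                 40, 0, 50, 45,
                 30, 50, 0, 25,
                 20, 45, 25, 0),
               4, 4, byrow = TRUE, dimnames = list(fac, fac))
  rc <- matrix("Partially paved", 4, 4, dimnames = list(fac, fac))
  dem <- matrix(0, 4, 2, dimnames = list(fac, c("Vaccine", "Syringes")))
  dem["Center A", ] <- demand_a
  dem["Center B", ] <- c(5, 10)
  make_instance(
    parameters = list(depot_name = "Depot", start_time = "08:00",
                      return_time = "18:00", weight_time = weight_time,
                      time_budget_seconds = 120,
                      service_hours_per_stop = service,
                      fuel_price = 1.5, per_diem_rate = 25),
    products = data.frame(product = c("Vaccine", "Syringes"),
                          requires_cold = c(TRUE, FALSE),
                          unit_volume = c(2, 1), stringsAsFactors = FALSE),
    facilities = data.frame(facility = fac,
                            cold_capacity = c(1000, 100, 100, 100),
                            ambient_capacity = c(2000, 200, 200, 200),
                            stringsAsFactors = FALSE),
    demand = dem,
    vehicles = data.frame(vehicle = "Truck", available = TRUE,
                          condition = "Good", cold_capacity = 100,
                          ambient_capacity = 200, fuel_consumption = 0.2,
                          crew_size = 2L, stringsAsFactors = FALSE),
    network = list(distance = dd, road_class = rc))
}

cyclone_path <- function() {
  system.file("extdata", "cyclone", package = "coldroute")
}

cyclone_instance <- function() {
  read_instance(cyclone_path())
}

cyclone_scenario <- function() {
  read_scenario(system.file("extdata", "cyclone_scenario.yaml",
                            package = "coldroute"))
}

fuzz_spec <- function(i, max_fac = 12, max_veh = 3) {
  generator_spec(seed = 20000 + i,
                 n_facilities = 4 + (i %% (max_fac - 3)),
                 n_vehicles = 1 + (i %% max_veh))
}

# Fuzzed solve results are computed once and shared between the
# feasibility and the evenness/conservation acceptance tests.
.fuzz_cache <- new.env(parent = emptyenv())

fuzz_results <- function(n = 500) {
  key <- paste0("n", n)
  if (!is.null(.fuzz_cache[[key]])) return(.fuzz_cache[[key]])
  out <- vector("list", n)
  for (i in seq_len(n)) {
    inst <- generate_instance(fuzz_spec(i))
    sol <- solve_routes(inst, solver_config(time_budget_seconds = 10,
                                            branching_width = 3))
    viol <- check_feasible(sol, inst)
    counts <- table(factor(
      vapply(sol$routes, function(r) r$vehicle, ""),
      levels = instance_available(inst)))
    dir <- file.path(tempdir(), sprintf("fuzz_out_%d", i))
    write_solution(sol, dir)
    hp <- read.csv(file.path(dir, "Health products.csv"),
                   check.names = FALSE)
    unlink(dir, recursive = TRUE)
    resum <- matrix(0, nrow(inst$demand), ncol(inst$demand),
                    dimnames = dimnames(inst$demand))
    for (k in seq_len(nrow(hp))) {
      resum[hp$facility[k], hp$product[k]] <-
        resum[hp$facility[k], hp$product[k]] + hp$quantity[k]
    }
    served <- rownames(inst$demand) %in% visit_set(inst)
    out[[i]] <- list(
      n_violations = nrow(viol),
      count_spread = if (length(counts)) max(counts) - min(counts) else 0,
      conserved = identical(unname(resum[served, , drop = FALSE]),
                            unname(inst$demand[served, , drop = FALSE])))
  }
  .fuzz_cache[[key]] <- out
  out
}

instance_available <- function(instance) {
  as.character(instance$vehicles$vehicle[instance$vehicles$available %in% TRUE])
}

# independent per-constraint evaluation used to cross-check check_feasible()
independent_violates <- function(solution, instance,
                                 profile = default_road_profile()) {
  p <- instance$parameters
  window <- parse_clock(p$return_time) - parse_clock(p$start_time)
  stops_all <- unlist(lapply(solution$routes, function(r) r$stops))
  if (!setequal(stops_all, visit_set(instance)) ||
      anyDuplicated(stops_all)) return(TRUE)
  counts <- table(factor(vapply(solution$routes, function(r) r$vehicle, ""),
                         levels = instance_available(instance)))
  if (length(counts) && length(solution$routes) &&
      max(counts) - min(counts) > 1) return(TRUE)
  for (r in solution$routes) {
    veh <- instance$vehicles[instance$vehicles$vehicle == r$vehicle, ]
    path <- c(p$depot_name, r$stops, p$depot_name)
    hours <- 0
    for (k in seq_len(length(path) - 1)) {
      cls <- instance$network$road_class[path[k], path[k + 1]]
      if (is.na(cls) || cls == "Not accessible") return(TRUE)
      hours <- hours + instance$network$distance[path[k], path[k + 1]] /
        profile$speed[[cls]]
    }
    hours <- hours + as.numeric(p$service_hours_per_stop) * length(r$stops)
    if (hours > window + 1e-9) return(TRUE)
    cold <- sum(vapply(r$stops,
                       function(f) aggregate_demand(instance, f)$cold_volume, 0))
    amb <- sum(vapply(r$stops,
                      function(f) aggregate_demand(instance, f)$ambient_volume, 0))
    if (cold > veh$cold_capacity + 1e-9 ||
        amb > veh$ambient_capacity + 1e-9) return(TRUE)
  }
  FALSE
}
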