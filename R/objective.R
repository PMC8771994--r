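#' Travel time, risk and distance of a single leg
#'
#' A leg's travel time is its distance divided by the speed of its road
#' class; its spoilage risk is `distance * (road_risk + vehicle_risk)`,
#' so longer exposure on worse roads in less reliable vehicles carries
#' more risk of a temperature excursion.
#'
#' @param i,j facility names (an ordered pair).
#' @param vehicle one row of the instance's vehicle table (or any list
#'   with a `condition` element).
#' @param network the instance's `network` list (`distance`, `road_class`).
#' @param profile a `road_profile`; defaults to [default_road_profile()].
#' @return list with `hours`, `risk` and `km`.
#' @export
leg_metrics <- function(i, j, vehicle, network,
                        profile = default_road_profile()) {
  d <- network$distance[i, j]
  if (i == j || d == 0) return(list(hours = 0, risk = 0, km = 0))
  cls <- network$road_class[i, j]
  if (is.na(cls) || cls == "Not accessible") {
    stop(errorCondition(paste0("leg ", i, " -> ", j, " is not accessible"),
                        class = c("coldroute_forbidden_leg", "error")))
  }
  cond <- as.character(vehicle$condition)
  list(hours = d / profile$speed[[cls]],
       risk = d * (profile$road_risk[[cls]] + profile$vehicle_risk[[cond]]),
       km = d)
}

#' Metrics and costs of one route
#'
#' Sums leg metrics over the depot-to-depot tour (depot implicit at both
#' ends of `stops`) and adds the per-stop service time to transit.
#' Fuel cost is `distance * fuel_consumption * fuel_price`; the per-diem
#' cost charges the daily allowance once per crew member for the route,
#' since each route is a single-day round trip.
#'
#' @param route list with `vehicle` (name) and `stops` (ordered character
#'   vector of facility names, depot excluded).
#' @param instance a `route_instance`.
#' @param profile a `road_profile`.
#' @return list with `transit_hours`, `risk`, `distance_km`, `fuel_cost`,
#'   `per_diem_cost`.
#' @export
route_metrics <- function(route, instance, profile = default_road_profile()) {
  p <- instance$parameters
  veh <- instance$vehicles[instance$vehicles$vehicle == route$vehicle, ]
  if (nrow(veh) != 1) stop("unknown vehicle: ", route$vehicle)
  path <- c(p$depot_name, route$stops, p$depot_name)
  hours <- 0; risk <- 0; km <- 0
  for (k in seq_len(length(path) - 1)) {
    lm <- leg_metrics(path[k], path[k + 1], veh, instance$network, profile)
    hours <- hours + lm$hours
    risk <- risk + lm$risk
    km <- km + lm$km
  }
  hours <- hours + as.numeric(p$service_hours_per_stop) * length(route$stops)
  list(transit_hours = hours,
       risk = risk,
       distance_km = km,
       fuel_cost = km * veh$fuel_consumption * as.numeric(p$fuel_price),
       per_diem_cost = as.numeric(p$per_diem_rate) * veh$crew_size)
}

solution_totals <- function(solution) {
  tot <- list(transit_hours = 0, risk = 0, distance_km = 0,
              fuel_cost = 0, per_diem_cost = 0)
  for (r in solution$routes) {
    for (k in names(tot)) tot[[k]] <- tot[[k]] + r$metrics[[k]]
  }
  tot
}

#' Normalization constants for the weighted objective
#'
#' Transit time (hours) and risk (dimensionless) live on different scales,
#' so the objective normalizes each by the corresponding total of a
#' deterministic reference solution -- the pure-time greedy construction.
#' This makes the integer weights affect both objectives similarly: with
#' weights 5/5 both terms of the reference solution contribute equally.
#' A zero reference total (e.g. all-paved roads and Good vehicles give
#' zero risk) is replaced by 1 so the objective stays finite.
#'
#' @param instance a `route_instance`.
#' @param reference a feasible `route_solution`, normally
#'   `greedy_construct(instance)` (the bootstrap pure-time pass).
#' @return list with `time_norm` (hours) and `risk_norm`.
#' @export
compute_normalizers <- function(instance, reference) {
  tot <- solution_totals(reference)
  list(time_norm = if (tot$transit_hours > 0) tot$transit_hours else 1,
       risk_norm = if (tot$risk > 0) tot$risk else 1)
}

#' Weighted, normalized objective of a solution
#'
#' The scalar the optimizer minimizes:
#' `weight_time * (total transit hours / time_norm) +
#'  weight_risk * (total risk / risk_norm)`.
#' At `weight_time = 10` the score depends only on transit time; at 0 only
#' on risk from unreliable roads and vehicles.
#'
#' @param solution a `route_solution`.
#' @param weights from [objective_weights()].
#' @param norms from [compute_normalizers()].
#' @return numeric score.
#' @export
weighted_objective <- function(solution, weights, norms) {
  tot <- solution_totals(solution)
  weights$weight_time * tot$transit_hours / norms$time_norm +
    weights$weight_risk * tot$risk / norms$risk_norm
}
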