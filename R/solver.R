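#' Solver configuration
#'
#' @param time_budget_seconds positive number of seconds the anytime
#'   search may run (default 120; the construction itself takes well under
#'   a second, the rest of the budget improves the incumbent). `Inf`
#'   removes the budget.
#' @param branching_width how many of the best facility-index extensions
#'   to branch on at each node (default 3), or `"all"`. `"all"` together
#'   with an unlimited budget makes the search exact: the returned score
#'   is a certified optimum under the evenness constraint.
#' @param seed integer, recorded for provenance; the solver itself is
#'   deterministic and uses no randomness (seeds matter only for the
#'   instance generator).
#' @return a `solver_config` list.
#' @export
solver_config <- function(time_budget_seconds = 120, branching_width = 3,
                          seed = 0) {
  if (!identical(branching_width, "all")) {
    branching_width <- as.integer(branching_width)
    if (is.na(branching_width) || branching_width < 1) {
      stop("branching_width must be a positive integer or \"all\"")
    }
  }
  if (!is.numeric(time_budget_seconds) || time_budget_seconds <= 0) {
    stop("time_budget_seconds must be positive")
  }
  structure(list(time_budget_seconds = time_budget_seconds,
                 branching_width = branching_width,
                 seed = as.integer(seed)),
            class = "solver_config")
}

infeasible_stop <- function(msg) {
  stop(errorCondition(msg, class = c("coldroute_infeasible", "error")))
}

# Static vehicle priority order: total capacity descending, condition
# Good < Fair < Poor, name ascending. Route counts (the first component of
# the vehicle index) are dynamic and handled by the search itself.
available_vehicles <- function(instance) {
  vh <- instance$vehicles[instance$vehicles$available %in% TRUE, , drop = FALSE]
  ord <- order(-(vh$cold_capacity + vh$ambient_capacity),
               match(vh$condition, VEHICLE_CONDITIONS),
               as.character(vh$vehicle))
  vh[ord, , drop = FALSE]
}

# Precompute everything the search core needs: node ordering (depot first,
# then the visit set in declaration order), leg time/risk/accessibility
# matrices, per-facility aggregated volumes, the vehicle table in static
# priority order, shortest-path return times/risks to the depot over the
# accessible graph, and obvious-infeasibility prechecks.
prep_core <- function(instance, profile = default_road_profile()) {
  p <- instance$parameters
  vs <- visit_set(instance)
  nodes <- c(p$depot_name, vs)
  n <- length(vs)
  d <- instance$network$distance[nodes, nodes, drop = FALSE]
  rc <- instance$network$road_class[nodes, nodes, drop = FALSE]
  acc <- !is.na(rc) & rc != "Not accessible"
  diag(acc) <- FALSE

  spd <- matrix(NA_real_, n + 1, n + 1)
  rr <- matrix(0, n + 1, n + 1)
  ok <- which(acc, arr.ind = TRUE)
  if (nrow(ok)) {
    spd[ok] <- profile$speed[rc[ok]]
    rr[ok] <- profile$road_risk[rc[ok]]
  }
  tim <- ifelse(acc, d / spd, Inf)
  tim[is.na(tim)] <- Inf
  diag(tim) <- 0
  riskBase <- d * rr

  loads <- lapply(nodes, function(f) aggregate_demand(instance, f))
  coldVol <- c(0, vapply(loads[-1], `[[`, 0, "cold_volume"))
  ambVol <- c(0, vapply(loads[-1], `[[`, 0, "ambient_volume"))

  vh <- available_vehicles(instance)
  if (!nrow(vh)) infeasible_stop("no available vehicle")
  addend <- profile$vehicle_risk[as.character(vh$condition)]
  minAdd <- min(addend)

  # shortest-path bounds to the depot over the accessible graph
  edges <- which(acc & upper.tri(acc), arr.ind = TRUE)
  spTime <- rep(Inf, n + 1)
  spRiskMin <- rep(Inf, n + 1)
  spTime[1] <- 0; spRiskMin[1] <- 0
  if (nrow(edges)) {
    g <- igraph::make_empty_graph(n = n + 1, directed = FALSE)
    g <- igraph::add_edges(g, rbind(edges[, 1], edges[, 2]))
    wt_time <- tim[edges]
    wt_risk <- riskBase[edges] + d[edges] * minAdd
    spTime <- as.numeric(igraph::distances(g, v = seq_len(n + 1), to = 1,
                                           weights = wt_time))
    spRiskMin <- as.numeric(igraph::distances(g, v = seq_len(n + 1), to = 1,
                                              weights = wt_risk))
  }

  window <- window_hours(instance)
  service <- as.numeric(p$service_hours_per_stop)

  # obvious infeasibility: a facility no route can ever serve
  if (n > 0) {
    for (j in 2:(n + 1)) {
      if (!any(acc[, j])) {
        infeasible_stop(paste0("facility '", nodes[j],
                               "' has no accessible road at all"))
      }
      if (is.infinite(spTime[j])) {
        infeasible_stop(paste0("facility '", nodes[j],
                               "' cannot reach the depot on accessible roads"))
      }
      if (coldVol[j] > max(vh$cold_capacity) + 1e-9 ||
          ambVol[j] > max(vh$ambient_capacity) + 1e-9) {
        infeasible_stop(paste0("demand volume of facility '", nodes[j],
                               "' exceeds every vehicle's capacity"))
      }
      if (2 * spTime[j] + service > window + 1e-9) {
        infeasible_stop(paste0("round trip to facility '", nodes[j],
                               "' cannot fit in the daily window"))
      }
    }
  }

  list(nodes = nodes, n = n, dist = d, tim = tim, riskBase = riskBase,
       acc = acc, coldVol = coldVol, ambVol = ambVol, vehicles = vh,
       addend = as.numeric(addend), minAdd = minAdd,
       spTime = spTime, spRiskMin = spRiskMin,
       window = window, service = service)
}

lb_incoming <- function(prep, wt, wp, tn, rn) {
  n <- prep$n
  lb <- numeric(n + 1)
  for (j in seq_len(n) + 1) {
    from <- which(prep$acc[, j])
    costs <- wt * (prep$tim[from, j] + prep$service) / tn +
      wp * (prep$riskBase[from, j] + prep$dist[from, j] * prep$minAdd) / rn
    lb[j] <- min(costs)
  }
  lb
}

run_core <- function(prep, wt, wp, tn, rn, width, first_leaf, branch_vehicles,
                     budget) {
  acc_int <- matrix(as.integer(prep$acc), nrow(prep$acc))
  tim <- prep$tim
  tim[is.infinite(tim)] <- 1e9  # never used: guarded by the access matrix
  .solve_core(tim, prep$riskBase, prep$dist, acc_int,
              prep$coldVol, prep$ambVol,
              prep$vehicles$cold_capacity, prep$vehicles$ambient_capacity,
              prep$addend, wt, wp, tn, rn, prep$service, prep$window,
              prep$spTime, prep$spRiskMin,
              lb_incoming(prep, wt, wp, tn, rn),
              as.integer(width), first_leaf, branch_vehicles,
              as.numeric(budget))
}

build_solution <- function(instance, prep, core_routes, core_veh, profile,
                           weights, norms) {
  p <- instance$parameters
  start <- parse_clock(p$start_time)
  service <- as.numeric(p$service_hours_per_stop)
  veh_names <- as.character(prep$vehicles$vehicle)
  day_count <- setNames(integer(length(veh_names)), veh_names)
  routes <- vector("list", length(core_routes))
  for (r in seq_along(core_routes)) {
    idx <- core_routes[[r]]
    stops <- prep$nodes[idx + 1]
    vname <- veh_names[core_veh[r]]
    day_count[vname] <- day_count[vname] + 1L
    metrics <- route_metrics(list(vehicle = vname, stops = stops),
                             instance, profile)
    # departure clock: depot at start time, each stop after arrival+service
    dep <- numeric(length(stops) + 1)
    dep[1] <- start
    path <- c(p$depot_name, stops)
    for (k in seq_along(stops)) {
      lm <- leg_metrics(path[k], path[k + 1],
                        prep$vehicles[core_veh[r], ], instance$network, profile)
      dep[k + 1] <- dep[k] + lm$hours + service
    }
    load <- list(
      cold_volume = sum(prep$coldVol[idx + 1]),
      ambient_volume = sum(prep$ambVol[idx + 1]))
    routes[[r]] <- list(vehicle = vname, day = day_count[[vname]],
                        stops = stops, departure_hours = dep,
                        return_hour = start + metrics$transit_hours,
                        metrics = metrics, load = load)
  }
  sol <- structure(list(routes = routes, objective_score = NA_real_,
                        totals = NULL, weights = weights, norms = norms,
                        instance = instance),
                   class = "route_solution")
  sol$totals <- solution_totals(sol)
  if (!is.null(weights) && !is.null(norms)) {
    sol$objective_score <- weighted_objective(sol, weights, norms)
  }
  sol
}

empty_solution <- function(instance, weights = NULL, norms = NULL) {
  sol <- structure(list(routes = list(), objective_score = 0,
                        totals = list(transit_hours = 0, risk = 0,
                                      distance_km = 0, fuel_cost = 0,
                                      per_diem_cost = 0),
                        weights = weights, norms = norms,
                        instance = instance),
                   class = "route_solution")
  sol
}

#' @export
print.route_solution <- function(x, ...) {
  cat("<route_solution>", length(x$routes), "route(s)\n")
  for (r in x$routes) {
    cat(sprintf("  %s (day %d): %s -> %s -> %s  [%.2f h, risk %.1f, %.1f km]\n",
                r$vehicle, r$day, x$instance$parameters$depot_name,
                paste(r$stops, collapse = " -> "),
                x$instance$parameters$depot_name,
                r$metrics$transit_hours, r$metrics$risk,
                r$metrics$distance_km))
  }
  t <- x$totals
  cat(sprintf("  totals: %.2f h transit, risk %.1f, %.1f km, fuel %.2f, per diem %.2f\n",
              t$transit_hours, t$risk, t$distance_km, t$fuel_cost,
              t$per_diem_cost))
  if (!is.na(x$objective_score)) {
    cat(sprintf("  objective score: %.4f\n", x$objective_score))
  }
  invisible(x)
}

#' Greedy route construction with the two-index rule
#'
#' Builds a feasible solution by repeatedly picking the next vehicle with
#' the vehicle index (fewest routes first, then largest capacity, best
#' condition, name) and extending its route with the facility of minimum
#' facility index until no extension is feasible, then closing the route
#' at the depot. If a chosen extension leads to a dead end (a route that
#' can neither continue nor return), the construction backtracks to the
#' next-best index choice, so a feasible solution is found whenever the
#' search space contains one.
#'
#' When `norms` is `NULL` (the bootstrap pass) the index uses raw leg
#' travel time only; the resulting solution is the normalization
#' reference for subsequent weighted runs.
#'
#' @param instance a `route_instance` (validated).
#' @param weights from [objective_weights()], or `NULL` for the bootstrap
#'   pure-time pass.
#' @param norms from [compute_normalizers()], or `NULL` for bootstrap.
#' @param profile a `road_profile`.
#' @return a feasible `route_solution`; throws a condition of class
#'   `coldroute_infeasible` if some facility can never be served.
#' @export
greedy_construct <- function(instance, weights = NULL, norms = NULL,
                             profile = default_road_profile()) {
  if (!length(visit_set(instance))) return(empty_solution(instance, weights, norms))
  prep <- prep_core(instance, profile)
  if (is.null(weights) || is.null(norms)) {
    res <- run_core(prep, 1, 0, 1, 1, width = 0L, first_leaf = TRUE,
                    branch_vehicles = FALSE, budget = 0)
    weights <- NULL; norms <- NULL
  } else {
    res <- run_core(prep, weights$weight_time, weights$weight_risk,
                    norms$time_norm, norms$risk_norm, width = 0L,
                    first_leaf = TRUE, branch_vehicles = FALSE, budget = 0)
  }
  if (!res$found) {
    infeasible_stop("no feasible set of routes serves every facility with demand")
  }
  build_solution(instance, prep, res$routes, res$route_vehicle, profile,
                 weights, norms)
}

#' Solve a routing instance
#'
#' The main entry point: validates the instance, computes normalization
#' constants from the pure-time greedy reference, constructs a greedy
#' incumbent with the two-index rule, and improves it with an anytime
#' depth-first branch-and-bound until the time budget expires. Branching
#' follows the `branching_width` best facility-index extensions plus the
#' "close route" alternative; nodes are pruned when the partial score plus
#' an admissible lower bound (cheapest accessible entering leg per
#' unvisited facility, shortest-path return of the open route) cannot beat
#' the incumbent. With `branching_width = "all"` and an unlimited budget
#' the search is exhaustive and the result a certified optimum under the
#' even-vehicle-use constraint.
#'
#' @param instance a `route_instance`.
#' @param config a [solver_config()]; `NULL` uses the instance's
#'   `time_budget_seconds` parameter with the default width.
#' @param weights objective weights; `NULL` uses the instance's
#'   `weight_time` parameter.
#' @param profile a `road_profile`.
#' @return a `route_solution` with attributes `greedy_score` (score of the
#'   initial incumbent), `exhausted` (`TRUE` when the search completed
#'   before the budget, certifying optimality for width `"all"`), and
#'   `nodes` (search nodes expanded). Throws `coldroute_validation_error`
#'   on blocking input errors and `coldroute_infeasible` when no feasible
#'   solution exists.
#' @export
solve_routes <- function(instance, config = NULL, weights = NULL,
                         profile = default_road_profile()) {
  report <- validate_instance(instance)
  if (nrow(report$errors)) {
    cond <- errorCondition(
      paste0("instance has ", nrow(report$errors), " blocking error(s); ",
             "see validate_instance()"),
      report = report,
      class = c("coldroute_validation_error", "error"))
    stop(cond)
  }
  if (is.null(config)) {
    config <- solver_config(
      time_budget_seconds = as.numeric(instance$parameters$time_budget_seconds))
  }
  if (is.null(weights)) {
    weights <- objective_weights(instance$parameters$weight_time)
  }
  if (!length(visit_set(instance))) {
    return(empty_solution(instance, weights, NULL))
  }

  prep <- prep_core(instance, profile)

  # bootstrap: pure-time greedy reference fixes the normalizers
  boot <- run_core(prep, 1, 0, 1, 1, width = 0L, first_leaf = TRUE,
                   branch_vehicles = FALSE, budget = 0)
  if (!boot$found) {
    infeasible_stop("no feasible set of routes serves every facility with demand")
  }
  reference <- build_solution(instance, prep, boot$routes, boot$route_vehicle,
                              profile, NULL, NULL)
  norms <- compute_normalizers(instance, reference)

  exhaustive <- identical(config$branching_width, "all")
  width <- if (exhaustive) 0L else as.integer(config$branching_width)
  budget <- if (is.infinite(config$time_budget_seconds)) 0 else
    config$time_budget_seconds

  res <- run_core(prep, weights$weight_time, weights$weight_risk,
                  norms$time_norm, norms$risk_norm, width = width,
                  first_leaf = FALSE, branch_vehicles = exhaustive,
                  budget = budget)
  if (!res$found) {
    # budget expired before the first leaf: fall back to the greedy pass
    res <- run_core(prep, weights$weight_time, weights$weight_risk,
                    norms$time_norm, norms$risk_norm, width = width,
                    first_leaf = TRUE, branch_vehicles = FALSE, budget = 0)
    if (!res$found) {
      infeasible_stop("no feasible set of routes serves every facility with demand")
    }
  }
  sol <- build_solution(instance, prep, res$routes, res$route_vehicle, profile,
                        weights, norms)
  attr(sol, "greedy_score") <- res$first_score
  attr(sol, "exhausted") <- isTRUE(res$exhausted)
  attr(sol, "nodes") <- res$nodes
  sol
}

#' Facility index of a candidate extension
#'
#' The priority score used during construction: the normalized marginal
#' objective of the leg from the route's current facility to the
#' candidate, `weight_time * dt/time_norm + weight_risk * drisk/risk_norm`
#' (with `dt` including the per-stop service time). Recalculated every
#' time a facility is added. Returns `Inf` ("infeasible") when the leg is
#' not accessible, the candidate's aggregated load overflows the remaining
#' vehicle capacity, or the elapsed time plus the leg, service, and the
#' shortest accessible return to the depot would exceed the daily window.
#'
#' @param instance a `route_instance`.
#' @param state list describing the open route: `vehicle` (name),
#'   `current` (facility name, the depot when the route is empty),
#'   `elapsed_hours`, `remaining_cold`, `remaining_ambient` (liters).
#' @param candidate an unvisited facility name.
#' @param weights,norms objective weights and normalizers.
#' @param profile a `road_profile`.
#' @return numeric score; `Inf` when infeasible.
#' @export
facility_index <- function(instance, state, candidate, weights, norms,
                           profile = default_road_profile()) {
  prep <- prep_core(instance, profile)
  i <- match(state$current, prep$nodes)
  j <- match(candidate, prep$nodes)
  if (is.na(i) || is.na(j)) stop("unknown facility in state or candidate")
  if (!prep$acc[i, j]) return(Inf)
  if (prep$coldVol[j] > state$remaining_cold + 1e-9 ||
      prep$ambVol[j] > state$remaining_ambient + 1e-9) return(Inf)
  if (state$elapsed_hours + prep$tim[i, j] + prep$service + prep$spTime[j] >
      prep$window + 1e-9) return(Inf)
  veh <- instance$vehicles[instance$vehicles$vehicle == state$vehicle, ]
  addend <- profile$vehicle_risk[[as.character(veh$condition)]]
  drisk <- prep$riskBase[i, j] + prep$dist[i, j] * addend
  weights$weight_time * (prep$tim[i, j] + prep$service) / norms$time_norm +
    weights$weight_risk * drisk / norms$risk_norm
}

#' Vehicle index: which vehicle opens the next route
#'
#' Ranks the available vehicles by the lexicographic key (routes already
#' assigned ascending, total capacity descending, condition Good < Fair <
#' Poor, name ascending); the first row gets the next route. Assigning
#' each new route to a vehicle currently holding the fewest routes keeps
#' the fleet's route counts within one of each other at all times, which
#' is how even vehicle use is enforced.
#'
#' @param instance a `route_instance`.
#' @param counts named integer vector of routes already assigned per
#'   available vehicle (missing names count as 0).
#' @return data.frame of available vehicles in rank order with the key
#'   columns `routes_assigned`, `total_capacity`, `condition`, `vehicle`.
#' @export
vehicle_index <- function(instance, counts = NULL) {
  vh <- available_vehicles(instance)
  routes_assigned <- rep(0L, nrow(vh))
  if (!is.null(counts)) {
    hit <- match(as.character(vh$vehicle), names(counts))
    routes_assigned[!is.na(hit)] <- as.integer(counts[hit[!is.na(hit)]])
  }
  key <- data.frame(vehicle = as.character(vh$vehicle),
                    routes_assigned = routes_assigned,
                    total_capacity = vh$cold_capacity + vh$ambient_capacity,
                    condition = as.character(vh$condition),
                    stringsAsFactors = FALSE)
  key[order(key$routes_assigned, -key$total_capacity,
            match(key$condition, VEHICLE_CONDITIONS), key$vehicle), ,
      drop = FALSE]
}

violation_row <- function(code, route, message) {
  data.frame(code = code, route = route, message = message,
             stringsAsFactors = FALSE)
}

#' Check a solution against every routing constraint
#'
#' Independent re-evaluation of the seven constraint families: the daily
#' time window, depot round trips, demand met, exactly-once visits, even
#' vehicle use, per-temperature-class vehicle capacity, and road
#' accessibility. Used to certify solver output and to fuzz-test the
#' solver; it shares no code with the search itself.
#'
#' @param solution a `route_solution`.
#' @param instance the `route_instance` it was solved from.
#' @param profile a `road_profile`.
#' @return data.frame of violations (columns `code`, `route`, `message`);
#'   zero rows iff the solution is feasible.
#' @export
check_feasible <- function(solution, instance,
                           profile = default_road_profile()) {
  v <- list()
  p <- instance$parameters
  window <- window_hours(instance)
  service <- as.numeric(p$service_hours_per_stop)
  vs <- visit_set(instance)
  seen <- character()

  for (ri in seq_along(solution$routes)) {
    r <- solution$routes[[ri]]
    label <- paste0("route ", ri)
    veh <- instance$vehicles[instance$vehicles$vehicle == r$vehicle, ]
    if (nrow(veh) != 1) {
      v[[length(v) + 1]] <- violation_row("NAME_ERROR", label,
                                          paste("unknown vehicle", r$vehicle))
      next
    }
    if (!isTRUE(veh$available)) {
      v[[length(v) + 1]] <- violation_row(
        "VEHICLE_UNAVAILABLE", label,
        paste(r$vehicle, "is marked not available"))
    }
    if (!length(r$stops)) {
      v[[length(v) + 1]] <- violation_row("EMPTY_ROUTE", label,
                                          "route visits no facility")
      next
    }
    if (anyDuplicated(r$stops)) {
      v[[length(v) + 1]] <- violation_row("DUPLICATE_STOP", label,
                                          "a facility appears twice on the route")
    }
    if (p$depot_name %in% r$stops) {
      v[[length(v) + 1]] <- violation_row("DEPOT_IN_STOPS", label,
                                          "the depot cannot be a delivery stop")
    }
    path <- c(p$depot_name, r$stops, p$depot_name)
    hours <- 0; blocked <- FALSE
    cold <- 0; amb <- 0
    for (k in seq_len(length(path) - 1)) {
      cls <- instance$network$road_class[path[k], path[k + 1]]
      if (path[k] == path[k + 1]) next
      if (is.na(cls) || cls == "Not accessible") {
        v[[length(v) + 1]] <- violation_row(
          "FORBIDDEN_LEG", label,
          paste0("leg ", path[k], " -> ", path[k + 1], " is not accessible"))
        blocked <- TRUE
      } else {
        hours <- hours + instance$network$distance[path[k], path[k + 1]] /
          profile$speed[[cls]]
      }
    }
    hours <- hours + service * length(r$stops)
    if (!blocked && hours > window + 1e-9) {
      v[[length(v) + 1]] <- violation_row(
        "WINDOW", label,
        sprintf("route takes %.2f h, window is %.2f h", hours, window))
    }
    for (f in r$stops) {
      if (!f %in% rownames(instance$demand)) {
        v[[length(v) + 1]] <- violation_row("NAME_ERROR", label,
                                            paste("unknown facility", f))
        next
      }
      load <- aggregate_demand(instance, f)
      cold <- cold + load$cold_volume
      amb <- amb + load$ambient_volume
    }
    if (cold > veh$cold_capacity + 1e-9) {
      v[[length(v) + 1]] <- violation_row(
        "CAPACITY_COLD", label,
        sprintf("cold load %.1f L exceeds capacity %.1f L", cold,
                veh$cold_capacity))
    }
    if (amb > veh$ambient_capacity + 1e-9) {
      v[[length(v) + 1]] <- violation_row(
        "CAPACITY_AMBIENT", label,
        sprintf("ambient load %.1f L exceeds capacity %.1f L", amb,
                veh$ambient_capacity))
    }
    seen <- c(seen, r$stops)
  }

  dup <- unique(seen[duplicated(seen)])
  for (f in dup) {
    v[[length(v) + 1]] <- violation_row(
      "MULTIPLE_VISITS", "solution",
      paste(f, "is visited by more than one route"))
  }
  for (f in setdiff(vs, seen)) {
    v[[length(v) + 1]] <- violation_row(
      "DEMAND_NOT_MET", "solution",
      paste(f, "has demand but is not visited"))
  }
  for (f in setdiff(unique(seen), vs)) {
    v[[length(v) + 1]] <- violation_row(
      "UNEXPECTED_VISIT", "solution",
      paste(f, "is visited but has no demand (or is the depot)"))
  }

  av <- available_vehicles(instance)
  counts <- setNames(rep(0L, nrow(av)), as.character(av$vehicle))
  for (r in solution$routes) {
    if (r$vehicle %in% names(counts)) counts[r$vehicle] <- counts[r$vehicle] + 1L
  }
  if (length(counts) && length(solution$routes) &&
      max(counts) - min(counts) > 1L) {
    v[[length(v) + 1]] <- violation_row(
      "EVENNESS", "solution",
      paste0("route counts per available vehicle differ by more than one (",
             paste(sprintf("%s=%d", names(counts), counts), collapse = ", "),
             ")"))
  }

  if (length(v)) do.call(rbind, v) else
    data.frame(code = character(), route = character(), message = character(),
               stringsAsFactors = FALSE)
}
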