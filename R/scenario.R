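#' Specification of an emergency scenario transform
#'
#' Captures the adjustments a logistician makes when a disaster (cyclone,
#' flood, outbreak) disrupts a distribution plan: relocating the
#' distribution warehouse, zeroing demand at facilities that can no
#' longer store products, scaling up demand where displaced populations
#' concentrate, and marking destroyed roads as not accessible.
#'
#' @param new_depot facility name to become the new start/return
#'   location, or `NULL` to keep the current depot.
#' @param zero_demand character vector of facilities whose demand is set
#'   to zero (they drop out of routing entirely).
#' @param demand_multipliers named numeric vector: each named facility's
#'   demand rows are multiplied by the factor (results rounded half-up to
#'   whole units).
#' @param road_blocks list of length-2 character vectors; each pair's
#'   road is set to "Not accessible" in both directions.
#' @return a `scenario_spec` list.
#' @export
scenario_spec <- function(new_depot = NULL, zero_demand = character(),
                          demand_multipliers = NULL,
                          road_blocks = list()) {
  if (!is.null(demand_multipliers)) {
    stopifnot(is.numeric(demand_multipliers),
              !is.null(names(demand_multipliers)),
              all(demand_multipliers >= 0))
  }
  stopifnot(is.list(road_blocks),
            all(vapply(road_blocks, length, 0L) == 2))
  structure(list(new_depot = new_depot,
                 zero_demand = as.character(zero_demand),
                 demand_multipliers = demand_multipliers,
                 road_blocks = road_blocks),
            class = "scenario_spec")
}

#' Read a scenario from a YAML or JSON file
#'
#' Keys mirror the arguments of [scenario_spec()]: `new_depot`,
#' `zero_demand`, `demand_multipliers` (a mapping facility -> factor),
#' `road_blocks` (a list of two-element facility pairs).
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file.
#' @return a `scenario_spec`.
#' @export
read_scenario <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  blocks <- raw$road_blocks %||% list()
  if (is.matrix(blocks)) blocks <- split(blocks, seq_len(nrow(blocks)))
  blocks <- lapply(blocks, as.character)
  mult <- raw$demand_multipliers
  if (!is.null(mult)) mult <- unlist(mult)
  scenario_spec(new_depot = raw$new_depot,
                zero_demand = raw$zero_demand %||% character(),
                demand_multipliers = mult,
                road_blocks = blocks)
}

#' Apply an emergency scenario to an instance
#'
#' Returns a new instance with the depot replaced, listed demands zeroed,
#' multipliers applied, and listed road pairs set to "Not accessible" in
#' both directions; the original instance is left unmodified. The
#' transform is idempotent: each applied scenario is recorded on the
#' instance and re-applying an identical one is a no-op (otherwise demand
#' multipliers would compound). When a facility appears both in
#' `zero_demand` and `demand_multipliers`, zeroing wins.
#'
#' @param instance a `route_instance`.
#' @param scenario a [scenario_spec()].
#' @return the transformed `route_instance`.
#' @export
apply_emergency <- function(instance, scenario) {
  stopifnot(inherits(scenario, "scenario_spec"))
  fac <- as.character(instance$facilities$facility)
  referenced <- c(scenario$new_depot, scenario$zero_demand,
                  names(scenario$demand_multipliers),
                  unlist(scenario$road_blocks))
  unknown <- setdiff(referenced, fac)
  if (length(unknown)) {
    stop(errorCondition(
      paste("scenario references undeclared facilities:",
            paste(unknown, collapse = ", ")),
      class = c("coldroute_name_error", "error")))
  }
  applied <- attr(instance, "applied_scenarios") %||% list()
  if (any(vapply(applied, identical, logical(1), y = scenario))) {
    return(instance)
  }
  out <- instance
  attr(out, "applied_scenarios") <- c(applied, list(scenario))
  if (!is.null(scenario$new_depot)) {
    out$parameters$depot_name <- scenario$new_depot
  }
  for (f in names(scenario$demand_multipliers)) {
    if (f %in% scenario$zero_demand) next
    out$demand[f, ] <- floor(out$demand[f, ] *
                               scenario$demand_multipliers[[f]] + 0.5)
  }
  if (length(scenario$zero_demand)) {
    out$demand[scenario$zero_demand, ] <- 0
  }
  for (pair in scenario$road_blocks) {
    out$network$road_class[pair[1], pair[2]] <- "Not accessible"
    out$network$road_class[pair[2], pair[1]] <- "Not accessible"
  }
  out
}
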