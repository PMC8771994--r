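#' Assemble a routing problem instance
#'
#' Builds the in-memory representation of one single-day distribution
#' problem: global parameters, product catalogue, facilities with storage
#' capacities, a facility-by-product demand table, the vehicle fleet, and
#' the road network (distance and road-condition matrices). The constructor
#' checks structure (column names, matrix dimensions); semantic
#' consistency is checked separately by [validate_instance()], which never
#' throws, so that imperfect workbooks can still be inspected.
#'
#' @param parameters named list with `depot_name`, `start_time` and
#'   `return_time` (24-h `HH:MM`), `weight_time` (integer 0-10; the weight
#'   on risk is always `10 - weight_time`), and optionally
#'   `time_budget_seconds` (default 120), `service_hours_per_stop`
#'   (default 0), `fuel_price` (currency per liter, default 1) and
#'   `per_diem_rate` (currency per crew member per route-day, default 0).
#' @param products data.frame with columns `product`, `requires_cold`
#'   (logical), `unit_volume` (liters per unit).
#' @param facilities data.frame with columns `facility`, `cold_capacity`,
#'   `ambient_capacity` (liters).
#' @param demand numeric matrix of units, rows named by facility, columns
#'   by product.
#' @param vehicles data.frame with columns `vehicle`, `available`
#'   (logical), `condition` (`Good`/`Fair`/`Poor`), `cold_capacity`,
#'   `ambient_capacity` (liters), `fuel_consumption` (liters per km),
#'   `crew_size`.
#' @param network list with `distance` (km) and `road_class` matrices,
#'   both square with facility dimnames.
#' @return an object of class `route_instance`.
#' @seealso [read_instance()] to build an instance from a workbook,
#'   [validate_instance()], [solve_routes()].
#' @export
make_instance <- function(parameters, products, facilities, demand,
                          vehicles, network) {
  defaults <- list(time_budget_seconds = 120, service_hours_per_stop = 0,
                   fuel_price = 1, per_diem_rate = 0)
  for (k in names(defaults)) {
    parameters[[k]] <- parameters[[k]] %||% defaults[[k]]
  }
  need <- c("depot_name", "start_time", "return_time", "weight_time")
  miss <- setdiff(need, names(parameters))
  if (length(miss)) stop("parameters missing: ", paste(miss, collapse = ", "))
  stopifnot(
    is.data.frame(products),
    all(c("product", "requires_cold", "unit_volume") %in% names(products)),
    is.data.frame(facilities),
    all(c("facility", "cold_capacity", "ambient_capacity") %in% names(facilities)),
    is.data.frame(vehicles),
    all(c("vehicle", "available", "condition", "cold_capacity",
          "ambient_capacity", "fuel_consumption", "crew_size") %in% names(vehicles)),
    is.list(network), all(c("distance", "road_class") %in% names(network))
  )
  demand <- as.matrix(demand)
  storage.mode(demand) <- "double"
  structure(list(
    parameters = parameters,
    products = products,
    facilities = facilities,
    demand = demand,
    vehicles = vehicles,
    network = network
  ), class = "route_instance")
}

#' @export
print.route_instance <- function(x, ...) {
  cat("<route_instance>\n")
  cat("  depot:     ", x$parameters$depot_name, "\n")
  cat("  window:    ", x$parameters$start_time, "-", x$parameters$return_time, "\n")
  cat("  facilities:", nrow(x$facilities),
      " products:", nrow(x$products),
      " vehicles:", nrow(x$vehicles),
      "(", sum(x$vehicles$available), "available )\n")
  cat("  visit set: ", length(visit_set(x)), "facilities with demand\n")
  invisible(x)
}

window_hours <- function(instance) {
  parse_clock(instance$parameters$return_time) -
    parse_clock(instance$parameters$start_time)
}

report_row <- function(code, location, message) {
  data.frame(code = code, location = location, message = message,
             stringsAsFactors = FALSE)
}

empty_report_df <- function() {
  data.frame(code = character(), location = character(), message = character(),
             stringsAsFactors = FALSE)
}

#' Validate a routing instance
#'
#' Performs every semantic check on an assembled instance and returns a
#' report instead of throwing, so that all problems are surfaced at once
#' with their sheet/cell locations. Blocking *errors* (blank matrix cells,
#' unresolved names, an objective weight outside 0-10, a daily window
#' longer than 24 h, asymmetric matrices, no available vehicle, ...) make
#' the instance unsolvable. Facility storage capacity is deliberately not
#' a constraint: when a facility's aggregated demand volume exceeds its
#' cold or ambient storage capacity a *warning* (`STORAGE_EXCEEDED`) is
#' emitted, and optimization can still proceed -- in practice facilities
#' find ways to store products beyond the designated space.
#'
#' @param instance a `route_instance`.
#' @return an object of class `validation_report`: list with `errors` and
#'   `warnings` data frames (columns `code`, `location`, `message`).
#' @export
validate_instance <- function(instance) {
  errs <- list()
  warns <- list()
  p <- instance$parameters
  fac_names <- as.character(instance$facilities$facility)
  prod_names <- as.character(instance$products$product)

  if (anyDuplicated(fac_names)) {
    errs[[length(errs) + 1]] <- report_row(
      "DUPLICATE_NAME", "center_capacities",
      paste("duplicated facility:",
            paste(unique(fac_names[duplicated(fac_names)]), collapse = ", ")))
  }
  if (anyDuplicated(prod_names)) {
    errs[[length(errs) + 1]] <- report_row(
      "DUPLICATE_NAME", "products",
      paste("duplicated product:",
            paste(unique(prod_names[duplicated(prod_names)]), collapse = ", ")))
  }
  if (!p$depot_name %in% fac_names) {
    errs[[length(errs) + 1]] <- report_row(
      "NAME_ERROR", "parameters!depot",
      paste0("depot '", p$depot_name, "' is not a declared facility"))
  }
  wt <- suppressWarnings(as.numeric(p$weight_time))
  if (is.na(wt) || wt < 0 || wt > 10 || wt != round(wt)) {
    errs[[length(errs) + 1]] <- report_row(
      "WEIGHT_OUT_OF_RANGE", "parameters!weight_time",
      "weight for transit time must be an integer between 0 and 10")
  }
  st <- parse_clock(p$start_time); rt <- parse_clock(p$return_time)
  if (is.na(st)) {
    errs[[length(errs) + 1]] <- report_row("BAD_TIME", "parameters!start_time",
                                           "start time must be HH:MM (24-h)")
  }
  if (is.na(rt)) {
    errs[[length(errs) + 1]] <- report_row("BAD_TIME", "parameters!return_time",
                                           "return time must be HH:MM (24-h)")
  }
  if (!is.na(st) && !is.na(rt)) {
    if (rt <= st) {
      errs[[length(errs) + 1]] <- report_row(
        "WINDOW_INVALID", "parameters",
        "return time must be after start time")
    } else if (rt - st > 24) {
      errs[[length(errs) + 1]] <- report_row(
        "WINDOW_TOO_LONG", "parameters",
        "routes must be completable within a 24-hour period")
    }
  }
  for (k in c("time_budget_seconds", "fuel_price")) {
    v <- suppressWarnings(as.numeric(p[[k]]))
    if (is.na(v) || v <= 0) {
      errs[[length(errs) + 1]] <- report_row(
        "BAD_VALUE", paste0("parameters!", k), paste(k, "must be positive"))
    }
  }
  for (k in c("service_hours_per_stop", "per_diem_rate")) {
    v <- suppressWarnings(as.numeric(p[[k]]))
    if (is.na(v) || v < 0) {
      errs[[length(errs) + 1]] <- report_row(
        "BAD_VALUE", paste0("parameters!", k), paste(k, "must be non-negative"))
    }
  }

  # products
  pr <- instance$products
  bad_vol <- which(is.na(pr$unit_volume) | pr$unit_volume <= 0)
  for (i in bad_vol) {
    errs[[length(errs) + 1]] <- report_row(
      "BAD_VALUE", paste0("products!", pr$product[i]),
      "unit volume must be a positive number of liters")
  }
  for (i in which(is.na(pr$requires_cold))) {
    errs[[length(errs) + 1]] <- report_row(
      "BLANK_CELL", paste0("products!", pr$product[i]),
      "cold-storage flag must be yes or no")
  }

  # facilities
  fc <- instance$facilities
  for (i in which(is.na(fc$cold_capacity) | fc$cold_capacity < 0)) {
    errs[[length(errs) + 1]] <- report_row(
      "BAD_VALUE", paste0("center_capacities!", fc$facility[i]),
      "cold storage capacity must be non-negative liters")
  }
  for (i in which(is.na(fc$ambient_capacity) | fc$ambient_capacity < 0)) {
    errs[[length(errs) + 1]] <- report_row(
      "BAD_VALUE", paste0("center_capacities!", fc$facility[i]),
      "ambient storage capacity must be non-negative liters")
  }

  # demand table: indexed only by declared names, no blank cells
  dm <- instance$demand
  unknown_f <- setdiff(rownames(dm), fac_names)
  unknown_p <- setdiff(colnames(dm), prod_names)
  for (f in unknown_f) {
    errs[[length(errs) + 1]] <- report_row(
      "NAME_ERROR", paste0("demand!", f), "facility not declared in center_capacities")
  }
  for (pp in unknown_p) {
    errs[[length(errs) + 1]] <- report_row(
      "NAME_ERROR", paste0("demand!", pp), "product not declared in products")
  }
  missing_f <- setdiff(fac_names, rownames(dm))
  missing_p <- setdiff(prod_names, colnames(dm))
  for (f in missing_f) {
    errs[[length(errs) + 1]] <- report_row(
      "BLANK_CELL", paste0("demand!", f), "facility row missing from demand sheet")
  }
  for (pp in missing_p) {
    errs[[length(errs) + 1]] <- report_row(
      "BLANK_CELL", paste0("demand!", pp), "product column missing from demand sheet")
  }
  known <- dm[intersect(rownames(dm), fac_names),
              intersect(colnames(dm), prod_names), drop = FALSE]
  nas <- which(is.na(known), arr.ind = TRUE)
  if (nrow(nas)) {
    for (i in seq_len(nrow(nas))) {
      errs[[length(errs) + 1]] <- report_row(
        "BLANK_CELL",
        paste0("demand!", rownames(known)[nas[i, 1]], "×",
               colnames(known)[nas[i, 2]]),
        "blank demand cell: enter 0 explicitly if nothing is requested")
    }
  }
  negs <- which(!is.na(known) & (known < 0 | known != round(known)), arr.ind = TRUE)
  if (nrow(negs)) {
    for (i in seq_len(nrow(negs))) {
      errs[[length(errs) + 1]] <- report_row(
        "BAD_VALUE",
        paste0("demand!", rownames(known)[negs[i, 1]], "×",
               colnames(known)[negs[i, 2]]),
        "demand must be a non-negative whole number of units")
    }
  }

  # vehicles
  vh <- instance$vehicles
  if (anyDuplicated(vh$vehicle)) {
    errs[[length(errs) + 1]] <- report_row(
      "DUPLICATE_NAME", "vehicle",
      paste("duplicated vehicle:",
            paste(unique(vh$vehicle[duplicated(vh$vehicle)]), collapse = ", ")))
  }
  for (i in which(!vh$condition %in% VEHICLE_CONDITIONS)) {
    errs[[length(errs) + 1]] <- report_row(
      "VOCAB_ERROR", paste0("vehicle!", vh$vehicle[i]),
      "condition must be Good, Fair or Poor")
  }
  for (i in which(is.na(vh$available))) {
    errs[[length(errs) + 1]] <- report_row(
      "VOCAB_ERROR", paste0("vehicle!", vh$vehicle[i]),
      "availability must be 'available' or 'not available'")
  }
  for (i in which(is.na(vh$cold_capacity) | vh$cold_capacity < 0 |
                  is.na(vh$ambient_capacity) | vh$ambient_capacity < 0)) {
    errs[[length(errs) + 1]] <- report_row(
      "BAD_VALUE", paste0("vehicle!", vh$vehicle[i]),
      "transport capacities must be non-negative liters")
  }
  for (i in which(is.na(vh$fuel_consumption) | vh$fuel_consumption <= 0)) {
    errs[[length(errs) + 1]] <- report_row(
      "BAD_VALUE", paste0("vehicle!", vh$vehicle[i]),
      "fuel consumption must be positive liters per km")
  }
  for (i in which(is.na(vh$crew_size) | vh$crew_size < 1 |
                  vh$crew_size != round(vh$crew_size))) {
    errs[[length(errs) + 1]] <- report_row(
      "BAD_VALUE", paste0("vehicle!", vh$vehicle[i]),
      "crew size must be a positive whole number")
  }
  if (!any(vh$available %in% TRUE)) {
    errs[[length(errs) + 1]] <- report_row(
      "NO_VEHICLE", "vehicle", "at least one vehicle must be available")
  }

  # network matrices
  errs <- c(errs, check_matrix(instance$network$distance, "distance_data",
                               fac_names, numeric_matrix = TRUE))
  errs <- c(errs, check_matrix(instance$network$road_class, "road_condition",
                               fac_names, numeric_matrix = FALSE))

  # storage-capacity warnings (never blocking)
  if (!length(errs)) {
    for (f in fac_names) {
      load <- aggregate_demand(instance, f)
      caps <- fc[fc$facility == f, ]
      if (load$cold_volume > caps$cold_capacity + 1e-9) {
        warns[[length(warns) + 1]] <- report_row(
          "STORAGE_EXCEEDED", paste0("demand!", f),
          sprintf("cold demand volume %.1f L exceeds cold storage capacity %.1f L",
                  load$cold_volume, caps$cold_capacity))
      }
      if (load$ambient_volume > caps$ambient_capacity + 1e-9) {
        warns[[length(warns) + 1]] <- report_row(
          "STORAGE_EXCEEDED", paste0("demand!", f),
          sprintf("ambient demand volume %.1f L exceeds ambient storage capacity %.1f L",
                  load$ambient_volume, caps$ambient_capacity))
      }
    }
  }

  structure(list(
    errors = if (length(errs)) do.call(rbind, errs) else empty_report_df(),
    warnings = if (length(warns)) do.call(rbind, warns) else empty_report_df()
  ), class = "validation_report")
}

check_matrix <- function(m, sheet, fac_names, numeric_matrix) {
  errs <- list()
  if (is.null(dim(m)) || is.null(rownames(m)) || is.null(colnames(m))) {
    return(list(report_row("SCHEMA_ERROR", sheet,
                           "matrix must carry facility row and column names")))
  }
  unknown <- setdiff(union(rownames(m), colnames(m)), fac_names)
  for (f in unknown) {
    errs[[length(errs) + 1]] <- report_row(
      "NAME_ERROR", paste0(sheet, "!", f), "facility not declared in center_capacities")
  }
  missing <- union(setdiff(fac_names, rownames(m)), setdiff(fac_names, colnames(m)))
  for (f in missing) {
    errs[[length(errs) + 1]] <- report_row(
      "BLANK_CELL", paste0(sheet, "!", f), "facility missing from matrix")
  }
  common <- intersect(intersect(rownames(m), colnames(m)), fac_names)
  mm <- m[common, common, drop = FALSE]
  nas <- which(is.na(mm), arr.ind = TRUE)
  if (nrow(nas)) {
    for (i in seq_len(min(nrow(nas), 50))) {
      errs[[length(errs) + 1]] <- report_row(
        "BLANK_CELL",
        paste0(sheet, "!", common[nas[i, 1]], "×", common[nas[i, 2]]),
        "no cell may be left empty")
    }
  }
  if (numeric_matrix) {
    if (any(diag(mm) != 0, na.rm = TRUE)) {
      errs[[length(errs) + 1]] <- report_row(
        "BAD_VALUE", sheet, "distances on the diagonal must be zero")
    }
    if (any(mm < 0, na.rm = TRUE)) {
      errs[[length(errs) + 1]] <- report_row(
        "BAD_VALUE", sheet, "distances must be non-negative km")
    }
    asym <- abs(mm - t(mm)) > 1e-6
  } else {
    bad <- which(!is.na(mm) & !mm %in% ROAD_CLASSES, arr.ind = TRUE)
    if (nrow(bad)) {
      for (i in seq_len(min(nrow(bad), 50))) {
        errs[[length(errs) + 1]] <- report_row(
          "VOCAB_ERROR",
          paste0(sheet, "!", common[bad[i, 1]], "×", common[bad[i, 2]]),
          paste("road condition must be one of:", paste(ROAD_CLASSES, collapse = ", ")))
      }
    }
    asym <- !is.na(mm) & !is.na(t(mm)) & mm != t(mm)
  }
  if (any(asym, na.rm = TRUE)) {
    errs[[length(errs) + 1]] <- report_row(
      "ASYMMETRIC", sheet, "matrix must be symmetric")
  }
  errs
}

#' @export
print.validation_report <- function(x, ...) {
  cat("<validation_report>", nrow(x$errors), "error(s),",
      nrow(x$warnings), "warning(s)\n")
  if (nrow(x$errors)) {
    cat("errors:\n")
    for (i in seq_len(nrow(x$errors))) {
      cat(sprintf("  [%s] %s: %s\n", x$errors$code[i], x$errors$location[i],
                  x$errors$message[i]))
    }
  }
  if (nrow(x$warnings)) {
    cat("warnings:\n")
    for (i in seq_len(nrow(x$warnings))) {
      cat(sprintf("  [%s] %s: %s\n", x$warnings$code[i], x$warnings$location[i],
                  x$warnings$message[i]))
    }
  }
  invisible(x)
}

#' Aggregate a facility's demand into cold and ambient volumes
#'
#' Computation is streamlined by collapsing the product catalogue into two
#' temperature categories: products that require cold storage and products
#' kept at ambient temperature. The aggregated liters per facility are
#' what the optimizer loads against vehicle capacities; the named products
#' are disaggregated again when the solution workbook is written.
#'
#' @param instance a `route_instance`.
#' @param facility a declared facility name.
#' @return an `aggregated_load`: list with `cold_volume` and
#'   `ambient_volume` in liters.
#' @export
aggregate_demand <- function(instance, facility) {
  if (!facility %in% rownames(instance$demand)) {
    stop("unknown facility: ", facility)
  }
  prods <- instance$products
  qty <- instance$demand[facility, as.character(prods$product)]
  qty[is.na(qty)] <- 0
  vols <- qty * prods$unit_volume
  structure(list(
    cold_volume = sum(vols[prods$requires_cold %in% TRUE]),
    ambient_volume = sum(vols[prods$requires_cold %in% FALSE])
  ), class = "aggregated_load")
}

#' Facilities that must be visited
#'
#' The visit set contains exactly the non-depot facilities whose total
#' demand volume is positive. Setting a facility's demand to zero (as in
#' emergency workflows where a facility cannot store products) removes it
#' from routing entirely; the depot is always excluded because every route
#' starts and ends there and its stock is on site.
#'
#' @param instance a `route_instance`.
#' @return character vector of facility names, in declaration order.
#' @export
visit_set <- function(instance) {
  fac <- as.character(instance$facilities$facility)
  fac <- setdiff(fac, instance$parameters$depot_name)
  keep <- vapply(fac, function(f) {
    load <- aggregate_demand(instance, f)
    load$cold_volume + load$ambient_volume > 0
  }, logical(1))
  fac[keep]
}

#' Accessible legs of the road network
#'
#' A leg (unordered facility pair) is usable by a route if its road
#' condition is anything but "Not accessible". The solver only ever
#' travels on accessible legs; a blocked road is simply never used and
#' deliveries are re-sequenced around it.
#'
#' @param instance a `route_instance`.
#' @return data.frame with columns `from` and `to` (one row per unordered
#'   pair, `from` before `to` in declaration order).
#' @export
accessible_legs <- function(instance) {
  fac <- as.character(instance$facilities$facility)
  rc <- instance$network$road_class[fac, fac, drop = FALSE]
  out <- list()
  n <- length(fac)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j <= i) next
      cls <- rc[i, j]
      if (!is.na(cls) && cls != "Not accessible") {
        out[[length(out) + 1]] <- data.frame(from = fac[i], to = fac[j],
                                             stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(from = character(), to = character(), stringsAsFactors = FALSE)
}

#' Objective weights from the transit-time weight
#'
#' The user enters a single integer weight for transit time between 0 and
#' 10; the weight for spoilage risk is always derived as its complement,
#' never entered. With the built-in normalization, weights of 5 and 5
#' give equal importance to both objectives; 10 optimizes transit time
#' only and 0 optimizes risk only.
#'
#' @param weight_time integer between 0 and 10.
#' @return list with `weight_time` and `weight_risk` (`= 10 - weight_time`).
#' @export
objective_weights <- function(weight_time) {
  weight_time <- as.numeric(weight_time)
  if (is.na(weight_time) || weight_time < 0 || weight_time > 10 ||
      weight_time != round(weight_time)) {
    stop("weight_time must be an integer between 0 and 10")
  }
  list(weight_time = weight_time, weight_risk = 10 - weight_time)
}
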