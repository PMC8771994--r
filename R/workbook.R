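# The seven input sheets and the two output sheets.
#
# Input workbook (XLSX, or a CSV bundle: one <sheet>.csv per sheet in a
# directory; sheet names are matched case-insensitively):
#   parameters         parameter,value rows (depot, start_time, return_time,
#                      weight_time, time_budget_seconds,
#                      service_hours_per_stop, fuel_price, per_diem_rate)
#   products           product, requires_cold (yes/no), unit_volume
#   center_capacities  facility, cold_capacity, ambient_capacity
#   demand             facility, one column per declared product
#   vehicle            vehicle, available, condition, cold_capacity,
#                      ambient_capacity, fuel_consumption, crew_size
#   distance_data      symmetric km matrix, facility row/column headers
#   road_condition     symmetric road-class matrix, same layout
#
# Facility and product names are declared once (center_capacities,
# products) and every other sheet is resolved against those declarations.
SHEET_NAMES <- c("parameters", "products", "center_capacities", "demand",
                 "vehicle", "distance_data", "road_condition")

read_error <- function(code, location, message) {
  stop(errorCondition(
    paste0("[", code, "] ", location, ": ", message),
    code = code, location = location,
    class = c(paste0("coldroute_", tolower(sub("_ERROR", "", code)), "_error"),
              "coldroute_read_error", "error")))
}

# read every sheet as character cells, from either dialect
read_sheets <- function(path, dialect = c("auto", "xlsx", "csv")) {
  dialect <- match.arg(dialect)
  if (dialect == "auto") {
    dialect <- if (dir.exists(path)) "csv" else "xlsx"
  }
  if (dialect == "csv") {
    if (!dir.exists(path)) read_error("SCHEMA_ERROR", path,
                                      "CSV bundle directory not found")
    files <- list.files(path, pattern = "\\.csv$", full.names = TRUE)
    sheets <- setNames(lapply(files, function(f) {
      read.csv(f, colClasses = "character", check.names = FALSE,
               fileEncoding = "UTF-8")
    }), tolower(sub("\\.csv$", "", basename(files))))
  } else {
    if (!file.exists(path)) read_error("SCHEMA_ERROR", path, "file not found")
    names_raw <- readxl::excel_sheets(path)
    sheets <- setNames(lapply(names_raw, function(s) {
      as.data.frame(suppressMessages(
        readxl::read_excel(path, sheet = s, col_types = "text")),
        check.names = FALSE, stringsAsFactors = FALSE)
    }), tolower(names_raw))
  }
  missing <- setdiff(SHEET_NAMES, names(sheets))
  if (length(missing)) {
    read_error("SCHEMA_ERROR", missing[1],
               paste("required sheet missing:", missing[1]))
  }
  sheets[SHEET_NAMES]
}

num_or_na <- function(x) suppressWarnings(as.numeric(x))

blank_to_na <- function(x) {
  x <- trimws(as.character(x))
  x[x == ""] <- NA_character_
  x
}

need_cols <- function(df, cols, sheet) {
  names(df) <- tolower(trimws(names(df)))
  miss <- setdiff(cols, names(df))
  if (length(miss)) {
    read_error("SCHEMA_ERROR", sheet,
               paste("missing column(s):", paste(miss, collapse = ", ")))
  }
  df
}

match_vocab <- function(x, vocab, sheet, rows) {
  out <- rep(NA_character_, length(x))
  x <- blank_to_na(x)
  hit <- match(tolower(x), tolower(vocab))
  bad <- which(!is.na(x) & is.na(hit))
  if (length(bad)) {
    read_error("VOCAB_ERROR", paste0(sheet, "!", rows[bad[1]]),
               paste0("'", x[bad[1]], "' is not one of: ",
                      paste(vocab, collapse = ", ")))
  }
  out[!is.na(hit)] <- vocab[hit[!is.na(hit)]]
  out
}

parse_matrix_sheet <- function(df, sheet, fac_names) {
  names(df)[1] <- "facility"
  rows <- blank_to_na(df$facility)
  cols <- names(df)[-1]
  for (f in c(rows, cols)) {
    if (!is.na(f) && !f %in% fac_names) {
      read_error("NAME_ERROR", paste0(sheet, "!", f),
                 "facility not declared in center_capacities")
    }
  }
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- rows
  m
}

#' Read an input workbook into a routing instance
#'
#' Reads the seven input sheets (`parameters`, `products`,
#' `center_capacities`, `demand`, `vehicle`, `distance_data`,
#' `road_condition`) from an XLSX workbook or a CSV bundle (a directory
#' with one CSV per sheet) and assembles a [make_instance()] object.
#' Facility and product names are taken only from their declaration
#' sheets; every other sheet is resolved against them. Schema problems
#' (missing sheet or column), controlled-vocabulary violations (road
#' classes, yes/no, availability, condition) and unresolvable names throw
#' classed errors with the offending sheet/cell; blank cells are kept as
#' `NA` so [validate_instance()] can report all of them at once. The
#' distance and road-condition matrices must be symmetric, which is
#' enforced here at read time.
#'
#' @param path path to an `.xlsx` file or a CSV-bundle directory.
#' @param dialect `"auto"` (directory means CSV), `"xlsx"` or `"csv"`.
#' @return a `route_instance`.
#' @export
read_instance <- function(path, dialect = c("auto", "xlsx", "csv")) {
  sheets <- read_sheets(path, dialect)

  pm <- need_cols(sheets$parameters, c("parameter", "value"), "parameters")
  keys <- tolower(trimws(pm$parameter))
  vals <- blank_to_na(pm$value)
  getp <- function(key, default = NULL) {
    i <- match(key, keys)
    if (is.na(i) || is.na(vals[i])) default else vals[i]
  }
  for (key in c("depot", "start_time", "return_time", "weight_time")) {
    if (is.null(getp(key))) {
      read_error("SCHEMA_ERROR", "parameters",
                 paste("missing required parameter:", key))
    }
  }
  parameters <- list(
    depot_name = getp("depot"),
    start_time = getp("start_time"),
    return_time = getp("return_time"),
    weight_time = num_or_na(getp("weight_time")),
    time_budget_seconds = num_or_na(getp("time_budget_seconds", "120")),
    service_hours_per_stop = num_or_na(getp("service_hours_per_stop", "0")),
    fuel_price = num_or_na(getp("fuel_price", "1")),
    per_diem_rate = num_or_na(getp("per_diem_rate", "0")))

  pr <- need_cols(sheets$products,
                  c("product", "requires_cold", "unit_volume"), "products")
  prod_names <- blank_to_na(pr$product)
  products <- data.frame(
    product = prod_names,
    requires_cold = match_vocab(pr$requires_cold, c("yes", "no"),
                                "products", prod_names) == "yes",
    unit_volume = num_or_na(blank_to_na(pr$unit_volume)),
    stringsAsFactors = FALSE)

  cc <- need_cols(sheets$center_capacities,
                  c("facility", "cold_capacity", "ambient_capacity"),
                  "center_capacities")
  fac_names <- blank_to_na(cc$facility)
  facilities <- data.frame(
    facility = fac_names,
    cold_capacity = num_or_na(blank_to_na(cc$cold_capacity)),
    ambient_capacity = num_or_na(blank_to_na(cc$ambient_capacity)),
    stringsAsFactors = FALSE)

  dm <- sheets$demand
  if (!ncol(dm) || tolower(trimws(names(dm)[1])) != "facility") {
    read_error("SCHEMA_ERROR", "demand",
               "first column must be 'facility'; remaining columns are products")
  }
  names(dm)[1] <- "facility"
  dem_rows <- blank_to_na(dm$facility)
  for (f in dem_rows) {
    if (!is.na(f) && !f %in% fac_names) {
      read_error("NAME_ERROR", paste0("demand!", f),
                 "facility not declared in center_capacities")
    }
  }
  for (pp in names(dm)[-1]) {
    if (!pp %in% prod_names) {
      read_error("NAME_ERROR", paste0("demand!", pp),
                 "product not declared in products")
    }
  }
  demand <- as.matrix(dm[, -1, drop = FALSE])
  demand <- apply(demand, 2, function(col) num_or_na(blank_to_na(col)))
  if (is.null(dim(demand))) demand <- matrix(demand, nrow = nrow(dm))
  dimnames(demand) <- list(dem_rows, names(dm)[-1])

  vh <- need_cols(sheets$vehicle,
                  c("vehicle", "available", "condition", "cold_capacity",
                    "ambient_capacity", "fuel_consumption", "crew_size"),
                  "vehicle")
  veh_names <- blank_to_na(vh$vehicle)
  vehicles <- data.frame(
    vehicle = veh_names,
    available = match_vocab(vh$available, c("available", "not available"),
                            "vehicle", veh_names) == "available",
    condition = match_vocab(vh$condition, VEHICLE_CONDITIONS,
                            "vehicle", veh_names),
    cold_capacity = num_or_na(blank_to_na(vh$cold_capacity)),
    ambient_capacity = num_or_na(blank_to_na(vh$ambient_capacity)),
    fuel_consumption = num_or_na(blank_to_na(vh$fuel_consumption)),
    crew_size = num_or_na(blank_to_na(vh$crew_size)),
    stringsAsFactors = FALSE)

  dd_raw <- parse_matrix_sheet(sheets$distance_data, "distance_data", fac_names)
  dd <- apply(dd_raw, 2, function(col) num_or_na(blank_to_na(col)))
  if (is.null(dim(dd))) dd <- matrix(dd, nrow = nrow(dd_raw))
  dimnames(dd) <- dimnames(dd_raw)

  rc_raw <- parse_matrix_sheet(sheets$road_condition, "road_condition",
                               fac_names)
  rc <- rc_raw
  for (j in seq_len(ncol(rc_raw))) {
    rc[, j] <- match_vocab(rc_raw[, j], ROAD_CLASSES, "road_condition",
                           paste0(rownames(rc_raw), "×", colnames(rc_raw)[j]))
  }

  # symmetry is a structural property of the sheets: enforce on read
  common <- intersect(rownames(dd), colnames(dd))
  if (length(common)) {
    dsub <- dd[common, common, drop = FALSE]
    if (any(abs(dsub - t(dsub)) > 1e-6, na.rm = TRUE)) {
      read_error("ASYMMETRIC", "distance_data",
                 "distance matrix must be symmetric")
    }
    rsub <- rc[common, common, drop = FALSE]
    mism <- !is.na(rsub) & !is.na(t(rsub)) & rsub != t(rsub)
    if (any(mism)) {
      read_error("ASYMMETRIC", "road_condition",
                 "road condition matrix must be symmetric")
    }
  }

  make_instance(parameters, products, facilities, demand, vehicles,
                list(distance = dd, road_class = rc))
}

write_sheet <- function(df, dir, sheet) {
  write.csv(df, file.path(dir, paste0(sheet, ".csv")), row.names = FALSE,
            fileEncoding = "UTF-8")
}

#' Write an instance as a CSV-bundle input workbook
#'
#' Writes the seven input sheets to `<path>/<sheet>.csv` so generated or
#' transformed instances flow through the same reader as user data.
#' Writing is deterministic: the same instance always produces
#' byte-identical files.
#'
#' @param instance a `route_instance`.
#' @param path directory to create/write into.
#' @return `path`, invisibly.
#' @export
write_instance <- function(instance, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  p <- instance$parameters
  write_sheet(data.frame(
    parameter = c("depot", "start_time", "return_time", "weight_time",
                  "time_budget_seconds", "service_hours_per_stop",
                  "fuel_price", "per_diem_rate"),
    value = as.character(c(p$depot_name, p$start_time, p$return_time,
                           p$weight_time, p$time_budget_seconds,
                           p$service_hours_per_stop, p$fuel_price,
                           p$per_diem_rate)),
    stringsAsFactors = FALSE), path, "parameters")
  pr <- instance$products
  write_sheet(data.frame(
    product = pr$product,
    requires_cold = ifelse(pr$requires_cold, "yes", "no"),
    unit_volume = as.character(pr$unit_volume),
    stringsAsFactors = FALSE), path, "products")
  write_sheet(instance$facilities, path, "center_capacities")
  dm <- data.frame(facility = rownames(instance$demand),
                   instance$demand, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_sheet(dm, path, "demand")
  vh <- instance$vehicles
  write_sheet(data.frame(
    vehicle = vh$vehicle,
    available = ifelse(vh$available, "available", "not available"),
    condition = vh$condition,
    cold_capacity = vh$cold_capacity,
    ambient_capacity = vh$ambient_capacity,
    fuel_consumption = vh$fuel_consumption,
    crew_size = vh$crew_size,
    stringsAsFactors = FALSE), path, "vehicle")
  dd <- data.frame(facility = rownames(instance$network$distance),
                   instance$network$distance, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_sheet(dd, path, "distance_data")
  rc <- data.frame(facility = rownames(instance$network$road_class),
                   instance$network$road_class, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_sheet(rc, path, "road_condition")
  invisible(path)
}

#' Write a solution workbook
#'
#' Writes the two output sheets as a CSV bundle. `Routes.csv` holds one
#' row per stop per route -- including the depot departure row and the
#' final return row -- with the vehicle, route and day numbers, the
#' departure clock time (24-h, whole minutes), the cold and ambient
#' utilization of the vehicle's capacity (the maximum over the route's
#' legs, as a percentage), and the route's fuel and per-diem costs.
#' `Health products.csv` disaggregates the two optimization categories
#' back into named products: the quantity of each product delivered to
#' each facility by each vehicle and route.
#'
#' @param solution a `route_solution` from [solve_routes()] or
#'   [greedy_construct()].
#' @param path directory to create/write into.
#' @return `path`, invisibly.
#' @export
write_solution <- function(solution, path) {
  instance <- solution$instance
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  p <- instance$parameters

  route_rows <- list()
  product_rows <- list()
  for (ri in seq_along(solution$routes)) {
    r <- solution$routes[[ri]]
    veh <- instance$vehicles[instance$vehicles$vehicle == r$vehicle, ]
    # onboard volume decreases along the route; utilization is its maximum
    # over the legs, i.e. the full load on the first leg
    cold_remaining <- r$load$cold_volume
    amb_remaining <- r$load$ambient_volume
    cold_util <- 0; amb_util <- 0
    for (f in r$stops) {
      if (veh$cold_capacity > 0) {
        cold_util <- max(cold_util, cold_remaining / veh$cold_capacity)
      }
      if (veh$ambient_capacity > 0) {
        amb_util <- max(amb_util, amb_remaining / veh$ambient_capacity)
      }
      load <- aggregate_demand(instance, f)
      cold_remaining <- cold_remaining - load$cold_volume
      amb_remaining <- amb_remaining - load$ambient_volume
    }
    stops <- c(p$depot_name, r$stops, p$depot_name)
    times <- format_clock(c(r$departure_hours, r$return_hour))
    route_rows[[ri]] <- data.frame(
      vehicle = r$vehicle, route = ri, day = r$day, stop = stops,
      departure_time = times,
      cold_utilization_pct = round(100 * cold_util, 1),
      ambient_utilization_pct = round(100 * amb_util, 1),
      fuel_cost = round(r$metrics$fuel_cost, 2),
      per_diem_cost = round(r$metrics$per_diem_cost, 2),
      stringsAsFactors = FALSE)

    for (f in r$stops) {
      qty <- instance$demand[f, ]
      pos <- which(!is.na(qty) & qty > 0)
      if (length(pos)) {
        product_rows[[length(product_rows) + 1]] <- data.frame(
          vehicle = r$vehicle, route = ri, day = r$day, facility = f,
          product = colnames(instance$demand)[pos],
          quantity = as.numeric(qty[pos]),
          stringsAsFactors = FALSE)
      }
    }
  }

  empty_routes <- data.frame(
    vehicle = character(), route = integer(), day = integer(),
    stop = character(), departure_time = character(),
    cold_utilization_pct = numeric(), ambient_utilization_pct = numeric(),
    fuel_cost = numeric(), per_diem_cost = numeric(),
    stringsAsFactors = FALSE)
  empty_products <- data.frame(
    vehicle = character(), route = integer(), day = integer(),
    facility = character(), product = character(), quantity = numeric(),
    stringsAsFactors = FALSE)

  write_sheet(if (length(route_rows)) do.call(rbind, route_rows)
              else empty_routes, path, "Routes")
  write_sheet(if (length(product_rows)) do.call(rbind, product_rows)
              else empty_products, path, "Health products")
  invisible(path)
}
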