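test_that("the CSV bundle reader populates every field of the bundled instance", {
  inst <- cyclone_instance()
  expect_s3_class(inst, "route_instance")
  expect_identical(inst$parameters$depot_name, "Province A")
  expect_identical(inst$parameters$start_time, "08:00")
  expect_equal(inst$parameters$weight_time, 5)
  expect_identical(nrow(inst$facilities), 8L)
  expect_identical(nrow(inst$products), 4L)
  expect_type(inst$products$requires_cold, "logical")
  expect_type(inst$vehicles$available, "logical")
  expect_true(all(inst$vehicles$condition %in% c("Good", "Fair", "Poor")))
  expect_equal(inst$network$distance["Province A", "Center B"],
               inst$network$distance["Center B", "Province A"])
  expect_identical(nrow(validate_instance(inst)$errors), 0L)
})

test_that("write-then-read is a fixed point of the reader", {
  inst <- cyclone_instance()
  dir <- file.path(tempdir(), "roundtrip")
  write_instance(inst, dir)
  back <- read_instance(dir)
  expect_equal(back$parameters, inst$parameters)
  expect_equal(back$products, inst$products)
  expect_equal(back$facilities, inst$facilities)
  expect_equal(back$demand, inst$demand)
  expect_equal(back$vehicles, inst$vehicles)
  expect_equal(back$network$distance, inst$network$distance)
  expect_identical(back$network$road_class, inst$network$road_class)

  # writing twice is byte-identical
  dir2 <- file.path(tempdir(), "roundtrip2")
  write_instance(back, dir2)
  for (f in list.files(dir)) {
    expect_identical(readBin(file.path(dir, f), "raw", 1e6),
                     readBin(file.path(dir2, f), "raw", 1e6))
  }
  unlink(c(dir, dir2), recursive = TRUE)
})

test_that("the XLSX dialect reads identically to the CSV bundle", {
  xlsx <- file.path(tempdir(), "cyclone.xlsx")
  script <- paste(
    "import sys, csv, pathlib, openpyxl",
    "src, dst = sys.argv[1], sys.argv[2]",
    "wb = openpyxl.Workbook()",
    "wb.remove(wb.active)",
    "names = ['parameters','products','center_capacities','demand',",
    "         'vehicle','distance_data','road_condition']",
    "for name in names:",
    "    ws = wb.create_sheet(name)",
    "    with open(pathlib.Path(src) / (name + '.csv'), newline='',",
    "              encoding='utf-8') as fh:",
    "        for row in csv.reader(fh):",
    "            ws.append(row)",
    "wb.save(dst)",
    sep = "\n")
  status <- system2("python", c("-c", shQuote(script), shQuote(cyclone_path()),
                                shQuote(xlsx)))
  expect_identical(status, 0L)
  from_xlsx <- read_instance(xlsx, dialect = "xlsx")
  from_csv <- cyclone_instance()
  expect_equal(from_xlsx$parameters, from_csv$parameters)
  expect_equal(from_xlsx$demand, from_csv$demand)
  expect_equal(from_xlsx$network$distance, from_csv$network$distance)
  expect_identical(from_xlsx$network$road_class, from_csv$network$road_class)
  expect_equal(from_xlsx$vehicles, from_csv$vehicles)
  unlink(xlsx)
})

test_that("schema, vocabulary, name and symmetry defects throw located errors", {
  src <- cyclone_path()
  corrupt <- function(edit) {
    dir <- file.path(tempdir(), "corrupt")
    unlink(dir, recursive = TRUE)
    dir.create(dir)
    file.copy(list.files(src, full.names = TRUE), dir)
    edit(dir)
    dir
  }

  d <- corrupt(function(dir) unlink(file.path(dir, "vehicle.csv")))
  expect_error(read_instance(d), class = "coldroute_schema_error")

  d <- corrupt(function(dir) {
    rc <- read.csv(file.path(dir, "road_condition.csv"), check.names = FALSE,
                   colClasses = "character")
    rc[2, 3] <- "Muddy"; rc[3, 2] <- "Muddy"
    write.csv(rc, file.path(dir, "road_condition.csv"), row.names = FALSE)
  })
  err <- tryCatch(read_instance(d), error = function(e) e)
  expect_s3_class(err, "coldroute_vocab_error")
  expect_match(conditionMessage(err), "road_condition!")

  d <- corrupt(function(dir) {
    dm <- read.csv(file.path(dir, "demand.csv"), check.names = FALSE,
                   colClasses = "character")
    names(dm)[2] <- "Unknown product"
    write.csv(dm, file.path(dir, "demand.csv"), row.names = FALSE)
  })
  expect_error(read_instance(d), class = "coldroute_name_error")

  d <- corrupt(function(dir) {
    dd <- read.csv(file.path(dir, "distance_data.csv"), check.names = FALSE,
                   colClasses = "character")
    dd[2, 4] <- "999"  # one direction of Center B <-> Center C only
    write.csv(dd, file.path(dir, "distance_data.csv"), row.names = FALSE)
  })
  expect_error(read_instance(d), class = "coldroute_asymmetric_error")

  # blank cells do not throw: they become validation errors with locations
  d <- corrupt(function(dir) {
    dm <- read.csv(file.path(dir, "demand.csv"), check.names = FALSE,
                   colClasses = "character")
    dm[3, 2] <- ""
    write.csv(dm, file.path(dir, "demand.csv"), row.names = FALSE)
  })
  inst <- read_instance(d)
  rep <- validate_instance(inst)
  expect_true("BLANK_CELL" %in% rep$errors$code)
})

test_that("the solution workbook carries schedules, utilization and exact quantities", {
  inst <- apply_emergency(cyclone_instance(), cyclone_scenario())
  sol <- solve_routes(inst, solver_config(3, 3))
  dir <- file.path(tempdir(), "solution_out")
  write_solution(sol, dir)
  routes <- read.csv(file.path(dir, "Routes.csv"), check.names = FALSE)
  hp <- read.csv(file.path(dir, "Health products.csv"), check.names = FALSE)

  # the first row of the first route departs the new depot at the start time
  expect_identical(routes$stop[1], "Center B")
  expect_identical(routes$departure_time[1], "08:00")
  # every printed time lies inside the daily window
  mins <- vapply(strsplit(routes$departure_time, ":"), function(p)
    as.numeric(p[1]) * 60 + as.numeric(p[2]), 0)
  expect_true(all(mins >= 8 * 60 & mins <= 18 * 60))
  # routes start and end at the depot
  for (ri in unique(routes$route)) {
    rows <- routes[routes$route == ri, ]
    expect_identical(rows$stop[1], "Center B")
    expect_identical(rows$stop[nrow(rows)], "Center B")
  }
  expect_true(all(routes$cold_utilization_pct <= 100 + 1e-9))
  expect_true(all(routes$ambient_utilization_pct <= 100 + 1e-9))

  # per-facility product quantities re-sum exactly to the demand table
  for (f in visit_set(inst)) {
    for (p in colnames(inst$demand)) {
      got <- sum(hp$quantity[hp$facility == f & hp$product == p])
      expect_equal(got, as.numeric(inst$demand[f, p]))
    }
  }
  # disaggregation inverse: per-route re-aggregation equals the load the
  # capacity check used
  prods <- inst$products
  for (ri in seq_along(sol$routes)) {
    sub <- hp[hp$route == ri, ]
    vol <- sub$quantity * prods$unit_volume[match(sub$product, prods$product)]
    cold <- sum(vol[prods$requires_cold[match(sub$product, prods$product)]])
    expect_equal(cold, sol$routes[[ri]]$load$cold_volume, tolerance = 1e-9)
  }
  unlink(dir, recursive = TRUE)

  # an empty visit set writes header-only sheets
  none <- cyclone_instance()
  none$demand[, ] <- 0
  esol <- solve_routes(none, solver_config(2, 3))
  edir <- file.path(tempdir(), "empty_out")
  write_solution(esol, edir)
  eroutes <- read.csv(file.path(edir, "Routes.csv"), check.names = FALSE)
  expect_identical(nrow(eroutes), 0L)
  expect_identical(names(eroutes)[1:5],
                   c("vehicle", "route", "day", "stop", "departure_time"))
  unlink(edir, recursive = TRUE)
})
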