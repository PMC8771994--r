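test_that("facility index equals independent recomputation and flags infeasibility", {
  inst <- generate_instance(generator_spec(seed = 3, n_facilities = 6))
  w <- objective_weights(5)
  ref <- greedy_construct(inst)
  norms <- compute_normalizers(inst, ref)
  veh <- inst$vehicles[1, ]
  prof <- default_road_profile()
  svc <- as.numeric(inst$parameters$service_hours_per_stop)
  state <- list(vehicle = veh$vehicle, current = "Warehouse",
                elapsed_hours = 0,
                remaining_cold = veh$cold_capacity,
                remaining_ambient = veh$ambient_capacity)
  cands <- head(visit_set(inst), 5)
  for (f in cands) {
    idx <- facility_index(inst, state, f, w, norms)
    lm <- leg_metrics("Warehouse", f, veh, inst$network, prof)
    want <- w$weight_time * (lm$hours + svc) / norms$time_norm +
      w$weight_risk * lm$risk / norms$risk_norm
    expect_equal(idx, want, tolerance = 1e-9)
  }

  # degenerate weights 10/0: index ordering equals leg travel time ordering
  w10 <- objective_weights(10)
  idx10 <- vapply(cands, function(f)
    facility_index(inst, state, f, w10, norms), 0)
  times <- vapply(cands, function(f)
    leg_metrics("Warehouse", f, veh, inst$network, prof)$hours, 0)
  expect_identical(order(idx10), order(times))

  # over remaining cold capacity -> infeasible
  tight <- state
  tight$remaining_cold <- 0.01
  heavy <- cands[which.max(vapply(cands, function(f)
    aggregate_demand(inst, f)$cold_volume, 0))]
  expect_identical(facility_index(inst, tight, heavy, w, norms), Inf)

  # no window slack left -> infeasible
  late <- state
  late$elapsed_hours <- 9.99
  expect_identical(facility_index(inst, late, cands[1], w, norms), Inf)
})

test_that("vehicle index enforces even use with deterministic tie-breaks", {
  inst <- generate_instance(generator_spec(seed = 5, n_facilities = 6,
                                           n_vehicles = 2))
  vehs <- as.character(inst$vehicles$vehicle)
  ranked <- vehicle_index(inst, setNames(c(1L, 0L), vehs))
  expect_identical(ranked$vehicle[1], vehs[2])  # 0 routes ranks first

  # identical vehicles: name breaks the tie
  twin <- inst
  twin$vehicles <- rbind(inst$vehicles[1, ], inst$vehicles[1, ])
  twin$vehicles$vehicle <- c("Twin B", "Twin A")
  ranked <- vehicle_index(twin)
  expect_identical(ranked$vehicle, c("Twin A", "Twin B"))

  # more routes than vehicles: counts stay within one of each other
  # ({2,1}, never {3,0})
  small <- generate_instance(generator_spec(seed = 8, n_facilities = 9,
                                            n_vehicles = 2))
  # shrink vehicle capacity so several routes are needed
  vols <- vapply(visit_set(small), function(f) {
    l <- aggregate_demand(small, f); l$cold_volume
  }, 0)
  small$vehicles$cold_capacity <- rep(ceiling(max(vols) * 1.1), 2)
  sol <- solve_routes(small, solver_config(3, 3))
  counts <- table(factor(vapply(sol$routes, function(r) r$vehicle, ""),
                         levels = as.character(small$vehicles$vehicle)))
  expect_gte(length(sol$routes), 3)
  expect_lte(max(counts) - min(counts), 1)
})

test_that("greedy construction is feasible; impossible loads are infeasible", {
  # single facility: the only feasible tour, departing at start time
  single <- tiny_instance()
  single$demand["Center B", ] <- 0
  sol <- greedy_construct(single, objective_weights(5),
                          list(time_norm = 1, risk_norm = 1))
  expect_length(sol$routes, 1)
  expect_identical(sol$routes[[1]]$stops, "Center A")
  expect_equal(sol$routes[[1]]$departure_hours[1], parse_clock("08:00"))

  # cold demand above every vehicle's cold capacity
  heavy <- tiny_instance(demand_a = c(200, 5))  # 400 L cold vs 100 L cap
  expect_error(greedy_construct(heavy), class = "coldroute_infeasible")

  # random instances always pass the independent feasibility checker
  for (seed in 1:10) {
    gi <- generate_instance(generator_spec(seed = 100 + seed,
                                           n_facilities = 5,
                                           n_vehicles = 1 + seed %% 2))
    g <- greedy_construct(gi, objective_weights(5),
                          compute_normalizers(gi, greedy_construct(gi)))
    expect_identical(nrow(check_feasible(g, gi)), 0L)
  }
})

test_that("exhaustive search equals the exact oracle and never loses to greedy", {
  for (seed in 1:20) {
    inst <- generate_instance(generator_spec(seed = 400 + seed,
                                             n_facilities = 3 + seed %% 3,
                                             n_vehicles = 1 + seed %% 2))
    w <- objective_weights(c(0, 3, 5, 7, 10)[(seed %% 5) + 1])
    norms <- compute_normalizers(inst, greedy_construct(inst))
    sol <- solve_routes(inst, solver_config(Inf, "all"), weights = w)
    orc <- enumerate_optimal(inst, w, norms)
    expect_equal(sol$objective_score, orc$score, tolerance = 1e-8)
    expect_lte(sol$objective_score, attr(sol, "greedy_score") + 1e-9)
    expect_true(attr(sol, "exhausted"))
  }
})

test_that("identical instance and config give identical solutions", {
  inst <- generate_instance(generator_spec(seed = 77, n_facilities = 10,
                                           n_vehicles = 2))
  a <- solve_routes(inst, solver_config(5, 3))
  b <- solve_routes(inst, solver_config(5, 3))
  expect_identical(lapply(a$routes, `[[`, "stops"),
                   lapply(b$routes, `[[`, "stops"))
  expect_identical(vapply(a$routes, `[[`, "", "vehicle"),
                   vapply(b$routes, `[[`, "", "vehicle"))
  expect_identical(a$objective_score, b$objective_score)
})

test_that("solutions never traverse blocked legs", {
  inst <- apply_emergency(cyclone_instance(), cyclone_scenario())
  sol <- solve_routes(inst, solver_config(3, 3))
  for (r in sol$routes) {
    path <- c("Center B", r$stops, "Center B")
    for (k in seq_len(length(path) - 1)) {
      expect_false(setequal(path[k:(k + 1)], c("Center B", "Center E")))
    }
  }
  # fuzz: random extra blocks never appear on a route
  for (seed in 1:10) {
    gi <- generate_instance(generator_spec(seed = 600 + seed,
                                           n_facilities = 8,
                                           block_probability = 0.15))
    gsol <- solve_routes(gi, solver_config(3, 3))
    for (r in gsol$routes) {
      path <- c("Warehouse", r$stops, "Warehouse")
      for (k in seq_len(length(path) - 1)) {
        expect_true(gi$network$road_class[path[k], path[k + 1]] !=
                      "Not accessible")
      }
    }
  }
})

test_that("the feasibility checker agrees with independent per-constraint evaluation", {
  inst <- tiny_instance()
  sol <- solve_routes(inst, solver_config(2, 3))
  expect_identical(nrow(check_feasible(sol, inst)), 0L)

  # hand-built route exceeding the window
  narrow <- tiny_instance()
  narrow$parameters$return_time <- "09:30"  # window 1.5 h
  bad <- sol
  bad$instance <- narrow
  # Depot->A->B->Depot on partially paved roads: (40+50+30)/60 = 2 h > 1.5 h
  bad$routes <- list(list(vehicle = "Truck", day = 1,
                          stops = c("Center A", "Center B"),
                          metrics = route_metrics(
                            list(vehicle = "Truck",
                                 stops = c("Center A", "Center B")), narrow),
                          load = list(cold_volume = 30, ambient_volume = 15)))
  v <- check_feasible(bad, narrow)
  expect_true("WINDOW" %in% v$code)

  # random perturbations: the checker flags a violation exactly when the
  # independent evaluator does
  set.seed(42)
  for (seed in 1:8) {
    gi <- generate_instance(generator_spec(seed = 700 + seed,
                                           n_facilities = 6,
                                           n_vehicles = 2))
    base <- solve_routes(gi, solver_config(2, 3))
    for (trial in 1:6) {
      pert <- base
      op <- sample(c("drop", "dup", "swap"), 1)
      ri <- sample(seq_along(pert$routes), 1)
      stops <- pert$routes[[ri]]$stops
      if (op == "drop" && length(stops) > 0) {
        pert$routes[[ri]]$stops <- stops[-1]
      } else if (op == "dup" && length(stops) > 0) {
        pert$routes[[ri]]$stops <- c(stops, stops[1])
      } else if (op == "swap" && length(pert$routes) > 1) {
        rj <- sample(setdiff(seq_along(pert$routes), ri), 1)
        a <- pert$routes[[ri]]$stops
        b <- pert$routes[[rj]]$stops
        if (length(a) && length(b)) {
          pert$routes[[ri]]$stops <- c(a[-1], b[1])
          pert$routes[[rj]]$stops <- c(b[-1], a[1])
        }
      }
      expect_identical(nrow(check_feasible(pert, gi)) > 0L,
                       independent_violates(pert, gi))
    }
  }
})

test_that("anytime search respects its budget and never loses to greedy", {
  inst <- generate_instance(generator_spec(seed = 900, n_facilities = 20,
                                           n_vehicles = 3))
  t0 <- Sys.time()
  sol <- solve_routes(inst, solver_config(time_budget_seconds = 3,
                                          branching_width = 3))
  elapsed <- as.numeric(Sys.time() - t0, units = "secs")
  expect_lt(elapsed, 15)  # budget plus bookkeeping slack
  expect_identical(nrow(check_feasible(sol, inst)), 0L)
  expect_lte(sol$objective_score, attr(sol, "greedy_score") + 1e-9)
})
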