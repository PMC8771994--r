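test_that("leg metrics follow the condition profile", {
  inst <- tiny_instance()
  net <- inst$network
  good <- list(condition = "Good")
  poor <- list(condition = "Poor")

  # 40 km partially paved (60 km/h, factor 1), Good vehicle (addend 0)
  lm <- leg_metrics("Depot", "Center A", good, net)
  expect_equal(lm$hours, 40 / 60, tolerance = 1e-9)
  expect_equal(lm$risk, 40)
  expect_equal(lm$km, 40)

  # self-leg
  lm0 <- leg_metrics("Depot", "Depot", good, net)
  expect_equal(unlist(lm0), c(hours = 0, risk = 0, km = 0))

  # 30 km dirt (rough) (25 km/h, factor 4), Poor vehicle (addend 2)
  net$distance["Center B", "Center C"] <- 30
  net$distance["Center C", "Center B"] <- 30
  net$road_class["Center B", "Center C"] <- "Dirt road (Rough)"
  net$road_class["Center C", "Center B"] <- "Dirt road (Rough)"
  lm <- leg_metrics("Center B", "Center C", poor, net)
  expect_equal(lm$hours, 1.2, tolerance = 1e-9)
  expect_equal(lm$risk, 30 * (4 + 2))
  expect_equal(lm$km, 30)

  net$road_class["Center B", "Center C"] <- "Not accessible"
  expect_error(leg_metrics("Center B", "Center C", good, net),
               class = "coldroute_forbidden_leg")
})

test_that("route metrics sum legs, service time and costs", {
  inst <- tiny_instance()
  inst$network$road_class[, ] <- "Fully paved"  # 80 km/h, zero road risk
  # Depot -> Center A -> Depot: 2 x 40 km at 80 km/h = 1.0 h
  m <- route_metrics(list(vehicle = "Truck", stops = "Center A"), inst)
  expect_equal(m$transit_hours, 1.0, tolerance = 1e-9)
  expect_equal(m$distance_km, 80)
  expect_equal(m$risk, 0)  # paved + Good
  expect_equal(m$fuel_cost, 80 * 0.2 * 1.5)  # 24.0
  expect_equal(m$per_diem_cost, 25 * 2)

  # service time adds per stop
  with_service <- tiny_instance(service = 0.5)
  with_service$network$road_class[, ] <- "Fully paved"
  m2 <- route_metrics(list(vehicle = "Truck", stops = c("Center A", "Center B")),
                      with_service)
  expect_equal(m2$transit_hours, (40 + 50 + 30) / 80 + 2 * 0.5, tolerance = 1e-9)

  # random multi-stop routes equal an independent leg-by-leg summation
  for (seed in 1:5) {
    gi <- generate_instance(generator_spec(seed = seed, n_facilities = 6))
    set.seed(seed)
    stops <- sample(visit_set(gi), 4)
    veh <- gi$vehicles[1, ]
    m <- route_metrics(list(vehicle = veh$vehicle, stops = stops), gi)
    path <- c("Warehouse", stops, "Warehouse")
    hours <- risk <- km <- 0
    prof <- default_road_profile()
    for (k in seq_len(length(path) - 1)) {
      d <- gi$network$distance[path[k], path[k + 1]]
      cls <- gi$network$road_class[path[k], path[k + 1]]
      hours <- hours + d / prof$speed[[cls]]
      risk <- risk + d * (prof$road_risk[[cls]] +
                            prof$vehicle_risk[[veh$condition]])
      km <- km + d
    }
    hours <- hours + 0.25 * length(stops)
    expect_equal(m$transit_hours, hours, tolerance = 1e-9)
    expect_equal(m$risk, risk, tolerance = 1e-9)
    expect_equal(m$distance_km, km, tolerance = 1e-9)
  }
})

test_that("normalizers are the reference totals with a zero guard", {
  fake_solution <- function(transit, risk) {
    structure(list(routes = list(list(metrics = list(
      transit_hours = transit, risk = risk, distance_km = 0,
      fuel_cost = 0, per_diem_cost = 0)))), class = "route_solution")
  }
  inst <- tiny_instance()
  norms <- compute_normalizers(inst, fake_solution(6, 240))
  expect_equal(norms$time_norm, 6)
  expect_equal(norms$risk_norm, 240)
  expect_equal(compute_normalizers(inst, fake_solution(6, 0))$risk_norm, 1)

  # normalization identity: the reference scores exactly 10 at weights 5/5
  ref <- greedy_construct(inst)
  norms <- compute_normalizers(inst, ref)
  expect_equal(weighted_objective(ref, objective_weights(5), norms), 10,
               tolerance = 1e-9)
})

test_that("weighted objective extremes, additivity and scale invariance", {
  inst <- generate_instance(generator_spec(seed = 11, n_facilities = 6))
  ref <- greedy_construct(inst)
  norms <- compute_normalizers(inst, ref)
  sol <- solve_routes(inst, solver_config(2, 3))

  tot <- sol$totals
  expect_equal(weighted_objective(sol, objective_weights(10), norms),
               10 * tot$transit_hours / norms$time_norm, tolerance = 1e-9)
  expect_equal(weighted_objective(sol, objective_weights(0), norms),
               10 * tot$risk / norms$risk_norm, tolerance = 1e-9)

  # additivity: totals are the sum of per-route metrics
  for (k in names(tot)) {
    expect_equal(tot[[k]],
                 sum(vapply(sol$routes, function(r) r$metrics[[k]], 0)),
                 tolerance = 1e-9)
  }

  # scaling all distances by c scales transit/risk/distance/fuel by c and
  # leaves the normalized objective of a fixed (solution, reference) pair
  # unchanged
  scaled <- inst
  scaled$network$distance <- inst$network$distance * 2
  rescale <- function(s, instance) {
    s$routes <- lapply(s$routes, function(r) {
      r$metrics <- route_metrics(list(vehicle = r$vehicle, stops = r$stops),
                                 instance)
      r
    })
    s
  }
  sol2 <- rescale(sol, scaled)
  svc <- as.numeric(inst$parameters$service_hours_per_stop)
  nstops <- sum(lengths(lapply(sol$routes, `[[`, "stops")))
  t1 <- sum(vapply(sol$routes, function(r) r$metrics$transit_hours, 0))
  t2 <- sum(vapply(sol2$routes, function(r) r$metrics$transit_hours, 0))
  expect_equal(t2 - svc * nstops, 2 * (t1 - svc * nstops), tolerance = 1e-9)
  r1 <- sum(vapply(sol$routes, function(r) r$metrics$risk, 0))
  r2 <- sum(vapply(sol2$routes, function(r) r$metrics$risk, 0))
  expect_equal(r2, 2 * r1, tolerance = 1e-9)
  w <- objective_weights(7)
  # without service time the normalized score is exactly scale-free
  no_svc <- inst; no_svc$parameters$service_hours_per_stop <- 0
  no_svc2 <- scaled; no_svc2$parameters$service_hours_per_stop <- 0
  s1 <- rescale(sol, no_svc); f1 <- rescale(ref, no_svc)
  s2 <- rescale(sol, no_svc2); f2 <- rescale(ref, no_svc2)
  expect_equal(
    weighted_objective(s1, w, compute_normalizers(no_svc, f1)),
    weighted_objective(s2, w, compute_normalizers(no_svc2, f2)),
    tolerance = 1e-9)
})
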