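#' Brute-force exact solver for small instances
#'
#' Enumerates every partition of the visit set into routes, every
#' evenness-respecting assignment of routes to available vehicles (route
#' counts differing by at most one, vehicles with zero routes included),
#' and every stop order within a route, discarding orders that violate
#' capacity, the daily window, or road accessibility. Returns the
#' feasible combination minimizing the weighted normalized objective.
#' Intended purely as a correctness oracle for the branch-and-bound
#' solver on small instances; it shares none of the search machinery.
#'
#' @param instance a `route_instance` with at most 8 facilities in the
#'   visit set and at most 3 available vehicles (otherwise a
#'   `coldroute_size_limit` condition is thrown).
#' @param weights from [objective_weights()].
#' @param norms normalizers; `NULL` computes the same pure-time greedy
#'   reference normalizers the solver uses, so scores are directly
#'   comparable.
#' @param profile a `road_profile`.
#' @return list with `solution` (a `route_solution`) and `score`; throws
#'   `coldroute_infeasible` when no feasible solution exists.
#' @export
enumerate_optimal <- function(instance, weights, norms = NULL,
                              profile = default_road_profile()) {
  vs <- visit_set(instance)
  n <- length(vs)
  if (n == 0) {
    sol <- empty_solution(instance, weights, norms)
    return(list(solution = sol, score = 0))
  }
  nveh <- sum(instance$vehicles$available %in% TRUE)
  if (n > 8 || nveh > 3) {
    stop(errorCondition(
      "exact enumeration is limited to 8 visit facilities and 3 vehicles",
      class = c("coldroute_size_limit", "error")))
  }
  if (is.null(norms)) {
    norms <- compute_normalizers(instance, greedy_construct(instance,
                                                            profile = profile))
  }
  prep <- prep_core(instance, profile)
  wt <- weights$weight_time; wp <- weights$weight_risk
  tn <- norms$time_norm; rn <- norms$risk_norm
  m <- nrow(prep$vehicles)

  # best feasible stop order of one block on one vehicle, memoized by
  # (bitmask over local facility ids, vehicle)
  memo <- new.env(parent = emptyenv())
  block_best <- function(ids, v) {
    key <- paste0(sum(2^(ids - 1)), ":", v)
    if (!is.null(memo[[key]])) return(memo[[key]])
    nodes <- ids + 1  # local id k -> prep node index k+1
    if (sum(prep$coldVol[nodes]) > prep$vehicles$cold_capacity[v] + 1e-9 ||
        sum(prep$ambVol[nodes]) > prep$vehicles$ambient_capacity[v] + 1e-9) {
      res <- list(score = Inf, perm = NULL)
      memo[[key]] <- res
      return(res)
    }
    add <- prep$addend[v]
    best <- Inf; best_perm <- NULL
    rec <- function(cur, remaining, elapsed, cost, seq) {
      if (!length(remaining)) {
        if (prep$acc[cur, 1] && elapsed + prep$tim[cur, 1] <= prep$window + 1e-9) {
          total <- cost + wt * prep$tim[cur, 1] / tn +
            wp * (prep$riskBase[cur, 1] + prep$dist[cur, 1] * add) / rn
          if (total < best - 1e-12) {
            best <<- total
            best_perm <<- seq
          }
        }
        return(invisible())
      }
      for (j in remaining) {
        node <- j + 1
        if (!prep$acc[cur, node]) next
        t <- prep$tim[cur, node]
        if (elapsed + t + prep$service + prep$spTime[node] > prep$window + 1e-9) next
        rec(node, setdiff(remaining, j),
            elapsed + t + prep$service,
            cost + wt * (t + prep$service) / tn +
              wp * (prep$riskBase[cur, node] + prep$dist[cur, node] * add) / rn,
            c(seq, j))
      }
    }
    rec(1L, ids, 0, 0, integer(0))
    res <- list(score = best, perm = best_perm)
    memo[[key]] <- res
    res
  }

  # enumerate set partitions of 1..n (blocks as sorted integer vectors)
  partitions <- list()
  build <- function(i, blocks) {
    if (i > n) {
      partitions[[length(partitions) + 1]] <<- blocks
      return(invisible())
    }
    for (b in seq_along(blocks)) {
      nb <- blocks
      nb[[b]] <- c(nb[[b]], i)
      build(i + 1, nb)
    }
    build(i + 1, c(blocks, list(i)))
  }
  build(2L, list(1L))

  best_score <- Inf
  best_plan <- NULL
  for (blocks in partitions) {
    k <- length(blocks)
    assign_rec <- function(b, vehs, cost, plan) {
      if (cost >= best_score - 1e-12) return(invisible())
      if (b > k) {
        counts <- tabulate(vehs, nbins = m)
        if (max(counts) - min(counts) > 1L) return(invisible())
        best_score <<- cost
        best_plan <<- plan
        return(invisible())
      }
      for (v in seq_len(m)) {
        bb <- block_best(blocks[[b]], v)
        if (is.infinite(bb$score)) next
        assign_rec(b + 1, c(vehs, v), cost + bb$score,
                   c(plan, list(list(v = v, perm = bb$perm))))
      }
    }
    assign_rec(1L, integer(0), 0, list())
  }

  if (is.infinite(best_score)) {
    infeasible_stop("no feasible set of routes serves every facility with demand")
  }
  core_routes <- lapply(best_plan, function(pl) pl$perm)
  core_veh <- vapply(best_plan, function(pl) pl$v, 0L)
  sol <- build_solution(instance, prep, core_routes, core_veh, profile,
                        weights, norms)
  list(solution = sol, score = best_score)
}
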