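#include <Rcpp.h>
#include <chrono>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Depth-first search over route constructions.
//
// Nodes are partial solutions: a set of closed routes, optionally one open
// route (vehicle, current facility, elapsed hours, remaining capacities),
// and the set of unvisited facilities.  Moves at a node:
//   * with an open route: extend to each feasible unvisited facility
//     (ordered by the facility index = normalized marginal objective of the
//     leg, ties by facility id), then "close route" (direct accessible leg
//     back to the depot within the window);
//   * without an open route and unvisited facilities left: open a new route
//     on a vehicle currently holding the minimum number of routes (all such
//     vehicles in exhaustive mode, only the first in static priority order
//     otherwise).  Opening only min-count vehicles keeps route counts
//     within one of each other at every point, so evenness holds by
//     construction.
//
// The first leaf reached is exactly the greedy (index-rule) solution; the
// search then continues as branch-and-bound, pruning on partial score plus
// an admissible bound (per-facility cheapest entering leg + shortest-path
// return of the open route).  Facility indices are 1..n, depot is 0.

struct Core {
  int n;                 // number of visit facilities
  int m;                 // number of available vehicles (static priority order)
  NumericMatrix tim, riskBase, dist;
  IntegerMatrix acc;
  NumericVector coldVol, ambVol;              // length n+1, depot 0
  NumericVector vehCold, vehAmb, vehAdd;      // length m
  double wt, wp, tn, rn, service, window;
  NumericVector spTime, spRiskMin, lbIn;      // length n+1
  int width;             // max extensions per node; 0 = all
  bool firstLeafOnly;
  bool branchVehicles;   // branch over all min-count vehicles
  double budgetSec;      // <= 0: none
  std::chrono::steady_clock::time_point t0;

  // state
  std::vector<char> visited;
  int nUnvis;
  double sumLb;          // sum of lbIn over unvisited
  std::vector<int> vehCount;
  std::vector<int> routeVeh;                 // closed routes
  std::vector<std::vector<int>> routeStops;
  bool open;
  int oveh, cur, curStops0;
  double elapsed, remC, remA;
  std::vector<int> curStops;
  double partial;

  // results
  bool haveBest;
  double bestScore;
  std::vector<int> bestVeh;
  std::vector<std::vector<int>> bestStops;
  bool haveFirst;
  double firstScore;
  bool aborted;
  long long nodes;

  double legRisk(int i, int j, int v) const {
    return riskBase(i, j) + dist(i, j) * vehAdd[v];
  }
  double legCost(int i, int j, int v, bool toDepot) const {
    double dt = tim(i, j) + (toDepot ? 0.0 : service);
    return wt * dt / tn + wp * legRisk(i, j, v) / rn;
  }

  bool timeUp() {
    if (budgetSec <= 0) return false;
    std::chrono::duration<double> el = std::chrono::steady_clock::now() - t0;
    return el.count() >= budgetSec;
  }

  void recordLeaf() {
    double sc = partial;
    if (!haveFirst) { haveFirst = true; firstScore = sc; }
    if (!haveBest || sc < bestScore - 1e-12) {
      haveBest = true;
      bestScore = sc;
      bestVeh = routeVeh;
      bestStops = routeStops;
    }
    if (firstLeafOnly) aborted = true;  // stop the whole search
  }

  void dfs() {
    if (aborted) return;
    if (++nodes % 512 == 0 && timeUp() && !firstLeafOnly) { aborted = true; return; }

    // bound
    if (haveBest && !firstLeafOnly) {
      double lb = partial + sumLb;
      if (open) lb += wt * spTime[cur] / tn + wp * spRiskMin[cur] / rn;
      if (lb >= bestScore - 1e-12) return;
    }

    if (open) {
      // candidate extensions
      std::vector<std::pair<double,int>> cand;
      for (int j = 1; j <= n; ++j) {
        if (visited[j]) continue;
        if (!acc(cur, j)) continue;
        if (coldVol[j] > remC + 1e-9 || ambVol[j] > remA + 1e-9) continue;
        double t = tim(cur, j);
        if (elapsed + t + service + spTime[j] > window + 1e-9) continue;
        cand.push_back(std::make_pair(legCost(cur, j, oveh, false), j));
      }
      std::stable_sort(cand.begin(), cand.end());
      int k = (int)cand.size();
      if (width > 0 && k > width) k = width;
      for (int c = 0; c < k; ++c) {
        int j = cand[c].second;
        double cost = cand[c].first;
        // apply
        visited[j] = 1; --nUnvis; sumLb -= lbIn[j];
        int pcur = cur; double pel = elapsed, pC = remC, pA = remA;
        cur = j; elapsed += tim(pcur, j) + service;
        remC -= coldVol[j]; remA -= ambVol[j];
        curStops.push_back(j);
        partial += cost;
        dfs();
        // undo
        partial -= cost;
        curStops.pop_back();
        cur = pcur; elapsed = pel; remC = pC; remA = pA;
        visited[j] = 0; ++nUnvis; sumLb += lbIn[j];
        if (aborted) return;
      }
      // close route
      if ((int)curStops.size() > 0 && acc(cur, 0) &&
          elapsed + tim(cur, 0) <= window + 1e-9) {
        double cost = legCost(cur, 0, oveh, true);
        routeVeh.push_back(oveh);
        routeStops.push_back(curStops);
        std::vector<int> savedStops; savedStops.swap(curStops);
        bool pOpen = open; int pveh = oveh, pcur = cur;
        double pel = elapsed, pC = remC, pA = remA;
        open = false;
        partial += cost;
        dfs();
        partial -= cost;
        open = pOpen; oveh = pveh; cur = pcur;
        elapsed = pel; remC = pC; remA = pA;
        curStops.swap(savedStops);
        routeVeh.pop_back();
        routeStops.pop_back();
        if (aborted) return;
      }
      return;
    }

    if (nUnvis == 0) { recordLeaf(); return; }

    // open a new route on a minimum-count vehicle
    int minCount = vehCount[0];
    for (int v = 1; v < m; ++v) if (vehCount[v] < minCount) minCount = vehCount[v];
    for (int v = 0; v < m; ++v) {
      if (vehCount[v] != minCount) continue;
      vehCount[v] += 1;
      open = true; oveh = v; cur = 0;
      elapsed = 0.0; remC = vehCold[v]; remA = vehAmb[v];
      curStops.clear();
      dfs();
      open = false;
      curStops.clear();
      vehCount[v] -= 1;
      if (aborted) return;
      if (!branchVehicles) break;
    }
  }
};

// [[Rcpp::export(name = ".solve_core")]]
List solve_core(NumericMatrix tim, NumericMatrix riskBase, NumericMatrix dist,
                IntegerMatrix acc, NumericVector coldVol, NumericVector ambVol,
                NumericVector vehCold, NumericVector vehAmb, NumericVector vehAdd,
                double wt, double wp, double tn, double rn,
                double service, double window,
                NumericVector spTime, NumericVector spRiskMin, NumericVector lbIn,
                int width, bool firstLeafOnly, bool branchVehicles,
                double budgetSec) {
  Core c;
  c.n = tim.nrow() - 1;
  c.m = vehCold.size();
  c.tim = tim; c.riskBase = riskBase; c.dist = dist; c.acc = acc;
  c.coldVol = coldVol; c.ambVol = ambVol;
  c.vehCold = vehCold; c.vehAmb = vehAmb; c.vehAdd = vehAdd;
  c.wt = wt; c.wp = wp; c.tn = tn; c.rn = rn;
  c.service = service; c.window = window;
  c.spTime = spTime; c.spRiskMin = spRiskMin; c.lbIn = lbIn;
  c.width = width; c.firstLeafOnly = firstLeafOnly;
  c.branchVehicles = branchVehicles; c.budgetSec = budgetSec;
  c.t0 = std::chrono::steady_clock::now();

  c.visited.assign(c.n + 1, 0);
  c.visited[0] = 1;
  c.nUnvis = c.n;
  c.sumLb = 0.0;
  for (int j = 1; j <= c.n; ++j) c.sumLb += lbIn[j];
  c.vehCount.assign(c.m, 0);
  c.open = false;
  c.partial = 0.0;
  c.haveBest = false; c.haveFirst = false;
  c.bestScore = R_PosInf; c.firstScore = R_PosInf;
  c.aborted = false;
  c.nodes = 0;

  bool timedOut = false;
  if (c.n > 0) c.dfs();
  else { c.haveBest = true; c.haveFirst = true; c.bestScore = 0.0; c.firstScore = 0.0; }
  if (c.aborted && !c.firstLeafOnly) timedOut = true;

  List routes(c.bestStops.size());
  IntegerVector rveh(c.bestStops.size());
  for (size_t r = 0; r < c.bestStops.size(); ++r) {
    routes[r] = wrap(c.bestStops[r]);
    rveh[r] = c.bestVeh[r] + 1;
  }
  return List::create(
    _["found"] = c.haveBest,
    _["score"] = c.haveBest ? c.bestScore : NA_REAL,
    _["first_score"] = c.haveFirst ? c.firstScore : NA_REAL,
    _["routes"] = routes,
    _["route_vehicle"] = rveh,
    _["exhausted"] = !timedOut,
    _["nodes"] = (double)c.nodes);
}
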