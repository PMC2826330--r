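// Exact depth-first branch-and-bound solver for 0/1 integer linear
// programs with two-sided row bounds:  lo <= a.x <= hi,  x binary,
// minimizing c.x.  Designed for the supertree fill-in models, where
// branching on the fill-in variables lets bound propagation fix all
// dependent pattern / bookkeeping variables, so the search tree is at
// most 2^U nodes and usually far smaller.
//
// Propagation: per-row running activity bounds (minAct/maxAct over the
// unassigned variables); a row whose bounds exclude [lo, hi] prunes the
// node, and a free variable whose either value would violate a row is
// fixed and queued.  Objective pruning uses the running lower bound
// sum(assigned c.x) + sum(free min(c, 0)).

#include <Rcpp.h>
#include <vector>
#include <chrono>
using namespace Rcpp;

namespace {

struct Solver {
  int nvar, nrow;
  std::vector<double> obj;
  // CSR rows
  std::vector<int> row_start, row_var;
  std::vector<double> row_coef, lo, hi;
  // per-variable occurrence lists
  std::vector<int> var_start, var_row;
  std::vector<double> var_coef;
  std::vector<int> branch;       // branching priority (variable ids)

  std::vector<signed char> val;  // -1 free, 0/1 assigned
  std::vector<double> minAct, maxAct;
  double lb;                     // objective lower bound at current node
  std::vector<int> trail;

  bool feas_only;
  double best_obj;
  std::vector<signed char> best_x;
  bool found;
  long long nodes, node_limit;
  std::chrono::steady_clock::time_point t_end;
  bool timed_out;

  static constexpr double EPS = 1e-6;

  bool assign(int v, int x, std::vector<int>& queue) {
    val[v] = (signed char)x;
    trail.push_back(v);
    double c = obj[v];
    if (c > 0) { if (x == 1) lb += c; }
    else if (c < 0) { if (x == 0) lb -= c; }   // free contribution was c
    bool ok = true;
    // update every row of v (unassign reverses the full loop, so a partial
    // update would corrupt the activity bounds)
    for (int t = var_start[v]; t < var_start[v + 1]; ++t) {
      int r = var_row[t];
      double a = var_coef[t];
      // free range was [min(a,0), max(a,0)]; now contributes a*x
      if (a > 0) { if (x == 1) minAct[r] += a; else maxAct[r] -= a; }
      else       { if (x == 1) maxAct[r] += a; else minAct[r] -= a; }
      if (minAct[r] > hi[r] + EPS || maxAct[r] < lo[r] - EPS) ok = false;
    }
    if (ok) queue.push_back(v);
    return ok;
  }

  void unassign(int v) {
    int x = val[v];
    double c = obj[v];
    if (c > 0) { if (x == 1) lb -= c; }
    else if (c < 0) { if (x == 0) lb += c; }
    for (int t = var_start[v]; t < var_start[v + 1]; ++t) {
      int r = var_row[t];
      double a = var_coef[t];
      if (a > 0) { if (x == 1) minAct[r] -= a; else maxAct[r] += a; }
      else       { if (x == 1) maxAct[r] -= a; else minAct[r] += a; }
    }
    val[v] = -1;
  }

  // propagate consequences of everything on `queue`; returns false on conflict
  bool propagate(std::vector<int>& queue) {
    for (size_t qi = 0; qi < queue.size(); ++qi) {
      int v = queue[qi];
      for (int t = var_start[v]; t < var_start[v + 1]; ++t) {
        int r = var_row[t];
        // scan row r for forced variables
        for (int u = row_start[r]; u < row_start[r + 1]; ++u) {
          int w = row_var[u];
          if (val[w] != -1) continue;
          double a = row_coef[u];
          int force = -1;
          if (a > 0) {
            if (minAct[r] + a > hi[r] + EPS) force = 0;
            else if (maxAct[r] - a < lo[r] - EPS) force = 1;
          } else {
            if (minAct[r] - a > hi[r] + EPS) force = 1;
            else if (maxAct[r] + a < lo[r] - EPS) force = 0;
          }
          if (force >= 0 && !assign(w, force, queue)) return false;
        }
      }
    }
    return true;
  }

  bool time_up() {
    if ((nodes & 1023) == 0 &&
        std::chrono::steady_clock::now() > t_end) timed_out = true;
    return timed_out;
  }

  void search() {
    ++nodes;
    if (time_up()) return;
    if (!feas_only && lb >= best_obj - EPS && found) return;
    // next branching variable
    int v = -1;
    for (int bi : branch) if (val[bi] == -1) { v = bi; break; }
    if (v == -1) {
      for (int i = 0; i < nvar; ++i) if (val[i] == -1) { v = i; break; }
    }
    if (v == -1) {                       // full assignment: feasible leaf
      if (feas_only || !found || lb < best_obj - EPS) {
        best_obj = lb;
        best_x.assign(val.begin(), val.end());
        found = true;
      }
      return;
    }
    int first = obj[v] > 0 ? 0 : (obj[v] < 0 ? 1 : 0);
    for (int pass = 0; pass < 2; ++pass) {
      int x = pass == 0 ? first : 1 - first;
      size_t mark = trail.size();
      double lb0 = lb;
      std::vector<int> queue;
      bool ok = assign(v, x, queue) && propagate(queue);
      if (ok) {
        search();
        if (feas_only && found) return;
      }
      while (trail.size() > mark) { unassign(trail.back()); trail.pop_back(); }
      lb = lb0;
      if (timed_out) return;
      if (!feas_only && found && lb >= best_obj - EPS) return;
    }
  }
};

}  // namespace

// [[Rcpp::export(name = ".bnb_solve")]]
List bnb_solve(int nvar, NumericVector obj,
               IntegerVector ri, IntegerVector vi, NumericVector av,
               NumericVector lo, NumericVector hi,
               IntegerVector branch_order,
               bool feasibility_only, double time_limit) {
  Solver s;
  s.nvar = nvar;
  s.nrow = lo.size();
  s.obj.assign(obj.begin(), obj.end());
  s.lo.assign(lo.begin(), lo.end());
  s.hi.assign(hi.begin(), hi.end());
  s.feas_only = feasibility_only;
  s.found = false;
  s.best_obj = R_PosInf;
  s.nodes = 0;
  s.timed_out = false;
  s.t_end = std::chrono::steady_clock::now() +
    std::chrono::milliseconds((long long)(time_limit * 1000.0));

  int nz = ri.size();
  // build CSR (rows are 1-based on input)
  std::vector<int> rcnt(s.nrow + 1, 0), vcnt(nvar + 1, 0);
  for (int t = 0; t < nz; ++t) { ++rcnt[ri[t]]; ++vcnt[vi[t]]; }
  s.row_start.assign(s.nrow + 1, 0);
  for (int r = 0; r < s.nrow; ++r) s.row_start[r + 1] = s.row_start[r] + rcnt[r + 1];
  s.var_start.assign(nvar + 1, 0);
  for (int v = 0; v < nvar; ++v) s.var_start[v + 1] = s.var_start[v] + vcnt[v + 1];
  s.row_var.resize(nz); s.row_coef.resize(nz);
  s.var_row.resize(nz); s.var_coef.resize(nz);
  std::vector<int> rpos(s.row_start.begin(), s.row_start.end());
  std::vector<int> vpos(s.var_start.begin(), s.var_start.end());
  for (int t = 0; t < nz; ++t) {
    int r = ri[t] - 1, v = vi[t] - 1;
    s.row_var[rpos[r]] = v; s.row_coef[rpos[r]] = av[t]; ++rpos[r];
    s.var_row[vpos[v]] = r; s.var_coef[vpos[v]] = av[t]; ++vpos[v];
  }
  s.branch.assign(branch_order.begin(), branch_order.end());
  for (auto& bv : s.branch) --bv;

  s.val.assign(nvar, -1);
  s.minAct.assign(s.nrow, 0.0);
  s.maxAct.assign(s.nrow, 0.0);
  for (int r = 0; r < s.nrow; ++r) {
    for (int u = s.row_start[r]; u < s.row_start[r + 1]; ++u) {
      double a = s.row_coef[u];
      if (a > 0) s.maxAct[r] += a; else s.minAct[r] += a;
    }
  }
  s.lb = 0.0;
  for (int v = 0; v < nvar; ++v) if (s.obj[v] < 0) s.lb += s.obj[v];

  // root propagation: seed with every row once by scanning all rows
  bool root_ok = true;
  for (int r = 0; r < s.nrow && root_ok; ++r) {
    if (s.minAct[r] > s.hi[r] + Solver::EPS ||
        s.maxAct[r] < s.lo[r] - Solver::EPS) root_ok = false;
  }
  if (root_ok) {
    std::vector<int> queue;
    // force via a sweep: emulate by scanning rows until fixpoint
    bool changed = true;
    while (changed && root_ok) {
      changed = false;
      for (int r = 0; r < s.nrow && root_ok; ++r) {
        for (int u = s.row_start[r]; u < s.row_start[r + 1]; ++u) {
          int w = s.row_var[u];
          if (s.val[w] != -1) continue;
          double a = s.row_coef[u];
          int force = -1;
          if (a > 0) {
            if (s.minAct[r] + a > s.hi[r] + Solver::EPS) force = 0;
            else if (s.maxAct[r] - a < s.lo[r] - Solver::EPS) force = 1;
          } else {
            if (s.minAct[r] - a > s.hi[r] + Solver::EPS) force = 1;
            else if (s.maxAct[r] + a < s.lo[r] - Solver::EPS) force = 0;
          }
          if (force >= 0) {
            if (!s.assign(w, force, queue)) { root_ok = false; break; }
            changed = true;
          }
        }
      }
    }
    if (root_ok) root_ok = s.propagate(queue);
  }
  if (root_ok) s.search();

  std::string status;
  if (s.timed_out && !s.found) status = "timeout";
  else if (s.timed_out) status = "timeout";          // best-so-far available
  else if (!s.found) status = "infeasible";
  else status = feasibility_only ? "feasible" : "optimal";

  IntegerVector xout(nvar, NA_INTEGER);
  if (s.found) for (int v = 0; v < nvar; ++v) xout[v] = s.best_x[v];
  return List::create(_["status"] = status,
                      _["objective"] = s.found ? s.best_obj : NA_REAL,
                      _["x"] = xout,
                      _["nodes"] = (double)s.nodes);
}
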