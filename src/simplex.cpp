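// Dense two-phase primal simplex for the small flux-balance LPs used in
// community metabolic scoring:
//
//   maximize c'v   subject to  S v = 0,  lb <= v <= ub.
//
// The problem is shifted to x = v - lb >= 0 and upper bounds are written
// as explicit slack rows, giving the standard form
//
//   min  f'x   s.t.  A x = b, x >= 0
//
// solved with a classic tableau, Dantzig pricing and a Bland fallback for
// anti-cycling. Problems here have tens of rows/columns, so a dense
// tableau is the simplest robust choice.

#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

static const double EPS = 1e-9;

// Solve min f'x s.t. T (rows) describe A x = b with b >= 0; basis holds
// the index of the basic variable of each row. Tableau T has ncols
// structural columns plus the rhs in the last column. Returns 0 on
// optimum, 1 if unbounded.
static int simplex_core(std::vector<std::vector<double>>& T,
                        std::vector<double>& cost,
                        std::vector<int>& basis,
                        std::vector<bool>& allowed,
                        int nrow, int ncol, double& objective,
                        int max_pivots) {
  // reduced costs maintained in a separate row `z` (cost - basic part)
  std::vector<double> z(ncol + 1, 0.0);
  for (int j = 0; j <= ncol; ++j) {
    double s = (j < ncol) ? cost[j] : 0.0;
    for (int i = 0; i < nrow; ++i) s -= cost[basis[i]] * T[i][j];
    z[j] = s;
  }
  int pivots = 0;
  bool bland = false;
  while (true) {
    // entering column
    int enter = -1;
    double best = -EPS;
    for (int j = 0; j < ncol; ++j) {
      if (!allowed[j]) continue;
      if (z[j] < (bland ? -EPS : best)) {
        best = z[j];
        enter = j;
        if (bland) break;
      }
    }
    if (enter < 0) break; // optimal
    // ratio test
    int leave = -1;
    double best_ratio = 0.0;
    for (int i = 0; i < nrow; ++i) {
      if (T[i][enter] > EPS) {
        double ratio = T[i][ncol] / T[i][enter];
        if (leave < 0 || ratio < best_ratio - EPS ||
            (std::fabs(ratio - best_ratio) <= EPS &&
             basis[i] < basis[leave])) {
          leave = i;
          best_ratio = ratio;
        }
      }
    }
    if (leave < 0) return 1; // unbounded
    // pivot
    double piv = T[leave][enter];
    for (int j = 0; j <= ncol; ++j) T[leave][j] /= piv;
    for (int i = 0; i < nrow; ++i) {
      if (i == leave) continue;
      double f = T[i][enter];
      if (std::fabs(f) > 0.0)
        for (int j = 0; j <= ncol; ++j) T[i][j] -= f * T[leave][j];
    }
    double fz = z[enter];
    for (int j = 0; j <= ncol; ++j) z[j] -= fz * T[leave][j];
    basis[leave] = enter;
    if (++pivots > max_pivots) {
      if (!bland) { bland = true; pivots = 0; } // switch to Bland's rule
      else return 2;                            // still cycling: give up
    }
  }
  objective = 0.0;
  for (int i = 0; i < nrow; ++i)
    if (basis[i] < (int)cost.size()) objective += cost[basis[i]] * T[i][ncol];
  return 0;
}

// [[Rcpp::export(name = ".simplex_fba")]]
List simplex_fba(NumericMatrix S, NumericVector lb, NumericVector ub,
                 NumericVector obj, bool maximize = true) {
  const int m = S.nrow();   // metabolites (equality rows)
  const int n = S.ncol();   // reactions
  // standard form: vars = x (n) + upper-bound slacks (n); rows = m + n
  const int nrow = m + n;
  const int nstruct = 2 * n;
  const int ncol = nstruct + nrow; // + artificials
  std::vector<std::vector<double>> T(nrow,
                                     std::vector<double>(ncol + 1, 0.0));
  // equality rows: S x = -S lb
  for (int i = 0; i < m; ++i) {
    double b = 0.0;
    for (int j = 0; j < n; ++j) b -= S(i, j) * lb[j];
    double sign = (b < 0) ? -1.0 : 1.0;
    for (int j = 0; j < n; ++j) T[i][j] = sign * S(i, j);
    T[i][ncol] = sign * b;
  }
  // bound rows: x_j + s_j = ub_j - lb_j
  for (int j = 0; j < n; ++j) {
    T[m + j][j] = 1.0;
    T[m + j][n + j] = 1.0;
    T[m + j][ncol] = ub[j] - lb[j];
    if (T[m + j][ncol] < 0)
      stop("invalid bounds: lb > ub");
  }
  // artificials: identity on all rows
  std::vector<int> basis(nrow);
  for (int i = 0; i < nrow; ++i) {
    T[i][nstruct + i] = 1.0;
    basis[i] = nstruct + i;
  }
  std::vector<bool> allowed(ncol, true);
  const int max_pivots = 200 * (nrow + ncol);

  // phase 1: minimize sum of artificials
  std::vector<double> cost1(ncol, 0.0);
  for (int i = 0; i < nrow; ++i) cost1[nstruct + i] = 1.0;
  double obj1 = 0.0;
  int rc = simplex_core(T, cost1, basis, allowed, nrow, ncol, obj1,
                        max_pivots);
  if (rc == 2) return List::create(_["status"] = "error",
                                   _["message"] = "simplex cycling");
  if (rc == 1 || obj1 > 1e-7)
    return List::create(_["status"] = "infeasible");

  // forbid artificials from re-entering
  for (int i = 0; i < nrow; ++i) allowed[nstruct + i] = false;
  // pivot any artificial still in the basis to a structural column
  for (int i = 0; i < nrow; ++i) {
    if (basis[i] >= nstruct) {
      int enter = -1;
      for (int j = 0; j < nstruct; ++j)
        if (std::fabs(T[i][j]) > EPS) { enter = j; break; }
      if (enter < 0) continue; // redundant row, harmless
      double piv = T[i][enter];
      for (int j = 0; j <= ncol; ++j) T[i][j] /= piv;
      for (int k = 0; k < nrow; ++k) {
        if (k == i) continue;
        double f = T[k][enter];
        if (std::fabs(f) > 0.0)
          for (int j = 0; j <= ncol; ++j) T[k][j] -= f * T[i][j];
      }
      basis[i] = enter;
    }
  }

  // phase 2: minimize -(obj)'x (maximize) or obj'x
  std::vector<double> cost2(ncol, 0.0);
  for (int j = 0; j < n; ++j) cost2[j] = maximize ? -obj[j] : obj[j];
  double obj2 = 0.0;
  rc = simplex_core(T, cost2, basis, allowed, nrow, ncol, obj2, max_pivots);
  if (rc == 1) return List::create(_["status"] = "unbounded");
  if (rc == 2) return List::create(_["status"] = "error",
                                   _["message"] = "simplex cycling");
  NumericVector x(n);
  for (int i = 0; i < nrow; ++i)
    if (basis[i] < n) x[basis[i]] = T[i][ncol];
  double fixed = 0.0; // add back the lb shift and constant term
  for (int j = 0; j < n; ++j) { x[j] += lb[j]; fixed += obj[j] * lb[j]; }
  double val = (maximize ? -obj2 : obj2) + fixed;
  return List::create(_["status"] = "optimal", _["objective"] = val,
                      _["x"] = x);
}
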