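// Bounded-variable two-phase primal simplex.
//
// Solves   min c'x   s.t.  A x = b,  lb <= x <= ub
// with a dense full tableau, Dantzig pricing (Bland fallback for
// anti-cycling), and periodic refactorization: every REFACTOR_EVERY pivots
// the tableau B^{-1}[A|E] and the basic values are recomputed from scratch
// from the current basis, which keeps the accumulated elimination error
// bounded on the larger parsimonious-FBA problems. A final feasibility
// audit rejects any drifted endpoint.
//
// Infinite bounds are passed as +/-1e30.

#include <RcppArmadillo.h>
#include <cmath>
#include <vector>
#include <limits>

// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static const double INF_BND = 1e29;
static const int REFACTOR_EVERY = 100;

// [[Rcpp::export(name = ".simplex_core")]]
List simplex_core(NumericMatrix A_in, NumericVector b_in, NumericVector cost,
                  NumericVector lb, NumericVector ub,
                  double pivot_tol = 1e-9, double feas_tol = 1e-9,
                  int max_iter = 200000) {
  const int m = A_in.nrow();
  const int n = A_in.ncol();
  const int ntot = n + m;

  arma::mat A(A_in.begin(), m, n);            // original, never modified
  arma::vec b(b_in.begin(), m);

  std::vector<int> state(ntot);               // 0 basic, 1 at lb, 2 at ub
  std::vector<double> xval(ntot, 0.0);        // value of nonbasic vars
  std::vector<double> lo(ntot), hi(ntot);
  std::vector<int> basic_of_row(m);
  arma::vec xB(m, arma::fill::zeros);
  arma::vec s(m);                             // artificial column signs

  for (int j = 0; j < n; ++j) {
    lo[j] = lb[j]; hi[j] = ub[j];
    if (lo[j] > hi[j]) return List::create(_["status"] = "infeasible");
    if (lo[j] > -INF_BND) { state[j] = 1; xval[j] = lo[j]; }
    else if (hi[j] < INF_BND) { state[j] = 2; xval[j] = hi[j]; }
    else { state[j] = 1; xval[j] = 0.0; lo[j] = 0.0; hi[j] = 1e30; }
  }

  arma::vec r = b;
  for (int j = 0; j < n; ++j) {
    if (xval[j] != 0.0) r -= A.col(j) * xval[j];
  }
  arma::mat T(m, ntot);                       // B^{-1} [A | E]
  for (int i = 0; i < m; ++i) {
    s[i] = (r[i] >= 0.0) ? 1.0 : -1.0;
    int aj = n + i;
    lo[aj] = 0.0; hi[aj] = 1e30; state[aj] = 0; xval[aj] = 0.0;
    basic_of_row[i] = aj;
    xB[i] = std::fabs(r[i]);
  }
  for (int j = 0; j < n; ++j) T.col(j) = A.col(j);
  T.cols(n, ntot - 1).zeros();
  for (int i = 0; i < m; ++i) {
    T.row(i) *= s[i];
    T(i, n + i) = 1.0;
  }

  // rebuild T and xB from the current basis (bounds accumulated error)
  auto refactor = [&]() -> bool {
    arma::mat B(m, m, arma::fill::zeros);
    for (int i = 0; i < m; ++i) {
      int j = basic_of_row[i];
      if (j < n) B.col(i) = A.col(j);
      else B(j - n, i) = s[j - n];
    }
    arma::mat Binv;
    if (!arma::inv(Binv, B)) return false;
    T.cols(0, n - 1) = Binv * A;
    for (int i = 0; i < m; ++i) T.col(n + i) = Binv.col(i) * s[i];
    arma::vec xb = Binv * b;
    for (int j = 0; j < ntot; ++j) {
      if (state[j] != 0 && xval[j] != 0.0) xb -= T.col(j) * xval[j];
    }
    xB = xb;
    return true;
  };

  std::vector<double> d(ntot);
  bool phase1 = true;
  int iter = 0, pivots_since_refactor = 0;
  const int bland_after = 20000;

  auto phase1_obj = [&]() {
    double p1 = 0.0;
    for (int i = 0; i < m; ++i) if (basic_of_row[i] >= n) p1 += xB[i];
    return p1;
  };

  double bnorm = 1.0;
  for (int i = 0; i < m; ++i) bnorm = std::max(bnorm, std::fabs(b[i]));

  while (true) {
    if (++iter > max_iter) return List::create(_["status"] = "maxiter");

    std::vector<double> cB(m);
    for (int i = 0; i < m; ++i) {
      int bj = basic_of_row[i];
      cB[i] = phase1 ? (bj >= n ? 1.0 : 0.0) : (bj >= n ? 0.0 : cost[bj]);
    }
    for (int j = 0; j < ntot; ++j) {
      if (state[j] == 0) { d[j] = 0.0; continue; }
      double cj = phase1 ? 0.0 : (j >= n ? 0.0 : cost[j]);
      double acc = cj;
      const double* col = T.colptr(j);
      for (int i = 0; i < m; ++i) {
        if (cB[i] != 0.0 && col[i] != 0.0) acc -= cB[i] * col[i];
      }
      d[j] = acc;
    }

    int enter = -1; double best = pivot_tol; int dir = 0;
    bool bland = iter > bland_after;
    for (int j = 0; j < ntot; ++j) {
      if (state[j] == 0 || j >= n) continue;  // artificials never (re)enter
      double viol = 0.0; int tdir = 0;
      if (state[j] == 1 && d[j] < -pivot_tol) { viol = -d[j]; tdir = +1; }
      else if (state[j] == 2 && d[j] > pivot_tol) { viol = d[j]; tdir = -1; }
      if (tdir != 0) {
        if (bland) { enter = j; dir = tdir; break; }
        if (viol > best) { best = viol; enter = j; dir = tdir; }
      }
    }

    if (enter < 0) {
      // candidate optimum for the current phase: refactor and re-verify
      refactor();
      if (phase1) {
        // re-price with the clean tableau: drift may have hidden candidates
        bool still_opt = true;
        for (int i = 0; i < m; ++i) {
          cB[i] = (basic_of_row[i] >= n) ? 1.0 : 0.0;
        }
        for (int j = 0; j < n && still_opt; ++j) {
          if (state[j] == 0) continue;
          double acc = 0.0;
          const double* col = T.colptr(j);
          for (int i = 0; i < m; ++i) {
            if (cB[i] != 0.0 && col[i] != 0.0) acc -= cB[i] * col[i];
          }
          if ((state[j] == 1 && acc < -1e-7) ||
              (state[j] == 2 && acc > 1e-7)) {
            still_opt = false;
          }
        }
        if (!still_opt) { pivots_since_refactor = 0; continue; }
        double p1 = phase1_obj();
        if (p1 > 1e-7 * (1.0 + bnorm)) {
          return List::create(_["status"] = "infeasible");
        }
        for (int i = 0; i < m; ++i) {
          if (basic_of_row[i] >= n) {
            lo[basic_of_row[i]] = 0.0;
            hi[basic_of_row[i]] = 0.0;
          }
        }
        phase1 = false;
        pivots_since_refactor = 0;
        continue;
      }
      // re-price once after refactor to confirm optimality
      bool still_opt = true;
      for (int i = 0; i < m; ++i) {
        int bj = basic_of_row[i];
        cB[i] = (bj >= n) ? 0.0 : cost[bj];
      }
      for (int j = 0; j < n && still_opt; ++j) {
        if (state[j] == 0) continue;
        double acc = cost[j];
        const double* col = T.colptr(j);
        for (int i = 0; i < m; ++i) {
          if (cB[i] != 0.0 && col[i] != 0.0) acc -= cB[i] * col[i];
        }
        if ((state[j] == 1 && acc < -1e-7) || (state[j] == 2 && acc > 1e-7)) {
          still_opt = false;
        }
      }
      if (still_opt) break;
      pivots_since_refactor = 0;
      continue;                                // resume with clean tableau
    }

    // ratio test: entering moves by delta >= 0 in direction `dir`
    double limit = hi[enter] - lo[enter];
    if (limit > 1e29) limit = std::numeric_limits<double>::infinity();
    int leave_row = -1; int leave_bound = 0;
    const double* wcol = T.colptr(enter);
    for (int i = 0; i < m; ++i) {
      double w = wcol[i] * dir;
      int bj = basic_of_row[i];
      if (w > pivot_tol) {
        double lim = (lo[bj] <= -INF_BND)
          ? std::numeric_limits<double>::infinity()
          : (xB[i] - lo[bj]) / w;
        if (lim < limit - 1e-12 ||
            (lim < limit + 1e-12 && leave_row >= 0 &&
             basic_of_row[i] < basic_of_row[leave_row])) {
          limit = lim; leave_row = i; leave_bound = 1;
        }
      } else if (w < -pivot_tol) {
        double lim = (hi[bj] >= INF_BND)
          ? std::numeric_limits<double>::infinity()
          : (hi[bj] - xB[i]) / (-w);
        if (lim < limit - 1e-12 ||
            (lim < limit + 1e-12 && leave_row >= 0 &&
             basic_of_row[i] < basic_of_row[leave_row])) {
          limit = lim; leave_row = i; leave_bound = 2;
        }
      }
    }

    if (!std::isfinite(limit)) {
      if (phase1) return List::create(_["status"] = "numeric_failure");
      return List::create(_["status"] = "unbounded");
    }
    if (limit < 0) limit = 0;

    if (leave_row < 0) {
      // bound flip
      for (int i = 0; i < m; ++i) {
        if (wcol[i] != 0.0) xB[i] -= wcol[i] * dir * limit;
      }
      if (dir > 0) { state[enter] = 2; xval[enter] = hi[enter]; }
      else { state[enter] = 1; xval[enter] = lo[enter]; }
      continue;
    }

    double piv = T(leave_row, enter);
    int leaving = basic_of_row[leave_row];
    double enter_newval = xval[enter] + dir * limit;

    for (int i = 0; i < m; ++i) {
      if (i == leave_row) continue;
      if (wcol[i] != 0.0) xB[i] -= wcol[i] * dir * limit;
    }

    T.row(leave_row) /= piv;
    for (int i = 0; i < m; ++i) {
      if (i == leave_row) continue;
      double f = T(i, enter);
      if (f != 0.0) T.row(i) -= f * T.row(leave_row);
    }

    basic_of_row[leave_row] = enter;
    state[enter] = 0;
    xB[leave_row] = enter_newval;
    state[leaving] = leave_bound;
    xval[leaving] = (leave_bound == 1) ? lo[leaving] : hi[leaving];

    if (++pivots_since_refactor >= REFACTOR_EVERY) {
      refactor();
      pivots_since_refactor = 0;
    }
  }

  // assemble and audit the solution
  NumericVector x(n);
  for (int j = 0; j < n; ++j) x[j] = (state[j] == 0) ? 0.0 : xval[j];
  for (int i = 0; i < m; ++i) {
    if (basic_of_row[i] < n) x[basic_of_row[i]] = xB[i];
  }
  arma::vec xv(x.begin(), n);
  double resid = arma::norm(A * xv - b, "inf");
  double bound_viol = 0.0;
  for (int j = 0; j < n; ++j) {
    if (lb[j] > -INF_BND) bound_viol = std::max(bound_viol, lb[j] - x[j]);
    if (ub[j] < INF_BND) bound_viol = std::max(bound_viol, x[j] - ub[j]);
  }
  if (resid > 1e-6 * (1.0 + bnorm) || bound_viol > 1e-6) {
    return List::create(_["status"] = "numeric_failure",
                        _["residual"] = resid,
                        _["bound_violation"] = bound_viol);
  }
  double obj = 0.0;
  for (int j = 0; j < n; ++j) obj += cost[j] * x[j];
  return List::create(_["status"] = "optimal", _["x"] = x,
                      _["objective"] = obj, _["iterations"] = iter);
}
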