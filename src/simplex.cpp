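// Bounded-variable two-phase primal simplex for the constraint-based
// analysis core (FBA, FVA, gap-filling, linear MOMA).
//
// Solves   min c'x   s.t.  A x = b,  lb <= x <= ub
// with all bounds finite (the R wrapper clamps open bounds to a large
// finite box; metabolic models use +/-1000 by convention).
//
// Deterministic: Dantzig pricing with index tie-breaks, switching to
// Bland's rule after a run of degenerate pivots, so identical inputs
// always produce identical solutions.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static const double DTOL = 1e-9;   // reduced-cost tolerance
static const double PTOL = 1e-9;   // pivot-element tolerance
static const double FEAS = 1e-7;   // phase-1 feasibility tolerance

// [[Rcpp::export(name = ".lp_solve_dense")]]
Rcpp::List lp_solve_dense(const arma::mat& A, const arma::vec& b,
                          const arma::vec& cost, const arma::vec& lb,
                          const arma::vec& ub, bool maximize,
                          int max_iter = 100000) {
  const int m = A.n_rows, n = A.n_cols;
  const int total = n + m;            // structural + artificial columns

  vec cobj = maximize ? vec(-cost) : vec(cost);

  // Column access: structural j -> A.col(j); artificial i -> sgn_i * e_i.
  vec art_sign(m, fill::ones);

  vec lba(total), uba(total);
  lba.head(n) = lb; uba.head(n) = ub;
  lba.tail(m).zeros(); uba.tail(m).fill(datum::inf);

  // start nonbasic structural variables at the bound nearest zero
  vec x(total, fill::zeros);
  ivec vstat(total);                  // 0 at lb, 1 at ub, 2 basic
  for (int j = 0; j < n; ++j) {
    if (std::abs(lb[j]) <= std::abs(ub[j])) { x[j] = lb[j]; vstat[j] = 0; }
    else                                     { x[j] = ub[j]; vstat[j] = 1; }
  }

  vec r = b - A * x.head(n);          // residual covered by artificials
  ivec basis(m);
  for (int i = 0; i < m; ++i) {
    basis[i] = n + i;
    if (r[i] < 0) { art_sign[i] = -1.0; }
    x[n + i] = std::abs(r[i]);
    vstat[n + i] = 2;
  }

  mat Binv = diagmat(art_sign);       // inverse of the artificial basis
  vec xB = x.tail(m);                 // values of basic variables

  auto colv = [&](int j) -> vec {
    if (j < n) return A.col(j);
    vec e(m, fill::zeros); e[j - n] = art_sign[j - n]; return e;
  };

  auto refactor = [&]() {
    mat B(m, m);
    for (int i = 0; i < m; ++i) B.col(i) = colv(basis[i]);
    mat Bi;
    if (!inv(Bi, B)) return;          // keep eta-updated inverse
    Binv = Bi;
    vec rr = b;
    for (int j = 0; j < total; ++j)
      if (vstat[j] != 2 && x[j] != 0.0) rr -= colv(j) * x[j];
    xB = Binv * rr;
    for (int i = 0; i < m; ++i) x[basis[i]] = xB[i];
  };

  int iter = 0, degen_run = 0, since_refactor = 0;
  bool bland = false;
  int status = 3;                     // 3 = iteration limit

  for (int phase = 1; phase <= 2; ++phase) {
    vec cc(total, fill::zeros);
    if (phase == 1) cc.tail(m).ones();
    else            cc.head(n) = cobj;

    if (phase == 2) {
      // artificials pinned at zero; they may linger in the basis at value 0
      uba.tail(m).zeros();
      bland = false; degen_run = 0;
    }

    while (true) {
      if (++iter > max_iter) return Rcpp::List::create(
          Rcpp::Named("status") = 3, Rcpp::Named("x") = x.head(n),
          Rcpp::Named("objective") = NA_REAL);

      // pricing
      vec cB(m);
      for (int i = 0; i < m; ++i) cB[i] = cc[basis[i]];
      rowvec y = cB.t() * Binv;

      int q = -1; double best = DTOL;
      for (int j = 0; j < total; ++j) {
        if (vstat[j] == 2) continue;
        if (phase == 2 && j >= n) continue;
        if (uba[j] - lba[j] < 1e-12) continue;
        double dj = cc[j] - as_scalar(y * colv(j));
        double viol = (vstat[j] == 0) ? -dj : dj;
        if (viol > best) { q = j; best = viol; if (bland) break; }
      }
      if (q < 0) break;               // phase optimal

      double dir = (vstat[q] == 0) ? 1.0 : -1.0;
      vec w = Binv * colv(q);

      // ratio test: step t >= 0 in x[q] along dir
      double tmax = uba[q] - lba[q];  // bound-flip limit
      int leave = -1, leave_to = 0;
      double pivmag = 0.0;
      for (int i = 0; i < m; ++i) {
        double wi = dir * w[i];
        int bi = basis[i];
        if (wi > PTOL) {
          if (!std::isfinite(lba[bi])) continue;
          double t = (xB[i] - lba[bi]) / wi;
          if (t < -1e-9) t = 0;
          if (t < tmax - 1e-10 ||
              (t < tmax + 1e-10 && leave >= 0 && std::abs(w[i]) > pivmag)) {
            tmax = t; leave = i; leave_to = 0; pivmag = std::abs(w[i]);
          }
        } else if (wi < -PTOL) {
          if (!std::isfinite(uba[bi])) continue;
          double t = (uba[bi] - xB[i]) / (-wi);
          if (t < -1e-9) t = 0;
          if (t < tmax - 1e-10 ||
              (t < tmax + 1e-10 && leave >= 0 && std::abs(w[i]) > pivmag)) {
            tmax = t; leave = i; leave_to = 1; pivmag = std::abs(w[i]);
          }
        }
      }
      if (!std::isfinite(tmax)) {
        status = 2;                   // unbounded (open box only)
        return Rcpp::List::create(
            Rcpp::Named("status") = status, Rcpp::Named("x") = x.head(n),
            Rcpp::Named("objective") = NA_REAL);
      }
      if (tmax < 0) tmax = 0;

      // degeneracy bookkeeping: long runs of zero-step pivots -> Bland
      if (tmax < 1e-10) { if (++degen_run > 2 * (m + n)) bland = true; }
      else degen_run = 0;

      double xq_new = ((vstat[q] == 0) ? lba[q] : uba[q]) + dir * tmax;
      for (int i = 0; i < m; ++i) {
        xB[i] -= tmax * dir * w[i];
        x[basis[i]] = xB[i];
      }

      if (leave < 0) {                // bound flip, basis unchanged
        vstat[q] = 1 - vstat[q];
        x[q] = (vstat[q] == 0) ? lba[q] : uba[q];
      } else {
        int bl = basis[leave];
        x[bl] = (leave_to == 0) ? lba[bl] : uba[bl];
        vstat[bl] = leave_to;
        basis[leave] = q;
        vstat[q] = 2;
        x[q] = xq_new;
        xB[leave] = xq_new;
        // eta update of the basis inverse
        double piv = w[leave];
        rowvec rl = Binv.row(leave) / piv;
        for (int i = 0; i < m; ++i)
          if (i != leave) Binv.row(i) -= w[i] * rl;
        Binv.row(leave) = rl;
        if (++since_refactor >= 64) { refactor(); since_refactor = 0; }
      }
    }

    if (phase == 1) {
      refactor();
      double art = 0;
      for (int j = n; j < total; ++j) art += std::abs(x[j]);
      if (art > FEAS) {
        return Rcpp::List::create(
            Rcpp::Named("status") = 1, Rcpp::Named("x") = x.head(n),
            Rcpp::Named("objective") = NA_REAL);
      }
    }
  }

  refactor();
  double obj = dot(cost, x.head(n));
  vec resid = A * x.head(n) - b;
  status = 0;
  return Rcpp::List::create(
      Rcpp::Named("status") = status,
      Rcpp::Named("x") = x.head(n),
      Rcpp::Named("objective") = obj,
      Rcpp::Named("residual") = norm(resid, "inf"),
      Rcpp::Named("iterations") = iter);
}
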