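// Unbalanced entropic optimal-transport solver.
//
// Objective (minimised over P >= 0, elementwise):
//   F(P) = <C,P> - eps * sum_ij P_ij log P_ij
//        + tau * || P 1_m - a ||_2^2  +  tau * || P^T 1_n - b ||_1
// with 0 log 0 = 0.  The squared-L2 / L1 marginal penalties break the
// classic Sinkhorn scaling, so the solver is multiplicative mirror descent
// on P with backtracking line search on the objective (monotone descent),
// restarted from several initial plans and returning the best iterate.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

static const double P_FLOOR = 1e-100;

static double uot_objective(const arma::mat& P, const arma::mat& C,
                            const arma::vec& a, const arma::vec& b,
                            double eps, double tau) {
  double cost = arma::accu(C % P);
  double plogp = 0.0;
  for (arma::uword i = 0; i < P.n_elem; ++i) {
    double v = P(i);
    if (v > 0.0) plogp += v * std::log(v);
  }
  arma::vec r = arma::sum(P, 1) - a;
  arma::vec c = arma::sum(P, 0).t() - b;
  return cost - eps * plogp + tau * arma::dot(r, r) + tau * arma::accu(arma::abs(c));
}

static arma::mat uot_gradient(const arma::mat& P, const arma::mat& C,
                              const arma::vec& a, const arma::vec& b,
                              double eps, double tau) {
  arma::vec r = arma::sum(P, 1) - a;          // length n
  arma::vec c = arma::sum(P, 0).t() - b;      // length m
  arma::mat G = C;
  for (arma::uword j = 0; j < P.n_cols; ++j) {
    double sj = (c(j) > 0) - (c(j) < 0);
    for (arma::uword i = 0; i < P.n_rows; ++i) {
      double lp = std::log(std::max(P(i, j), P_FLOOR));
      G(i, j) += -eps * (lp + 1.0) + 2.0 * tau * r(i) + tau * sj;
    }
  }
  return G;
}

struct UotResult {
  arma::mat P;
  double objective;
  int iterations;
  bool converged;
};

// 1-D slice of the objective along one plan entry:
//   phi(p) = C p - eps p log p + tau (p + r)^2 + tau |p + c|,  p >= 0
static inline double phi1d(double p, double C, double r, double c,
                           double eps, double tau) {
  double ent = (p > 0.0) ? p * std::log(p) : 0.0;
  return C * p - eps * ent + tau * (p + r) * (p + r) + tau * std::fabs(p + c);
}

// root of psi(p) = C - eps(log p + 1) + 2 tau (p + r) + tau s on (lo, hi),
// where psi is increasing on (eps/(2 tau), inf); returns -1 if none
static double psi_right_root(double C, double r, double s, double eps,
                             double tau, double lo) {
  auto psi = [&](double p) {
    return C - eps * (std::log(p) + 1.0) + 2.0 * tau * (p + r) + tau * s;
  };
  double pmin = std::max(eps / (2.0 * tau), lo);
  if (psi(pmin) >= 0.0) return -1.0;
  double hi = std::max(1.0, 2.0 * pmin);
  int guard = 0;
  while (psi(hi) < 0.0 && guard++ < 200) hi *= 2.0;
  double a = pmin, b = hi;
  for (int i = 0; i < 80; ++i) {
    double mid = 0.5 * (a + b);
    if (psi(mid) < 0.0) a = mid; else b = mid;
  }
  return 0.5 * (a + b);
}

// exact coordinate-descent sweeps: each plan entry is set to the global
// minimiser of its 1-D slice (candidates: 0, the L1 kink, and the interior
// stationary point on each smooth piece)
static double coord_sweep(arma::mat& P, const arma::mat& C,
                          const arma::vec& a, const arma::vec& b,
                          double eps, double tau,
                          arma::vec& rowsum, arma::vec& colsum) {
  const arma::uword n = P.n_rows, m = P.n_cols;
  double gain = 0.0;
  for (arma::uword j = 0; j < m; ++j) {
    for (arma::uword i = 0; i < n; ++i) {
      const double pcur = P(i, j);
      const double r = rowsum(i) - pcur - a(i);
      const double c = colsum(j) - pcur - b(j);
      const double kink = -c;
      double cand[4];
      int ncand = 0;
      cand[ncand++] = 0.0;
      if (kink > 0.0) cand[ncand++] = kink;
      // piece p + c < 0 (only exists when kink > 0): sign -1
      if (kink > 0.0) {
        double rt = psi_right_root(C(i, j), r, -1.0, eps, tau, 0.0);
        if (rt > 0.0) cand[ncand++] = std::min(rt, kink);
      }
      // piece p + c > 0: sign +1, valid for p > max(0, kink)
      {
        double rt = psi_right_root(C(i, j), r, 1.0, eps, tau, 0.0);
        if (rt > 0.0) cand[ncand++] = std::max(rt, std::max(kink, 0.0));
      }
      double bestp = pcur;
      double bestf = phi1d(pcur, C(i, j), r, c, eps, tau);
      for (int k = 0; k < ncand; ++k) {
        double f = phi1d(cand[k], C(i, j), r, c, eps, tau);
        if (f < bestf - 1e-15) { bestf = f; bestp = cand[k]; }
      }
      if (bestp != pcur) {
        gain += phi1d(pcur, C(i, j), r, c, eps, tau) - bestf;
        rowsum(i) += bestp - pcur;
        colsum(j) += bestp - pcur;
        P(i, j) = bestp;
      }
    }
  }
  return gain;
}

// exact transfer of mass t from entry (i2, j) to (i1, j): the column sum is
// unchanged (the L1 term drops out), leaving a smooth 1-D problem in t whose
// stationary points have closed-form bracketing.  Returns the gain.
static double pair_transfer(arma::mat& P, const arma::mat& C,
                            const arma::vec& a, double eps, double tau,
                            arma::vec& rowsum, arma::uword i1, arma::uword i2,
                            arma::uword j) {
  const double p1 = P(i1, j), p2 = P(i2, j);
  const double r1 = rowsum(i1) - a(i1), r2 = rowsum(i2) - a(i2);
  const double dC = C(i1, j) - C(i2, j);
  auto f = [&](double t) {
    double u = p1 + t, v = p2 - t;
    double ent = 0.0;
    if (u > 0) ent += u * std::log(u);
    if (v > 0) ent += v * std::log(v);
    return dC * t - eps * ent + tau * (r1 + t) * (r1 + t) +
           tau * (r2 - t) * (r2 - t);
  };
  auto psi = [&](double t) { // df/dt
    double u = std::max(p1 + t, P_FLOOR), v = std::max(p2 - t, P_FLOOR);
    return dC - eps * (std::log(u) - std::log(v)) +
           2.0 * tau * (r1 + t) + 2.0 * tau * (t - r2);
  };
  const double S = p1 + p2;
  double bestT = 0.0, f0 = f(0.0), bestF = f0;
  auto consider = [&](double t) {
    if (t < -p1) t = -p1;
    if (t > p2) t = p2;
    double v = f(t);
    if (v < bestF - 1e-15) { bestF = v; bestT = t; }
  };
  consider(-p1);
  consider(p2);
  if (S > eps / tau) {
    // psi is increasing for u in (u-, u+): bracket the interior root there
    double disc = std::sqrt(std::max(S * S - eps * S / tau, 0.0));
    double lo = -p1 + 0.5 * (S - disc), hi = -p1 + 0.5 * (S + disc);
    if (psi(lo) < 0.0 && psi(hi) > 0.0) {
      double aT = lo, bT = hi;
      for (int k = 0; k < 80; ++k) {
        double mid = 0.5 * (aT + bT);
        if (psi(mid) < 0.0) aT = mid; else bT = mid;
      }
      consider(0.5 * (aT + bT));
    }
  }
  if (bestT != 0.0) {
    P(i1, j) = p1 + bestT;
    P(i2, j) = p2 - bestT;
    rowsum(i1) += bestT;
    rowsum(i2) -= bestT;
    return f0 - bestF;
  }
  return 0.0;
}

// column-wise exchange phase: escapes L1-kink stalls where improving needs
// a joint move that leaves the column sum unchanged
static double exchange_sweep(arma::mat& P, const arma::mat& C,
                             const arma::vec& a, const arma::vec& b,
                             double eps, double tau, arma::vec& rowsum) {
  const arma::uword n = P.n_rows, m = P.n_cols;
  double gain = 0.0;
  if (n < 2) return 0.0;
  if (n <= 24) {
    // small problems: exact transfers over every row pair of every column
    // (the heuristic below scores pairs without the entropy term and can
    // stall when scores are within eps of each other)
    for (int pass = 0; pass < 8; ++pass) {
      double g = 0.0;
      for (arma::uword j = 0; j < m; ++j)
        for (arma::uword i1 = 0; i1 < n; ++i1)
          for (arma::uword i2 = i1 + 1; i2 < n; ++i2) {
            if (P(i1, j) <= 2.0 * P_FLOOR && P(i2, j) <= 2.0 * P_FLOOR)
              continue;
            g += pair_transfer(P, C, a, eps, tau, rowsum, i1, i2, j);
          }
      gain += g;
      if (g <= 1e-14) break;
    }
    return gain;
  }
  for (arma::uword j = 0; j < m; ++j) {
    for (int pass = 0; pass < 8; ++pass) {
      // score increasing each entry a finite amount (entropy left out: it is
      // bounded by eps/e and the exact transfer re-checks the objective)
      arma::uword iRec = 0, iDon = 0;
      double hMin = arma::datum::inf, hMax = -arma::datum::inf;
      for (arma::uword i = 0; i < n; ++i) {
        double h = C(i, j) + 2.0 * tau * (rowsum(i) - a(i));
        if (h < hMin) { hMin = h; iRec = i; }
        if (P(i, j) > 2.0 * P_FLOOR && h > hMax) { hMax = h; iDon = i; }
      }
      if (!(hMax > hMin) || iRec == iDon) break;
      double g = pair_transfer(P, C, a, eps, tau, rowsum, iRec, iDon, j);
      gain += g;
      if (g <= 1e-14) break;
    }
  }
  return gain;
}

// stepping-stone cycle phase: transfers delta around (i1,j1)->(i1,j2)->
// (i2,j2)->(i2,j1), which leaves every row and column sum unchanged, so both
// marginal penalties drop out.  Needed to reach the optimal vertex when the
// penalties are stiff (the balanced-OT limit).
static double cycle_sweep(arma::mat& P, const arma::mat& C,
                          double eps, double tau) {
  const arma::uword n = P.n_rows, m = P.n_cols;
  if (n < 2 || m < 2) return 0.0;
  double gain = 0.0;
  auto ent = [&](double p) { return (p > 0.0) ? p * std::log(p) : 0.0; };
  for (arma::uword j1 = 0; j1 + 1 < m; ++j1) {
    for (arma::uword j2 = j1 + 1; j2 < m; ++j2) {
      for (int pass = 0; pass < 4; ++pass) {
        // d_i = C(i,j1) - C(i,j2); gain rate of the cycle is d_i1 - d_i2
        double dMin = arma::datum::inf, dMax = -arma::datum::inf;
        arma::uword i1 = 0, i2 = 0;
        bool f1 = false, f2 = false;
        for (arma::uword i = 0; i < n; ++i) {
          double d = C(i, j1) - C(i, j2);
          if (P(i, j2) > 2.0 * P_FLOOR && d < dMin) { dMin = d; i1 = i; f1 = true; }
          if (P(i, j1) > 2.0 * P_FLOOR && d > dMax) { dMax = d; i2 = i; f2 = true; }
        }
        if (!f1 || !f2 || i1 == i2 || dMin - dMax >= 0.0) break;
        const double hi = std::min(P(i1, j2), P(i2, j1));
        if (hi <= 0.0) break;
        const double rate = dMin - dMax;   // negative: descent direction
        auto f = [&](double t) {
          return rate * t -
            eps * (ent(P(i1, j1) + t) + ent(P(i1, j2) - t) +
                   ent(P(i2, j2) + t) + ent(P(i2, j1) - t));
        };
        // entropy is a small smooth perturbation: endpoint vs golden section
        double bestT = 0.0, bestF = 0.0;
        double lo = 0.0, up = hi;
        double g1 = up - (up - lo) / 1.61803398875, g2 = lo + (up - lo) / 1.61803398875;
        for (int k = 0; k < 60; ++k) {
          if (f(g1) < f(g2)) { up = g2; g2 = g1; g1 = up - (up - lo) / 1.61803398875; }
          else { lo = g1; g1 = g2; g2 = lo + (up - lo) / 1.61803398875; }
        }
        for (double t : {hi, 0.5 * (lo + up)}) {
          double v = f(t);
          if (v < bestF - 1e-15) { bestF = v; bestT = t; }
        }
        if (bestT <= 0.0) break;
        P(i1, j1) += bestT; P(i1, j2) -= bestT;
        P(i2, j2) += bestT; P(i2, j1) -= bestT;
        gain -= bestF;
      }
    }
  }
  return gain;
}

// exact 1-D minimisation of rate * t - eps * sum entropies along a cycle
static double cycle_line_search(const std::vector<double>& plus,
                                const std::vector<double>& minus,
                                double rate, double eps, double hi) {
  auto ent = [&](double p) { return (p > 0.0) ? p * std::log(p) : 0.0; };
  auto f = [&](double t) {
    double s = rate * t;
    for (double p : plus) s -= eps * ent(p + t);
    for (double p : minus) s -= eps * ent(p - t);
    return s;
  };
  double lo = 0.0, up = hi;
  double g1 = up - (up - lo) / 1.61803398875, g2 = lo + (up - lo) / 1.61803398875;
  for (int k = 0; k < 60; ++k) {
    if (f(g1) < f(g2)) { up = g2; g2 = g1; g1 = up - (up - lo) / 1.61803398875; }
    else { lo = g1; g1 = g2; g2 = lo + (up - lo) / 1.61803398875; }
  }
  double bestT = 0.0, bestF = 0.0;
  for (double t : {hi, 0.5 * (lo + up)}) {
    double v = f(t);
    if (v < bestF - 1e-15) { bestF = v; bestT = t; }
  }
  return bestT;
}

// length-6 stepping-stone cycles (three rows, three columns); together with
// the length-4 cycles this covers every simple cycle of a 3x3 plan, so the
// stiff-penalty (balanced) limit can reach the optimal transport vertex.
// Only run on small plans: the neighbourhood is O((nm)^3).
static double cycle6_sweep(arma::mat& P, const arma::mat& C, double eps) {
  const arma::uword n = P.n_rows, m = P.n_cols;
  if (n < 3 || m < 3 || n > 8 || m > 8) return 0.0;
  double gain = 0.0;
  auto ent = [&](double p) { return (p > 0.0) ? p * std::log(p) : 0.0; };
  for (arma::uword i1 = 0; i1 < n; ++i1)
  for (arma::uword i2 = 0; i2 < n; ++i2)
  for (arma::uword i3 = 0; i3 < n; ++i3) {
    if (i1 == i2 || i1 == i3 || i2 == i3) continue;
    for (arma::uword j1 = 0; j1 < m; ++j1)
    for (arma::uword j2 = 0; j2 < m; ++j2)
    for (arma::uword j3 = 0; j3 < m; ++j3) {
      if (j1 == j2 || j1 == j3 || j2 == j3) continue;
      // +(i1,j1) -(i1,j2) +(i2,j2) -(i2,j3) +(i3,j3) -(i3,j1)
      double rate = C(i1, j1) - C(i1, j2) + C(i2, j2) - C(i2, j3) +
                    C(i3, j3) - C(i3, j1);
      if (rate >= 0.0) continue;
      double hi = std::min({P(i1, j2), P(i2, j3), P(i3, j1)});
      if (hi <= 2.0 * P_FLOOR) continue;
      std::vector<double> plus = {P(i1, j1), P(i2, j2), P(i3, j3)};
      std::vector<double> minus = {P(i1, j2), P(i2, j3), P(i3, j1)};
      double t = cycle_line_search(plus, minus, rate, eps, hi);
      if (t <= 0.0) continue;
      double delta = rate * t;
      for (double p : plus) delta -= eps * (ent(p + t) - ent(p));
      for (double p : minus) delta -= eps * (ent(p - t) - ent(p));
      P(i1, j1) += t; P(i1, j2) -= t;
      P(i2, j2) += t; P(i2, j3) -= t;
      P(i3, j3) += t; P(i3, j1) -= t;
      gain -= delta;
    }
  }
  return gain;
}

static UotResult uot_descend(arma::mat P, const arma::mat& C,
                             const arma::vec& a, const arma::vec& b,
                             double eps, double tau, double tol, int max_iter) {
  double F = uot_objective(P, C, a, b, eps, tau);
  double step = 1.0;
  int it = 0;
  bool converged = false;
  for (int outer = 0; outer < 40 && it < max_iter; ++outer) {
    const double Fouter = F;
    // mirror-descent phase: multiplicative updates with backtracking
    while (it < max_iter) {
      arma::mat G = uot_gradient(P, C, a, b, eps, tau);
      bool accepted = false;
      double Fn = F;
      arma::mat Pn;
      for (int bt = 0; bt < 60; ++bt) {
        arma::mat E = arma::clamp(-step * G, -50.0, 50.0);
        Pn = P % arma::exp(E);
        Pn.clamp(P_FLOOR, arma::datum::inf);
        Fn = uot_objective(Pn, C, a, b, eps, tau);
        if (Fn <= F) { accepted = true; break; }
        step *= 0.5;
        if (step < 1e-16) break;
      }
      if (!accepted) break;                 // stalled (e.g. at an L1 kink)
      double drop = F - Fn;
      P = Pn;
      F = Fn;
      ++it;
      step = std::min(step * 1.5, 1e6);
      if (drop <= tol * std::max(1.0, std::abs(F))) break;
    }
    // proximal polish phase: exact 1-D coordinate minimisation sweeps
    arma::vec rowsum = arma::sum(P, 1);
    arma::vec colsum = arma::sum(P, 0).t();
    while (it < max_iter) {
      double gain = coord_sweep(P, C, a, b, eps, tau, rowsum, colsum);
      gain += exchange_sweep(P, C, a, b, eps, tau, rowsum);
      gain += cycle_sweep(P, C, eps, tau);
      gain += cycle6_sweep(P, C, eps);
      ++it;
      if (gain <= tol * std::max(1.0, std::abs(F))) break;
    }
    F = uot_objective(P, C, a, b, eps, tau);
    step = std::max(step, 1e-3);
    if (Fouter - F <= tol * std::max(1.0, std::abs(F))) {
      converged = true;
      break;
    }
  }
  UotResult res;
  res.P = P;
  res.objective = F;
  res.iterations = it;
  res.converged = converged;
  return res;
}

// [[Rcpp::export(name = ".uot_solve_cpp")]]
Rcpp::List uot_solve_cpp(const arma::vec& a, const arma::vec& b,
                         const arma::mat& C, double eps, double tau,
                         double tol, int max_iter) {
  const arma::uword n = a.n_elem, m = b.n_elem;
  if (C.n_rows != n || C.n_cols != m)
    Rcpp::stop("cost matrix dimensions do not match the marginals");

  double sa = arma::accu(a), sb = arma::accu(b);
  // Degenerate all-zero mass: the zero plan is optimal with objective 0.
  if (sa <= 0.0 && sb <= 0.0) {
    return Rcpp::List::create(
      Rcpp::Named("plan") = arma::mat(n, m, arma::fill::zeros),
      Rcpp::Named("objective") = 0.0,
      Rcpp::Named("iterations") = 0,
      Rcpp::Named("converged") = true);
  }

  double scale = (sa + sb) / 2.0;
  if (scale <= 0.0) scale = 1.0;

  std::vector<arma::mat> inits;
  // product coupling (plus a floor so zero rows/columns can still receive mass)
  arma::mat P0 = (a + 1e-3 * scale / n) * (b + 1e-3 * scale / m).t();
  double s0 = arma::accu(P0);
  if (s0 > 0) P0 *= scale / s0;
  inits.push_back(P0);
  // uniform at the problem's mass scale
  inits.push_back(arma::mat(n, m, arma::fill::value(scale / double(n * m))));
  // near-empty plan (lets mass grow only where it pays)
  inits.push_back(arma::mat(n, m, arma::fill::value(1e-6 * scale / double(n * m))));

  UotResult best;
  bool have = false;
  for (auto& Pi : inits) {
    Pi.clamp(P_FLOOR, arma::datum::inf);
    UotResult r = uot_descend(Pi, C, a, b, eps, tau, tol, max_iter);
    if (!have || r.objective < best.objective) { best = r; have = true; }
  }
  // report near-floor entries as exact zeros
  best.P.elem(arma::find(best.P <= 2.0 * P_FLOOR)).zeros();
  return Rcpp::List::create(
    Rcpp::Named("plan") = best.P,
    Rcpp::Named("objective") = best.objective,
    Rcpp::Named("iterations") = best.iterations,
    Rcpp::Named("converged") = best.converged);
}
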