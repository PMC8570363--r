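// Multi-block ADMM core for integrative generalized convex clustering with
// feature selection.
//
// Outer iteration (one-step inexact scheme): for each view take a single
// sub-problem update -- smooth losses get a majorized quadratic update
// (exact solve in the metric pi*L*I + rho*D'D [+ rho*I], with L an adaptive
// per-view curvature bound; for the Euclidean loss L = 1 and the update is
// the exact sub-problem solution), non-differentiable distance losses get
// one sweep of the four-variable splitting with M = (D'D + 2I)^{-1} --
// followed by the joint fusion-variable block soft-threshold and dual
// ascent.  With inner_steps > 1 the sub-problems are iterated to an inner
// tolerance instead, giving the full (reference) ADMM.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

enum Family { EUCLIDEAN = 0, POISSON_LL = 1, POISSON_DEV = 2,
              BERNOULLI_LL = 3, BINOMIAL_DEV = 4, NEGBIN_LL = 5,
              NEGBIN_DEV = 6, MANHATTAN = 10, CHEBYCHEV = 11 };

static inline bool is_smooth(int fam) { return fam < 10; }

// clamp mean-scale deviance parameters into their admissible domain
static void clamp_domain(int fam, mat& U) {
  if (fam == POISSON_DEV || fam == NEGBIN_DEV)
    U = clamp(U, 1e-8, datum::inf);
  else if (fam == BINOMIAL_DEV)
    U = clamp(U, 1e-8, 1.0 - 1e-8);
}

// ---- elementwise losses (smooth families) ----

static double eval_loss(int fam, double theta, const mat& X, const mat& U) {
  double s = 0.0;
  const uword nn = X.n_elem;
  for (uword i = 0; i < nn; ++i) {
    double xi = X(i), ui = U(i);
    switch (fam) {
    case EUCLIDEAN: { double d = xi - ui; s += 0.5 * d * d; break; }
    case POISSON_LL: s += -xi * ui + std::exp(std::min(ui, 700.0)); break;
    case POISSON_DEV:
      if (ui <= 0.0) return datum::inf;
      s += (xi > 0.0 ? xi * std::log(xi / ui) : 0.0) - xi + ui;
      break;
    case BERNOULLI_LL:
      s += -xi * ui + (ui > 0.0 ? ui + std::log1p(std::exp(-ui))
                                : std::log1p(std::exp(ui)));
      break;
    case BINOMIAL_DEV:
      if (ui <= 0.0 || ui >= 1.0) return datum::inf;
      s += (xi > 0.0 ? xi * std::log(xi / ui) : 0.0) +
           (xi < 1.0 ? (1.0 - xi) * std::log((1.0 - xi) / (1.0 - ui)) : 0.0);
      break;
    case NEGBIN_LL: {
      double it = 1.0 / theta;
      double lse = (ui > 30.0) ? ui + std::log1p(it * std::exp(-ui))
                               : std::log(it + std::exp(ui));
      s += -xi * ui + (xi + it) * lse;
      break;
    }
    case NEGBIN_DEV:
      if (ui <= 0.0) return datum::inf;
      s += (xi > 0.0 ? xi * std::log(xi / ui) : 0.0) -
           (xi + 1.0 / theta) *
             std::log((1.0 + theta * xi) / (1.0 + theta * ui));
      break;
    }
  }
  return s;
}

static void grad_mat(int fam, double theta, const mat& X, const mat& U,
                     mat& G) {
  switch (fam) {
  case EUCLIDEAN: G = U - X; break;
  case POISSON_LL: G = -X + exp(clamp(U, -700.0, 700.0)); break;
  case POISSON_DEV: G = 1.0 - X / U; break;
  case BERNOULLI_LL: G = -X + 1.0 / (1.0 + exp(-clamp(U, -700.0, 700.0)));
    break;
  case BINOMIAL_DEV: G = -X / U + (1.0 - X) / (1.0 - U); break;
  case NEGBIN_LL: {
    mat eu = exp(clamp(U, -700.0, 700.0));
    G = -X + (X + 1.0 / theta) % (eu / (1.0 / theta + eu));
    break;
  }
  case NEGBIN_DEV: G = -X / U + (theta * X + 1.0) / (1.0 + theta * U); break;
  }
}

// ---- proximal pieces ----

// rowwise projection onto the l1 ball of radius r (for the Chebychev prox)
static rowvec proj_l1(const rowvec& a, double r) {
  if (accu(abs(a)) <= r) return a;
  vec u = sort(abs(a).t(), "descend");
  vec cs = cumsum(u);
  uword k = 0;
  for (uword j = 0; j < u.n_elem; ++j)
    if (u(j) > (cs(j) - r) / double(j + 1)) k = j;
  double tau = (cs(k) - r) / double(k + 1);
  return sign(a) % max(abs(a) - tau, zeros<rowvec>(a.n_elem));
}

static void prox_dist(int fam, mat& Z, const mat& A, double t) {
  if (t <= 0.0) { Z = A; return; }
  if (fam == MANHATTAN) {
    Z = sign(A) % max(abs(A) - t, zeros<mat>(A.n_rows, A.n_cols));
  } else {  // CHEBYCHEV: Moreau decomposition via l1-ball projection
    Z.set_size(A.n_rows, A.n_cols);
    for (uword i = 0; i < A.n_rows; ++i)
      Z.row(i) = A.row(i) - proj_l1(A.row(i), t);
  }
}

// columnwise block soft-threshold with per-column thresholds (around 0)
static void prox_cols(mat& R, const mat& A, const vec& t) {
  for (uword j = 0; j < A.n_cols; ++j) {
    double nrm = norm(A.col(j), 2);
    double scl = (nrm > t(j)) ? (1.0 - t(j) / nrm) : 0.0;
    R.col(j) = scl * A.col(j);
  }
}

// rowwise block soft-threshold with per-row thresholds
static void prox_row_groups(mat& V, const mat& A, const vec& t) {
  V.set_size(A.n_rows, A.n_cols);
  for (uword l = 0; l < A.n_rows; ++l) {
    double nrm = norm(A.row(l), 2);
    double scl = (nrm > t(l)) ? (1.0 - t(l) / nrm) : 0.0;
    V.row(l) = scl * A.row(l);
  }
}

// ---- difference operator (edge list form) ----

static mat Dmul(const umat& E, const mat& U) {
  mat DU(E.n_rows, U.n_cols, fill::none);
  for (uword l = 0; l < E.n_rows; ++l)
    DU.row(l) = U.row(E(l, 0)) - U.row(E(l, 1));
  return DU;
}

static mat Dtmul(const umat& E, const mat& A, uword n) {
  mat R(n, A.n_cols, fill::zeros);
  for (uword l = 0; l < E.n_rows; ++l) {
    R.row(E(l, 0)) += A.row(l);
    R.row(E(l, 1)) -= A.row(l);
  }
  return R;
}

// [[Rcpp::export(name = ".cc_admm_cpp")]]
Rcpp::List cc_admm_cpp(const Rcpp::List& Xs, const Rcpp::IntegerVector& fam,
                       const Rcpp::NumericVector& theta,
                       const Rcpp::NumericVector& pis,
                       const Rcpp::List& centers, const Rcpp::List& zetas,
                       const arma::umat& edges0, const arma::vec& w,
                       double gamma, double alpha, double rho,
                       int max_iter, double tol, int inner_steps,
                       double inner_tol, const Rcpp::List& init) {
  const int K = Xs.size();
  std::vector<mat> X(K), U(K), Lam(K), Z(K), Rv(K), Psi(K), N(K);
  std::vector<vec> ctr(K), zeta(K);
  uvec pk(K);
  for (int k = 0; k < K; ++k) {
    X[k] = Rcpp::as<mat>(Xs[k]);
    ctr[k] = Rcpp::as<vec>(centers[k]);
    zeta[k] = Rcpp::as<vec>(zetas[k]);
    pk(k) = X[k].n_cols;
  }
  const uword n = X[0].n_rows;
  const umat E = edges0;  // 0-based
  const uword m = E.n_rows;
  const uword ptot = accu(pk);

  uvec off(K);
  { uword o = 0; for (int k = 0; k < K; ++k) { off(k) = o; o += pk(k); } }

  std::vector<bool> useRN(K);
  bool any_nonsmooth = false;
  for (int k = 0; k < K; ++k) {
    useRN[k] = !is_smooth(fam[k]) || alpha > 0.0;
    if (!is_smooth(fam[k])) any_nonsmooth = true;
  }

  mat DtD(n, n, fill::zeros);
  for (uword l = 0; l < m; ++l) {
    DtD(E(l, 0), E(l, 0)) += 1.0; DtD(E(l, 1), E(l, 1)) += 1.0;
    DtD(E(l, 0), E(l, 1)) -= 1.0; DtD(E(l, 1), E(l, 0)) -= 1.0;
  }
  // Cholesky of (D'D + 2I), shared by all non-smooth views
  mat Mchol;
  if (any_nonsmooth) {
    mat Q = DtD;
    Q.diag() += 2.0;
    Mchol = chol(Q);
  }
  // curvature bounds and factors for the smooth-view updates
  std::vector<double> L(K, 1.0);
  for (int k = 0; k < K; ++k) if (fam[k] == BERNOULLI_LL) L[k] = 0.25;
  std::vector<mat> cholS(K);
  auto refactor = [&](int k, double rho_now) {
    mat Q = rho_now * DtD;
    Q.diag() += pis[k] * L[k] + (alpha > 0.0 ? rho_now : 0.0);
    cholS[k] = chol(Q);
  };
  for (int k = 0; k < K; ++k) if (is_smooth(fam[k])) refactor(k, rho);

  std::vector<mat> Ctrm(K);
  for (int k = 0; k < K; ++k) {
    Ctrm[k].set_size(n, pk(k));
    for (uword j = 0; j < pk(k); ++j) Ctrm[k].col(j).fill(ctr[k](j));
  }

  mat V(m, ptot, fill::zeros);
  bool warm = init.size() > 0;
  if (warm) {
    if (init.containsElementNamed("rho")) {
      double r0 = Rcpp::as<double>(init["rho"]);
      if (r0 > 1e-6 && r0 < 1e8) {
        rho = r0;
        for (int k = 0; k < K; ++k) if (is_smooth(fam[k])) refactor(k, rho);
      }
    }
    Rcpp::List iU = init["U"], iL = init["Lambda"];
    V = Rcpp::as<mat>(init["V"]);
    for (int k = 0; k < K; ++k) {
      U[k] = Rcpp::as<mat>(iU[k]);
      Lam[k] = Rcpp::as<mat>(iL[k]);
    }
    if (init.containsElementNamed("Z")) {
      Rcpp::List iZ = init["Z"], iR = init["R"], iP = init["Psi"],
                 iN = init["N"];
      for (int k = 0; k < K; ++k) {
        if (!is_smooth(fam[k]) && iZ.size() > k && !Rf_isNull(iZ[k])) {
          Z[k] = Rcpp::as<mat>(iZ[k]);
          Psi[k] = Rcpp::as<mat>(iP[k]);
        }
        if (useRN[k] && iR.size() > k && !Rf_isNull(iR[k])) {
          Rv[k] = Rcpp::as<mat>(iR[k]);
          N[k] = Rcpp::as<mat>(iN[k]);
        }
      }
    }
  }
  for (int k = 0; k < K; ++k) {
    if (!warm || U[k].n_rows == 0) {
      U[k] = X[k];
      if (fam[k] == POISSON_DEV || fam[k] == NEGBIN_DEV)
        U[k] = clamp(U[k], 1e-3, datum::inf);
      if (fam[k] == BINOMIAL_DEV) U[k] = clamp(U[k], 1e-3, 1.0 - 1e-3);
      Lam[k].zeros(m, pk(k));
    } else {
      clamp_domain(fam[k], U[k]);
    }
    if (!is_smooth(fam[k]) && Z[k].n_rows == 0) {
      Z[k].zeros(n, pk(k)); Psi[k].zeros(n, pk(k));
    }
    if (useRN[k] && Rv[k].n_rows == 0) {
      N[k].zeros(n, pk(k));
      Rv[k] = U[k] - Ctrm[k];
    }
  }

  double rel_p = datum::inf, rel_d = datum::inf;
  int it = 0;
  bool converged = false;
  // primal scale floor at 1% of the data norm so that the criterion is
  // attainable when V (and DU) vanish in the fully fused regime
  double x_sc = 0.0, g_sc = 0.0;
  for (int k = 0; k < K; ++k) {
    x_sc += accu(square(X[k]));
    g_sc += pis[k] * pis[k] * accu(square(X[k]));
  }
  const double sc_floor = 0.01 * std::sqrt(x_sc) + 1e-12;
  const double du_floor = 0.01 * std::sqrt(g_sc) + 1e-12;

  for (it = 1; it <= max_iter; ++it) {
    mat Vold = V;
    std::vector<mat> Zold(K), Rold(K);

    for (int k = 0; k < K; ++k) {
      const double pi_k = pis[k];
      mat Vk = V.cols(off(k), off(k) + pk(k) - 1);
      if (useRN[k]) Rold[k] = Rv[k];
      if (is_smooth(fam[k])) {
        // majorized quadratic update; for Euclidean (L = 1) this solves the
        // penalized sub-problem exactly
        int steps = inner_steps;
        for (int s_i = 0; s_i < steps; ++s_i) {
          mat Uprev = U[k];
          double f0 = eval_loss(fam[k], theta[k], X[k], U[k]);
          mat G;
          grad_mat(fam[k], theta[k], X[k], U[k], G);
          mat Bfix = rho * Dtmul(E, Vk - Lam[k], n);
          if (alpha > 0.0) Bfix += rho * (Ctrm[k] + Rv[k] - N[k]);
          for (int bt = 0; bt < 60; ++bt) {
            mat B = Bfix + pi_k * (L[k] * U[k] - G);
            mat Unew = solve(trimatu(cholS[k]),
                             solve(trimatl(cholS[k].t()), B));
            if (fam[k] == EUCLIDEAN) { U[k] = Unew; break; }
            // curvature-bound (majorization) check on the loss alone
            mat d = Unew - Uprev;
            double f1 = eval_loss(fam[k], theta[k], X[k], Unew);
            double bound = f0 + accu(G % d) +
                           0.5 * L[k] * accu(square(d)) + 1e-10;
            if (std::isfinite(f1) && f1 <= bound) { U[k] = Unew; break; }
            if (L[k] > 1e8) {
              // numerical safeguard for domain-constrained losses: project
              // the candidate into the domain instead of growing L further
              clamp_domain(fam[k], Unew);
              U[k] = Unew;
              break;
            }
            L[k] *= 2.0;
            refactor(k, rho);
          }
          if (alpha > 0.0) {
            mat RA = U[k] - Ctrm[k] + N[k];
            prox_cols(Rv[k], RA, (alpha / rho) * zeta[k]);
            N[k] += U[k] - Ctrm[k] - Rv[k];
          }
          if (steps > 1 && norm(U[k] - Uprev, "fro") /
                (1.0 + norm(Uprev, "fro")) < inner_tol) break;
        }
      } else {
        // one sweep (or inner iterations) of the four-variable splitting
        Zold[k] = Z[k];
        int steps = inner_steps;
        for (int s_i = 0; s_i < steps; ++s_i) {
          mat B = Dtmul(E, Vk - Lam[k], n) + Ctrm[k] + Rv[k] - N[k] +
                  X[k] - Z[k] + Psi[k];
          mat Uprev = U[k];
          U[k] = solve(trimatu(Mchol), solve(trimatl(Mchol.t()), B));
          prox_dist(fam[k], Z[k], X[k] - U[k] + Psi[k], pi_k / rho);
          mat RA = U[k] - Ctrm[k] + N[k];
          prox_cols(Rv[k], RA, (alpha / rho) * zeta[k]);
          Psi[k] += X[k] - U[k] - Z[k];
          N[k] += U[k] - Ctrm[k] - Rv[k];
          if (steps > 1 && norm(U[k] - Uprev, "fro") /
                (1.0 + norm(Uprev, "fro")) < inner_tol) break;
        }
        if (!U[k].is_finite())
          Rcpp::stop("divergence in non-smooth view update; reduce rho");
      }
    }

    // joint fusion-variable update over the stacked views
    mat A(m, ptot, fill::none);
    std::vector<mat> DUs(K);
    for (int k = 0; k < K; ++k) {
      DUs[k] = Dmul(E, U[k]);
      A.cols(off(k), off(k) + pk(k) - 1) = DUs[k] + Lam[k];
    }
    if (m > 0) prox_row_groups(V, A, (gamma / rho) * w);

    double pr2 = 0.0, du2 = 0.0, sc_p = sc_floor, du_sc2 = 0.0;
    for (int k = 0; k < K; ++k) {
      mat Vk = V.cols(off(k), off(k) + pk(k) - 1);
      mat rk = DUs[k] - Vk;
      Lam[k] += rk;
      pr2 += accu(square(rk));
      sc_p = std::max(sc_p, std::max(norm(DUs[k], "fro"), norm(Vk, "fro")));
      mat dVk = Vk - Vold.cols(off(k), off(k) + pk(k) - 1);
      du2 += accu(square(rho * Dtmul(E, dVk, n)));
      du_sc2 += accu(square(rho * Dtmul(E, Lam[k], n)));
      if (!is_smooth(fam[k])) {
        pr2 += accu(square(X[k] - U[k] - Z[k]));
        du2 += accu(square(rho * (Z[k] - Zold[k])));
        du_sc2 += accu(square(rho * Psi[k]));
        sc_p = std::max(sc_p, norm(X[k], "fro"));
      }
      if (useRN[k]) {
        pr2 += accu(square(U[k] - Ctrm[k] - Rv[k]));
        du2 += accu(square(rho * (Rv[k] - Rold[k])));
        du_sc2 += accu(square(rho * N[k]));
        sc_p = std::max(sc_p, norm(U[k], "fro"));
      }
    }
    rel_p = std::sqrt(pr2) / sc_p;
    // dual residual relative to the dual-variable magnitude ||A' y||
    rel_d = std::sqrt(du2) / std::max(du_floor, std::sqrt(du_sc2));
    if (rel_p < tol && rel_d < tol) { converged = true; break; }
    // residual balancing: keep primal and dual residuals within a decade
    // of each other (scaled duals are rescaled when rho changes)
    if (it % 10 == 0) {
      double tau = 0.0;
      if (rel_p > 10.0 * rel_d) tau = 2.0;
      else if (rel_d > 10.0 * rel_p) tau = 0.5;
      if (tau != 0.0 && rho * tau > 1e-6 && rho * tau < 1e8) {
        rho *= tau;
        for (int k = 0; k < K; ++k) {
          Lam[k] /= tau;
          if (!is_smooth(fam[k])) Psi[k] /= tau;
          if (useRN[k]) N[k] /= tau;
          if (is_smooth(fam[k])) refactor(k, rho);
        }
      }
    }
  }
  if (it > max_iter) it = max_iter;

  Rcpp::List Uo(K), Lo(K), Zo(K), Ro(K), Po(K), No(K);
  for (int k = 0; k < K; ++k) {
    Uo[k] = U[k]; Lo[k] = Lam[k];
    Zo[k] = R_NilValue; Ro[k] = R_NilValue;
    Po[k] = R_NilValue; No[k] = R_NilValue;
    if (!is_smooth(fam[k])) { Zo[k] = Z[k]; Po[k] = Psi[k]; }
    if (useRN[k]) { Ro[k] = Rv[k]; No[k] = N[k]; }
  }
  return Rcpp::List::create(
    Rcpp::Named("U") = Uo, Rcpp::Named("V") = V, Rcpp::Named("Lambda") = Lo,
    Rcpp::Named("Z") = Zo, Rcpp::Named("R") = Ro, Rcpp::Named("Psi") = Po,
    Rcpp::Named("N") = No, Rcpp::Named("objective") = 0.0,
    Rcpp::Named("iter") = it, Rcpp::Named("converged") = converged,
    Rcpp::Named("primal") = rel_p, Rcpp::Named("dual") = rel_d,
    Rcpp::Named("rho") = rho);
}
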