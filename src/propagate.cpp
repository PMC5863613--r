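// Fixed-step RK4 propagators for exciton dynamics.
//
// All quantities enter in consistent units: Hamiltonians as angular
// frequencies (rad/fs), rates in fs^-1, time steps in fs. The effective
// Hamiltonian is complex symmetric (real symmetric system part plus
// anti-Hermitian diagonal trapping/loss), and is expected to be shifted by
// its mean site energy by the caller; the shift is a global phase that
// leaves the density matrix untouched but keeps the RK4 step well inside
// its stability region.
//
// For a single Drude exponential per site every auxiliary density operator
// (ADO) remains Hermitian along the whole trajectory: each term of the
// hierarchy maps Hermitian inputs to Hermitian outputs. The system
// commutator is therefore evaluated from a single matrix product,
// D = -i (M - M^H) with M = H_eff A, and that product is batched over all
// ADOs as one (n x n) * (n x n*K) BLAS gemm.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

using namespace arma;

typedef std::complex<double> cxd;
static const cxd I_UNIT(0.0, 1.0);

// [[Rcpp::export]]
Rcpp::List cpp_propagate_unitary_sink(const arma::cx_mat& Heff,
                                      const arma::cx_mat& rho0,
                                      double dt, int n_steps, int store_every,
                                      double tail_tol) {
  const int n = Heff.n_rows;
  cx_mat HeffH = Heff.t();
  cx_mat rho = rho0, k1(n, n), k2(n, n), k3(n, n), k4(n, n), tmp(n, n);
  auto deriv = [&](const cx_mat& r, cx_mat& out) {
    out = -I_UNIT * (Heff * r - r * HeffH);
  };

  const int n_store = n_steps / store_every + 1;
  mat pops(n_store, n);
  vec total(n_store), times(n_store);
  int js = 0;
  auto record = [&](int step) {
    times(js) = step * dt;
    vec d = real(rho.diag());
    pops.row(js) = d.t();
    total(js) = accu(d);
    ++js;
  };
  record(0);

  bool unstable = false;
  for (int step = 0; step < n_steps; ++step) {
    deriv(rho, k1);
    tmp = rho + (0.5 * dt) * k1; deriv(tmp, k2);
    tmp = rho + (0.5 * dt) * k2; deriv(tmp, k3);
    tmp = rho + dt * k3;         deriv(tmp, k4);
    rho += (dt / 6.0) * (k1 + 2.0 * k2 + 2.0 * k3 + k4);
    if ((step + 1) % store_every == 0) {
      record(step + 1);
      double tot = total(js - 1);
      if (!std::isfinite(tot) || tot > 1.0 + 1e-3) { unstable = true; break; }
      if (tot < tail_tol) break;
    }
  }

  times.resize(js); total.resize(js); pops.resize(js, n);
  return Rcpp::List::create(Rcpp::Named("times") = times,
                            Rcpp::Named("pops") = pops,
                            Rcpp::Named("total") = total,
                            Rcpp::Named("unstable") = unstable);
}

// Scaled hierarchical equations of motion with one Drude mode per site and
// an optional time-local (Ishizaki-Tanimura) correction for the dropped
// Matsubara terms:
//
//   dA_n/dt = -i [Heff A_n - A_n Heff^dag] - (sum_m n_m) nu A_n
//             - Delta sum_m [V_m, [V_m, A_n]]
//             - i sum_m sqrt((n_m + 1) |c|) [V_m, A_{n + e_m}]
//             - i sum_m sqrt(n_m / |c|) (c V_m A_{n - e_m} - c* A_{n - e_m} V_m)
//
// with V_m = |m><m| and c = lambda nu (cot(beta nu / 2) - i).
struct HeomWork {
  cx_mat Heff;
  const imat* up; const imat* dn;   // K x n, 0-based ADO position or -1
  vec damp;                         // nu * depth per ADO
  const mat* s_up; const mat* s_dn; // scaled coupling coefficients
  cxd c;
  double delta2;                    // 2 * Delta (time-local correction)
  int n, K;
  cx_mat M;                         // scratch: n x n*K product H * A
};

static void heom_deriv(HeomWork& w, const cx_cube& A, cx_cube& dA) {
  const int n = w.n, K = w.K;
  const size_t nn = (size_t)n * n;

  // batched system part: M = Heff * [A_1 | A_2 | ... | A_K]
  const cx_mat Acat(const_cast<cxd*>(A.memptr()), n, (size_t)n * K, false, true);
  w.M = w.Heff * Acat;

  const cxd* Mp = w.M.memptr();
  const cxd* Ap = A.memptr();
  cxd* Dp = dA.memptr();

  for (int k = 0; k < K; ++k) {
    const cxd* Ak = Ap + k * nn;
    const cxd* Mk = Mp + k * nn;
    cxd* Dk = Dp + k * nn;
    const double dk = w.damp(k);
    // D = -i (M - M^H) - damp A - delta2 * (A off-diagonal)
    for (int j = 0; j < n; ++j) {
      for (int i = 0; i < n; ++i) {
        cxd comm = Mk[i + j * n] - std::conj(Mk[j + i * n]);
        cxd a = Ak[i + j * n];
        Dk[i + j * n] = -I_UNIT * comm - dk * a - (i == j ? 0.0 : w.delta2) * a;
      }
    }
    // hierarchy couplings: O(n) row/column updates per site
    for (int m = 0; m < n; ++m) {
      int ku = (*w.up)(k, m);
      if (ku >= 0) {
        cxd s = -I_UNIT * (*w.s_up)(k, m);
        const cxd* Au = Ap + (size_t)ku * nn;
        for (int j = 0; j < n; ++j) Dk[m + j * n] += s * Au[m + j * n];
        for (int i = 0; i < n; ++i) Dk[i + m * n] -= s * Au[i + m * n];
      }
      int kd = (*w.dn)(k, m);
      if (kd >= 0) {
        const cxd* Ad = Ap + (size_t)kd * nn;
        cxd sc  = -I_UNIT * (*w.s_dn)(k, m) * w.c;
        cxd scc = -I_UNIT * (*w.s_dn)(k, m) * std::conj(w.c);
        for (int j = 0; j < n; ++j) Dk[m + j * n] += sc * Ad[m + j * n];
        for (int i = 0; i < n; ++i) Dk[i + m * n] -= scc * Ad[i + m * n];
      }
    }
  }
}

// [[Rcpp::export]]
Rcpp::List cpp_propagate_heom(const arma::cx_mat& Heff,
                              const arma::imat& up, const arma::imat& dn,
                              const arma::vec& damp,
                              const arma::mat& s_up, const arma::mat& s_dn,
                              std::complex<double> c_coef, double delta_tl,
                              const arma::cx_mat& rho0,
                              double dt, int n_steps, int store_every,
                              double tail_tol, double ado_norm_cap) {
  const int n = Heff.n_rows;
  const int K = up.n_rows;
  HeomWork w;
  w.Heff = Heff; w.up = &up; w.dn = &dn; w.damp = damp;
  w.s_up = &s_up; w.s_dn = &s_dn; w.c = c_coef; w.delta2 = 2.0 * delta_tl;
  w.n = n; w.K = K; w.M.set_size(n, (size_t)n * K);

  cx_cube A(n, n, K, fill::zeros);
  A.slice(0) = rho0;
  cx_cube k1(n, n, K), k2(n, n, K), k3(n, n, K), k4(n, n, K), tmp(n, n, K);

  const int n_store = n_steps / store_every + 1;
  mat pops(n_store, n);
  vec total(n_store), times(n_store);
  int js = 0;
  auto record = [&](int step) {
    times(js) = step * dt;
    vec d = real(A.slice(0).diag());
    pops.row(js) = d.t();
    total(js) = accu(d);
    ++js;
  };
  record(0);

  bool unstable = false, diverged = false;
  for (int step = 0; step < n_steps; ++step) {
    heom_deriv(w, A, k1);
    tmp = A + (0.5 * dt) * k1; heom_deriv(w, tmp, k2);
    tmp = A + (0.5 * dt) * k2; heom_deriv(w, tmp, k3);
    tmp = A + dt * k3;         heom_deriv(w, tmp, k4);
    A += (dt / 6.0) * (k1 + 2.0 * k2 + 2.0 * k3 + k4);
    if ((step + 1) % store_every == 0) {
      record(step + 1);
      double tot = total(js - 1);
      if (!std::isfinite(tot) || tot > 1.0 + 1e-3) { unstable = true; break; }
      if (abs(A).max() > ado_norm_cap) { diverged = true; break; }
      if (tot < tail_tol) break;
    }
  }

  times.resize(js); total.resize(js); pops.resize(js, n);
  return Rcpp::List::create(Rcpp::Named("times") = times,
                            Rcpp::Named("pops") = pops,
                            Rcpp::Named("total") = total,
                            Rcpp::Named("unstable") = unstable,
                            Rcpp::Named("diverged") = diverged);
}
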