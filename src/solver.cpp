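// Implicit time stepping of the (possibly two-layer) compartmental system
//   M x' = A x + b(t)
// with optional Dirichlet (voltage-clamp) rows, injected currents and
// Hodgkin-Huxley-style channels on the axolemma. Units: mV, ms, nA, uS, nF.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

static inline double rate_eval(int form, double A, double Vh, double k, double V) {
  double u = (V - Vh) / k;
  switch (form) {
  case 1: { // exp-linear A*(V-Vh)/(1-exp(-(V-Vh)/k))
    if (std::fabs(u) < 1e-6) return A * k * (1.0 + u / 2.0);
    return A * (V - Vh) / (1.0 - std::exp(-u));
  }
  case 2: return A * std::exp(u);            // exponential
  case 3: return A / (1.0 + std::exp(-u));   // sigmoid
  default: Rcpp::stop("unknown rate form");
  }
}

// [[Rcpp::export]]
Rcpp::List cpp_integrate(const arma::mat& M, const arma::mat& A,
                         const arma::vec& b0, const arma::vec& x0,
                         double dt, int nstep, int method,
                         const arma::uvec& rec_idx,
                         const arma::uvec& inj_idx, const arma::mat& inj,
                         const arma::uvec& clamp_idx, const arma::mat& clamp,
                         Rcpp::List channels, bool record_all) {
  const uword n = M.n_rows;
  const bool cn = (method == 1);

  // channel tables (may be empty)
  ivec ch_core, ch_peri; vec ch_g, ch_e; mat gates; uword ng = 0, nch = 0;
  if (channels.size() > 0) {
    ch_core = Rcpp::as<ivec>(channels["core"]);
    ch_peri = Rcpp::as<ivec>(channels["peri"]);
    ch_g    = Rcpp::as<vec>(channels["gmax"]);
    ch_e    = Rcpp::as<vec>(channels["erev"]);
    gates   = Rcpp::as<mat>(channels["gates"]);
    ng = gates.n_rows; nch = ch_g.n_elem;
  }
  const bool active = nch > 0;

  // gate state, initialised at steady state for the initial Vm
  vec gstate(ng, fill::zeros);
  auto vm_of = [&](const vec& x, uword ci) {
    double v = x(ch_core(ci));
    if (ch_peri(ci) >= 0) v -= x(ch_peri(ci));
    return v;
  };
  vec x = x0;
  for (uword g = 0; g < ng; ++g) {
    uword ci = (uword) gates(g, 0);
    double V = vm_of(x, ci);
    double a = rate_eval((int) gates(g, 2), gates(g, 3), gates(g, 4), gates(g, 5), V);
    double bb = rate_eval((int) gates(g, 6), gates(g, 7), gates(g, 8), gates(g, 9), V);
    gstate(g) = a / (a + bb);
  }

  mat LHS = M / dt - (cn ? 0.5 : 1.0) * A;
  mat RHSM = cn ? mat(M / dt + 0.5 * A) : mat(M / dt);
  for (uword j = 0; j < clamp_idx.n_elem; ++j) {
    LHS.row(clamp_idx(j)).zeros();
    LHS(clamp_idx(j), clamp_idx(j)) = 1.0;
  }

  // pre-invert when the matrix is constant across steps; the RHS multiply
  // uses the sparsity of M (and A for CN), a few nonzeros per row
  mat LHSinv;
  sp_mat RHSs;
  bool prefactored = false;
  if (!active) {
    if (!inv(LHSinv, LHS)) Rcpp::stop("singular system matrix: check conductances");
    RHSs = sp_mat(RHSM);
    prefactored = true;
  }

  const uword nrec = record_all ? n : rec_idx.n_elem;
  mat out(nstep + 1, nrec);
  auto record = [&](uword row, const vec& xx) {
    if (record_all) out.row(row) = xx.t();
    else for (uword j = 0; j < nrec; ++j) out(row, j) = xx(rec_idx(j));
  };
  record(0, x);

  vec ggates_pow(ng);
  mat LHS_step;
  for (int s = 0; s < nstep; ++s) {
    vec rhs = prefactored ? vec(RHSs * x + b0) : vec(RHSM * x + b0);
    // inj(s, j) is the current over the interval [t_s, t_{s+1}); with
    // piecewise-constant sources this is exact for both BE and CN
    for (uword j = 0; j < inj_idx.n_elem; ++j) rhs(inj_idx(j)) += inj(s, j);

    if (active) {
      LHS_step = LHS;
      // update gates (exponential Euler at current Vm), then add channel
      // conductances implicitly for the linear solve
      for (uword g = 0; g < ng; ++g) {
        uword ci = (uword) gates(g, 0);
        double V = vm_of(x, ci);
        double sc = gates(g, 10);
        double a = sc * rate_eval((int) gates(g, 2), gates(g, 3), gates(g, 4), gates(g, 5), V);
        double bb = sc * rate_eval((int) gates(g, 6), gates(g, 7), gates(g, 8), gates(g, 9), V);
        double tau = 1.0 / (a + bb), inf = a * tau;
        gstate(g) = inf + (gstate(g) - inf) * std::exp(-dt / tau);
        if (gstate(g) < 0) gstate(g) = 0;
        if (gstate(g) > 1) gstate(g) = 1;
        ggates_pow(g) = std::pow(gstate(g), gates(g, 1));
      }
      vec gch(nch, fill::ones);
      gch %= ch_g;
      for (uword g = 0; g < ng; ++g) gch((uword) gates(g, 0)) *= ggates_pow(g);
      for (uword ci = 0; ci < nch; ++ci) {
        double gg = gch(ci), E = ch_e(ci);
        int c = ch_core(ci), p = ch_peri(ci);
        LHS_step(c, c) += gg; rhs(c) += gg * E;
        if (p >= 0) {
          LHS_step(c, p) -= gg; LHS_step(p, c) -= gg;
          LHS_step(p, p) += gg; rhs(p) -= gg * E;
        }
      }
      for (uword j = 0; j < clamp_idx.n_elem; ++j) {
        LHS_step.row(clamp_idx(j)).zeros();
        LHS_step(clamp_idx(j), clamp_idx(j)) = 1.0;
      }
    }

    for (uword j = 0; j < clamp_idx.n_elem; ++j) rhs(clamp_idx(j)) = clamp(s, j);

    if (prefactored) {
      x = LHSinv * rhs;
    } else {
      if (!solve(x, LHS_step, rhs)) Rcpp::stop("singular system matrix during step");
    }
    record(s + 1, x);
  }

  return Rcpp::List::create(Rcpp::Named("traj") = out,
                            Rcpp::Named("x_final") = x,
                            Rcpp::Named("gates_final") = gstate);
}
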