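// Conductance-based canonical microcircuit network: compiled core.
//
// State layout (per source, 16 states): populations in order
//   SS (spiny stellate), SP (superficial pyramidal), II (inhibitory
//   interneuron), DP (deep pyramidal); per population V, gAMPA, gGABAA, gNMDA.
// Global state index: src*16 + pop*4 + state (0-based). Time unit: ms.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;
using Rcpp::List;
using Rcpp::as;

namespace {

struct Ctx {
  int nsrc;
  mat kappa;            // nsrc x 3 rate constants (AMPA, GABAA, NMDA), ms^-1
  cube WA, WG, WN;      // 4 x 4 x nsrc intrinsic weights (post, pre)
  imat edges;           // nE x 5: from_src, from_pop, to_src, to_pop, receptor
  vec ew;               // nE extrinsic weights
  double mg_a, mg_b, mg_g;      // Mg-block sigmoid
  double VR, sig;               // firing threshold (mV), ensemble SD (mV)
  double EA, EG, EN, VL;        // reversal potentials (mV)
  double gL, Cm, bg;            // leak, capacitance (ms units), background
  vec delays;                   // nsrc intra-source delays (ms)
  double dext;                  // inter-source delay (ms)
};

Ctx parse_ctx(const List& L) {
  Ctx c;
  c.nsrc  = as<int>(L["nsrc"]);
  c.kappa = as<mat>(L["kappa"]);
  c.WA = as<cube>(L["WA"]); c.WG = as<cube>(L["WG"]); c.WN = as<cube>(L["WN"]);
  c.edges = as<imat>(L["edges"]);
  c.ew = as<vec>(L["ew"]);
  vec mg = as<vec>(L["mg"]);
  c.mg_a = mg(0); c.mg_b = mg(1); c.mg_g = mg(2);
  c.VR = as<double>(L["VR"]); c.sig = as<double>(L["sigma"]);
  vec rev = as<vec>(L["rev"]);
  c.EA = rev(0); c.EG = rev(1); c.EN = rev(2);
  c.VL = as<double>(L["VL"]); c.gL = as<double>(L["gL"]);
  c.Cm = as<double>(L["C"]);  c.bg = as<double>(L["bg"]);
  c.delays = as<vec>(L["delays"]);
  c.dext = as<double>(L["dext"]);
  return c;
}

inline int ix(int s, int p, int st) { return s * 16 + p * 4 + st; }

inline double sigm(double v, const Ctx& c) {
  double z = (v - c.VR) / c.sig;
  if (z > 30.0) return 1.0;
  if (z < -30.0) return std::exp(z);
  return 1.0 / (1.0 + std::exp(-z));
}
inline double dsigm(double v, const Ctx& c) {
  double s = sigm(v, c);
  return s * (1.0 - s) / c.sig;
}
inline double mgate(double v, const Ctx& c) {
  double e = std::exp(-c.mg_g * v);
  return c.mg_a / (1.0 + c.mg_b * e);
}
inline double dmgate(double v, const Ctx& c) {
  double e = std::exp(-c.mg_g * v);
  double d = 1.0 + c.mg_b * e;
  return c.mg_a * c.mg_b * c.mg_g * e / (d * d);
}

// receptor-wise presynaptic drive u(r) for every (src, pop); presynaptic
// rates are supplied so the simulator can pass delayed values
void drives(const Ctx& c, const mat& S, cube& U) {
  U.zeros();
  for (int s = 0; s < c.nsrc; ++s)
    for (int p = 0; p < 4; ++p)
      for (int q = 0; q < 4; ++q) {
        U(p, 0, s) += c.WA(p, q, s) * S(q, s);
        U(p, 1, s) += c.WG(p, q, s) * S(q, s);
        U(p, 2, s) += c.WN(p, q, s) * S(q, s);
      }
  for (unsigned int e = 0; e < c.edges.n_rows; ++e)
    U(c.edges(e, 3), c.edges(e, 4), c.edges(e, 2)) +=
        c.ew(e) * S(c.edges(e, 1), c.edges(e, 0));
}

vec rhs(const Ctx& c, const vec& x) {
  int n = c.nsrc * 16;
  vec dx(n);
  mat S(4, c.nsrc);
  for (int s = 0; s < c.nsrc; ++s)
    for (int p = 0; p < 4; ++p) S(p, s) = sigm(x(ix(s, p, 0)), c);
  cube U(4, 3, c.nsrc);
  drives(c, S, U);
  for (int s = 0; s < c.nsrc; ++s)
    for (int p = 0; p < 4; ++p) {
      double V = x(ix(s, p, 0));
      double gA = x(ix(s, p, 1)), gG = x(ix(s, p, 2)), gN = x(ix(s, p, 3));
      dx(ix(s, p, 0)) = (c.gL * (c.VL - V) + gA * (c.EA - V) +
                         gG * (c.EG - V) + gN * mgate(V, c) * (c.EN - V) +
                         c.bg) / c.Cm;
      dx(ix(s, p, 1)) = c.kappa(s, 0) * (U(p, 0, s) - gA);
      dx(ix(s, p, 2)) = c.kappa(s, 1) * (U(p, 1, s) - gG);
      dx(ix(s, p, 3)) = c.kappa(s, 2) * (U(p, 2, s) - gN);
    }
  return dx;
}

mat jac(const Ctx& c, const vec& x) {
  int n = c.nsrc * 16;
  mat J(n, n, fill::zeros);
  for (int s = 0; s < c.nsrc; ++s)
    for (int p = 0; p < 4; ++p) {
      int iV = ix(s, p, 0);
      double V = x(iV);
      double gA = x(ix(s, p, 1)), gG = x(ix(s, p, 2)), gN = x(ix(s, p, 3));
      double m = mgate(V, c), dm = dmgate(V, c);
      J(iV, iV) = (-c.gL - gA - gG + gN * (dm * (c.EN - V) - m)) / c.Cm;
      J(iV, ix(s, p, 1)) = (c.EA - V) / c.Cm;
      J(iV, ix(s, p, 2)) = (c.EG - V) / c.Cm;
      J(iV, ix(s, p, 3)) = m * (c.EN - V) / c.Cm;
      for (int r = 0; r < 3; ++r)
        J(ix(s, p, 1 + r), ix(s, p, 1 + r)) = -c.kappa(s, r);
      // intrinsic: dot-g depends on presynaptic voltages within the source
      for (int q = 0; q < 4; ++q) {
        double ds = dsigm(x(ix(s, q, 0)), c);
        J(ix(s, p, 1), ix(s, q, 0)) += c.kappa(s, 0) * c.WA(p, q, s) * ds;
        J(ix(s, p, 2), ix(s, q, 0)) += c.kappa(s, 1) * c.WG(p, q, s) * ds;
        J(ix(s, p, 3), ix(s, q, 0)) += c.kappa(s, 2) * c.WN(p, q, s) * ds;
      }
    }
  for (unsigned int e = 0; e < c.edges.n_rows; ++e) {
    int fs = c.edges(e, 0), fp = c.edges(e, 1);
    int ts = c.edges(e, 2), tp = c.edges(e, 3), r = c.edges(e, 4);
    J(ix(ts, tp, 1 + r), ix(fs, fp, 0)) +=
        c.kappa(ts, r) * c.ew(e) * dsigm(x(ix(fs, fp, 0)), c);
  }
  return J;
}

mat delay_matrix(const Ctx& c) {
  int n = c.nsrc * 16;
  mat D(n, n, fill::zeros);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j) {
      int si = i / 16, sj = j / 16;
      int pi = (i % 16) / 4, pj = (j % 16) / 4;
      if (si != sj) D(i, j) = c.dext;
      else if (pi != pj) D(i, j) = c.delays(si);
    }
  return D;
}

// first-order delay compensation: Jd = (I - D % J)^-1 J
mat delayed_jacobian(const Ctx& c, const mat& J) {
  mat D = delay_matrix(c);
  mat A = eye(J.n_rows, J.n_cols) - D % J;
  return solve(A, J);
}

struct FP { vec x; double res; int iters; bool ok; };

FP fixed_point(const Ctx& c, vec x, double tol, int maxit,
               int relax_steps = 4000) {
  // relax towards the dynamical attractor before Newton: with coexisting
  // equilibria the linearization must be taken at the state the stochastic
  // dynamics actually orbit, which relaxation selects and Newton then
  // sharpens; a warm start close to the attractor needs few steps
  for (int k = 0; k < relax_steps; ++k) x += 0.08 * rhs(c, x);
  vec f = rhs(c, x);
  double r = norm(f, "inf");
  int it = 0;
  while (r > tol && it < maxit) {
    mat J = jac(c, x);
    vec dx;
    bool solved = solve(dx, J, -f);
    if (!solved) break;
    double t = 1.0;
    vec xn; vec fn; double rn = r;
    for (int k = 0; k < 8; ++k) {
      xn = x + t * dx;
      fn = rhs(c, xn);
      rn = norm(fn, "inf");
      if (rn < r) break;
      t *= 0.5;
    }
    if (rn >= r) {          // Newton stalled: relax by integration
      double dt = 0.05;
      for (int k = 0; k < 2000; ++k) x += dt * rhs(c, x);
      f = rhs(c, x); r = norm(f, "inf");
    } else {
      x = xn; f = fn; r = rn;
    }
    ++it;
  }
  FP out; out.x = x; out.res = r; out.iters = it; out.ok = (r <= tol);
  return out;
}

} // namespace

// [[Rcpp::export(name = ".cmc_rhs")]]
arma::vec cmc_rhs_cpp(Rcpp::List ctx, arma::vec x) {
  return rhs(parse_ctx(ctx), x);
}

// [[Rcpp::export(name = ".cmc_jacobian")]]
arma::mat cmc_jacobian_cpp(Rcpp::List ctx, arma::vec x) {
  return jac(parse_ctx(ctx), x);
}

// [[Rcpp::export(name = ".cmc_delay_matrix")]]
arma::mat cmc_delay_matrix_cpp(Rcpp::List ctx) {
  return delay_matrix(parse_ctx(ctx));
}

// [[Rcpp::export(name = ".cmc_fixed_point")]]
Rcpp::List cmc_fixed_point_cpp(Rcpp::List ctx, arma::vec x0, double tol,
                               int maxit, int relax_steps) {
  Ctx c = parse_ctx(ctx);
  FP fp = fixed_point(c, x0, tol, maxit, relax_steps);
  return List::create(Rcpp::Named("x") = fp.x,
                      Rcpp::Named("residual") = fp.res,
                      Rcpp::Named("iterations") = fp.iters,
                      Rcpp::Named("converged") = fp.ok);
}

// Full analytic prediction: fixed point -> Jacobian -> delay compensation ->
// eigen-based transfer functions -> cross-spectral density.
//   Out:  n_out x n_states observation matrix (already includes lead field,
//         population weights and spatial-mode projection)
//   Bin:  n_states x n_in innovations input matrix
//   gu:   n_freq innovations power spectral density (shared across inputs)
// [[Rcpp::export(name = ".cmc_predict")]]
Rcpp::List cmc_predict_cpp(Rcpp::List ctx, arma::vec freq_hz, arma::mat Out,
                           arma::mat Bin, arma::vec gu, arma::vec x0,
                           double fp_tol, int fp_maxit,
                           bool exact_delays, int relax_steps) {
  Ctx c = parse_ctx(ctx);
  FP fp = fixed_point(c, x0, fp_tol, fp_maxit, relax_steps);
  if (!fp.ok)
    return List::create(Rcpp::Named("status") = "fp_failed",
                        Rcpp::Named("residual") = fp.res);
  mat J = jac(c, fp.x);
  mat Jd = delayed_jacobian(c, J);
  cx_vec eval; cx_mat evec;
  bool ok = eig_gen(eval, evec, Jd);
  if (!ok)
    return List::create(Rcpp::Named("status") = "eig_failed");
  double maxre = eval.n_elem ? max(real(eval)) : datum::nan;
  if (maxre >= 0)
    return List::create(Rcpp::Named("status") = "unstable",
                        Rcpp::Named("max_real") = maxre,
                        Rcpp::Named("eigenvalues") = eval,
                        Rcpp::Named("x") = fp.x);
  cx_mat OQ = cx_mat(Out, mat(Out.n_rows, Out.n_cols, fill::zeros)) * evec;
  cx_mat QB = solve(evec, cx_mat(Bin, mat(Bin.n_rows, Bin.n_cols,
                                          fill::zeros)));
  int nf = freq_hz.n_elem, no = Out.n_rows, ni = Bin.n_cols;
  cx_cube S(no, no, nf);
  cx_cube H(no, ni, nf);
  mat D;
  cx_mat Oc, Bc;
  if (exact_delays) {
    D = delay_matrix(c);
    Oc = cx_mat(Out, mat(Out.n_rows, Out.n_cols, fill::zeros));
    Bc = cx_mat(Bin, mat(Bin.n_rows, Bin.n_cols, fill::zeros));
  }
  int n = J.n_rows;
  for (int k = 0; k < nf; ++k) {
    double w = 2.0 * datum::pi * freq_hz(k) / 1000.0;  // rad/ms
    cx_mat Hk;
    if (exact_delays) {
      // delays evaluated exactly in the frequency domain:
      // H(w) = Out (iwI - J % exp(-iwD))^-1 B
      cx_mat Jw(J % cos(w * D), -J % sin(w * D));
      cx_mat A = cx_double(0, w) * cx_mat(eye(n, n),
                                          mat(n, n, fill::zeros)) - Jw;
      Hk = Oc * solve(A, Bc);
    } else {
      cx_vec d = 1.0 / (cx_double(0, w) - eval);
      Hk = OQ * diagmat(d) * QB;
    }
    H.slice(k) = Hk;
    S.slice(k) = gu(k) * (Hk * Hk.t());   // .t() is conjugate transpose
  }
  return List::create(Rcpp::Named("status") = "ok",
                      Rcpp::Named("csd") = S,
                      Rcpp::Named("transfer") = H,
                      Rcpp::Named("x") = fp.x,
                      Rcpp::Named("jacobian") = J,
                      Rcpp::Named("jacobian_delayed") = Jd,
                      Rcpp::Named("eigenvalues") = eval,
                      Rcpp::Named("max_real") = maxre);
}

// Euler-Maruyama simulation of the delayed stochastic system. Innovations
// (SD innov_sd per sqrt(ms) after division by C) drive SS membrane equations.
// Returns voltage states (16 per source rows) thinned by keep_every.
// [[Rcpp::export(name = ".cmc_simulate")]]
arma::mat cmc_simulate_cpp(Rcpp::List ctx, arma::vec x0, double dt,
                           int nsteps, int keep_every, double innov_sd,
                           int burn_steps) {
  Ctx c = parse_ctx(ctx);
  int npop = 4 * c.nsrc;
  // delay lags in steps
  int lag_ext = (int) std::round(c.dext / dt);
  ivec lag_int(c.nsrc);
  for (int s = 0; s < c.nsrc; ++s)
    lag_int(s) = (int) std::round(c.delays(s) / dt);
  int maxlag = std::max(lag_ext, (int) lag_int.max()) + 1;
  mat hist(npop, maxlag, fill::zeros);       // circular buffer of voltages
  for (int s = 0; s < c.nsrc; ++s)
    for (int p = 0; p < 4; ++p)
      hist.row(s * 4 + p).fill(x0(ix(s, p, 0)));
  vec x = x0;
  int total = burn_steps + nsteps;
  int nkeep = nsteps / keep_every;
  mat out(npop, nkeep, fill::zeros);
  int head = 0, kept = 0;
  double sqdt = std::sqrt(dt);
  Rcpp::RNGScope scope;
  cube U(4, 3, c.nsrc);
  mat Sdel(4, c.nsrc);
  for (int t = 0; t < total; ++t) {
    // intrinsic drives with per-source intra delays (cross-population only)
    U.zeros();
    for (int s = 0; s < c.nsrc; ++s) {
      int li = (head - (int) lag_int(s) + 10 * maxlag) % maxlag;
      for (int q = 0; q < 4; ++q) {
        double Vq_now = hist(s * 4 + q, head);
        double Vq_del = hist(s * 4 + q, li);
        double s_now = sigm(Vq_now, c), s_del = sigm(Vq_del, c);
        for (int p = 0; p < 4; ++p) {
          double sv = (p == q) ? s_now : s_del;
          U(p, 0, s) += c.WA(p, q, s) * sv;
          U(p, 1, s) += c.WG(p, q, s) * sv;
          U(p, 2, s) += c.WN(p, q, s) * sv;
        }
      }
    }
    int le = (head - lag_ext + 10 * maxlag) % maxlag;
    for (unsigned int e = 0; e < c.edges.n_rows; ++e) {
      double Vd = hist(c.edges(e, 0) * 4 + c.edges(e, 1), le);
      U(c.edges(e, 3), c.edges(e, 4), c.edges(e, 2)) += c.ew(e) * sigm(Vd, c);
    }
    for (int s = 0; s < c.nsrc; ++s)
      for (int p = 0; p < 4; ++p) {
        double V = x(ix(s, p, 0));
        double gA = x(ix(s, p, 1)), gG = x(ix(s, p, 2)), gN = x(ix(s, p, 3));
        double dv = (c.gL * (c.VL - V) + gA * (c.EA - V) + gG * (c.EG - V) +
                     gN * mgate(V, c) * (c.EN - V) + c.bg) / c.Cm;
        x(ix(s, p, 0)) += dt * dv;
        if (p == 0)   // innovations current into spiny stellate cells
          x(ix(s, p, 0)) += sqdt * innov_sd / c.Cm * R::rnorm(0.0, 1.0);
        x(ix(s, p, 1)) += dt * c.kappa(s, 0) * (U(p, 0, s) - gA);
        x(ix(s, p, 2)) += dt * c.kappa(s, 1) * (U(p, 1, s) - gG);
        x(ix(s, p, 3)) += dt * c.kappa(s, 2) * (U(p, 2, s) - gN);
      }
    head = (head + 1) % maxlag;
    for (int s = 0; s < c.nsrc; ++s)
      for (int p = 0; p < 4; ++p) hist(s * 4 + p, head) = x(ix(s, p, 0));
    if (t >= burn_steps) {
      int k = t - burn_steps;
      if ((k + 1) % keep_every == 0 && kept < nkeep) {
        for (int s = 0; s < c.nsrc; ++s)
          for (int p = 0; p < 4; ++p)
            out(s * 4 + p, kept) = x(ix(s, p, 0));
        ++kept;
      }
    }
  }
  return out;
}
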