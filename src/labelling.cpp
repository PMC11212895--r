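// Fast path for the deterministic labelling curves: builds the compartment
// generator, solves the label-free steady state, and propagates the
// BrdU-positive block through pulse and chase by eigendecomposition.
// Mirrors the R implementation (used as fallback and cross-checked in the
// test suite).
#define ARMA_WARN_LEVEL 1
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

struct KPar {
  int topo;        // 0 branched, 1 linear, 2 burst, 3 temporal
  double eps, beta, af, as, df, ds, gam, act, rev, f, pf, Nf, Ns;
  int nstage;
};

// 0-based state index; stage s: 0 = Ki67-low, 1..n = high stages
static inline int ix(int pool, int s, int b, int npool, int S) {
  return (b * npool + pool) * S + (s == 0 ? S - 1 : s - 1);
}

static void build_gen(const KPar& P, double eps, mat& A, vec& b) {
  int npool = (P.topo == 3) ? 1 : 2;
  int n = P.nstage, S = n + 1, d = npool * S * 2;
  A.zeros(d, d);
  b.zeros(d);
  double bn = P.beta * n;
  double phi = P.f * (P.Nf + P.Ns);
  double t01 = 0, t10 = 0;  // pool transitions [from][to]
  if (P.topo == 1) t01 = P.gam;             // linear: fast -> slow
  if (P.topo == 2) { t01 = P.rev; t10 = P.act; }  // burst
  for (int i = 0; i < npool; ++i) {
    double alpha_i = (P.topo == 3 || i == 0) ? P.af : P.as;
    double t_out = (npool == 2) ? (i == 0 ? t01 : t10) : 0.0;
    double phi_i = (npool == 1) ? phi : (i == 0 ? phi * P.pf : phi * (1 - P.pf));
    for (int br = 0; br < 2; ++br) {
      int hi1_pos = ix(i, 1, 1, npool, S);
      int hi1_neg = ix(i, 1, 0, npool, S);
      for (int s = 0; s <= n; ++s) {
        int j = ix(i, s, br, npool, S);
        double delta_is;
        if (P.topo == 3) delta_is = (s == 0) ? P.ds : P.df;
        else delta_is = (i == 0) ? P.df : P.ds;
        double out = alpha_i + delta_is + t_out;
        if (s != 0) out += bn;
        A(j, j) -= out;
        if (s != 0) {
          int jn = ix(i, (s == n) ? 0 : s + 1, br, npool, S);
          A(jn, j) += bn;
        }
        if (t_out > 0) {
          int jk = ix(1 - i, s, br, npool, S);
          A(jk, j) += t_out;
        }
        if (br == 1) {
          A(hi1_pos, j) += 2 * alpha_i;
        } else {
          if (eps > 0) A(hi1_pos, j) += 2 * alpha_i * eps;
          A(hi1_neg, j) += 2 * alpha_i * (1 - eps);
        }
      }
    }
    b(ix(i, 1, 1, npool, S)) += phi_i * eps;
    b(ix(i, 1, 0, npool, S)) += phi_i * (1 - eps);
  }
}

// z(t) for z' = Ae z + ce from z0, columns = times; returns false on failure
static bool propagate(const mat& Ae, const vec& ce, const vec& z0,
                      const vec& times, mat& out) {
  int d = Ae.n_rows;
  vec xp;
  if (!solve(xp, Ae, -ce, solve_opts::no_approx)) return false;
  cx_vec lam;
  cx_mat V;
  if (!eig_gen(lam, V, Ae)) return false;
  cx_vec w;
  if (!solve(w, V, cx_vec(z0 - xp, vec(d, fill::zeros)), solve_opts::no_approx)) return false;
  // verify the eigenbasis is usable
  cx_vec recon = V * w;
  if (norm(real(recon) - (z0 - xp), "inf") >
      1e-8 * std::max(1.0, norm(z0 - xp, "inf"))) return false;
  out.set_size(d, times.n_elem);
  for (uword k = 0; k < times.n_elem; ++k) {
    cx_vec zt = V * (w % exp(lam * times(k)));
    out.col(k) = real(zt) + xp;
  }
  return out.is_finite();
}

// [[Rcpp::export(name = ".labelling_curves_cpp")]]
Rcpp::NumericMatrix labelling_curves_cpp(Rcpp::NumericVector par, int topo,
                                         int nstage, double pulse_end,
                                         Rcpp::NumericVector times_r) {
  KPar P;
  P.topo = topo; P.nstage = nstage;
  P.eps = par["epsilon"]; P.beta = par["beta"];
  P.af = par["alpha_fast"]; P.as = par["alpha_slow"];
  P.df = par["delta_fast"]; P.ds = par["delta_slow"];
  P.gam = par["gamma"]; P.act = par["activation"]; P.rev = par["reversion"];
  P.f = par["f"]; P.pf = par["phi_fast_fraction"];
  P.Nf = par["N_fast"]; P.Ns = par["N_slow"];
  int npool = (P.topo == 3) ? 1 : 2;
  int n = P.nstage, S = n + 1;
  vec times(times_r.begin(), times_r.size());
  Rcpp::NumericMatrix fail(0, 0);

  mat Ap, Ac; vec bp, bc;
  build_gen(P, P.eps, Ap, bp);
  build_gen(P, 0.0, Ac, bc);

  // steady occupancy: BrdU-negative block, pool sizes fixed
  uvec hi_idx(npool * n), lo_idx(npool);
  for (int i = 0; i < npool; ++i) {
    for (int s = 1; s <= n; ++s) hi_idx(i * n + s - 1) = ix(i, s, 0, npool, S);
    lo_idx(i) = ix(i, 0, 0, npool, S);
  }
  uvec neg_idx = join_cols(hi_idx, lo_idx);
  vec Npool(npool);
  Npool(0) = P.Nf;
  if (npool == 2) Npool(1) = P.Ns;
  int nh = npool * n;
  mat Ahh = Ac(hi_idx, hi_idx);
  mat Ahl = Ac(hi_idx, lo_idx);
  mat Sm(npool, nh, fill::zeros);
  for (int i = 0; i < npool; ++i)
    for (int s = 0; s < n; ++s) Sm(i, i * n + s) = 1.0;
  vec y;
  if (!solve(y, Ahh - Ahl * Sm, -(Ahl * Npool + bc(hi_idx)), solve_opts::no_approx)) return fail;
  vec xlo = Npool - Sm * y;
  double Nmax = Npool.max();
  if (y.min() < -1e-9 * Nmax || xlo.min() < -1e-9 * Nmax) return fail;
  y = clamp(y, 0.0, datum::inf);
  xlo = clamp(xlo, 0.0, datum::inf);
  vec ystar = join_cols(y, xlo);

  // positive block: same ordering shifted by d/2
  uvec pos_idx = neg_idx + Ap.n_rows / 2;
  vec ts = sort(unique(times));
  int d2 = pos_idx.n_elem;
  mat z(d2, ts.n_elem);
  uvec ip = find(ts <= pulse_end + 1e-12);
  uvec ic = find(ts > pulse_end + 1e-12);
  mat App = Ap(pos_idx, pos_idx), Cp = Ap(pos_idx, neg_idx);
  vec cep = Cp * ystar + bp(pos_idx);
  mat AeP = App - Cp;
  vec z0(d2, fill::zeros);
  if (!ip.is_empty()) {
    mat zp;
    if (!propagate(AeP, cep, z0, ts(ip), zp)) return fail;
    z.cols(ip) = zp;
  }
  if (!ic.is_empty()) {
    mat ztr;
    vec pe(1); pe(0) = pulse_end;
    if (!propagate(AeP, cep, z0, pe, ztr)) return fail;
    mat Acc = Ac(pos_idx, pos_idx), Cc = Ac(pos_idx, neg_idx);
    vec cec = Cc * ystar + bc(pos_idx);
    mat zc;
    vec tc = ts(ic) - pulse_end;
    if (!propagate(Acc - Cc, cec, ztr.col(0), tc, zc)) return fail;
    z.cols(ic) = zc;
  }
  double N = accu(ystar);
  if (z.min() < -1e-6 * N) return fail;
  for (uword k = 0; k < z.n_cols; ++k)
    z.col(k) = clamp(z.col(k), 0.0, datum::inf);
  z = min(z, repmat(ystar, 1, z.n_cols));
  double hi_tot = accu(y), lo_tot = accu(xlo);
  Rcpp::NumericMatrix out(ts.n_elem, 6);
  for (uword k = 0; k < ts.n_elem; ++k) {
    double hp = accu(z.submat(0, k, nh - 1, k));
    double lp = accu(z.submat(nh, k, d2 - 1, k));
    out(k, 0) = ts(k);
    out(k, 1) = (hp + lp) / N;
    out(k, 2) = hi_tot > 0 ? hp / hi_tot : 0.0;
    out(k, 3) = lo_tot > 0 ? lp / lo_tot : 0.0;
    out(k, 4) = hi_tot / N;
    out(k, 5) = N;
  }
  return out;
}
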