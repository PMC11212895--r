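// Exact event-driven stochastic simulation of BrdU/Ki67 labelling dynamics.
// Independent of the deterministic matrix-exponential solver: the per-cell
// rules (division with probabilistic BrdU uptake during the pulse, Ki67
// staged decay, death, pool transitions, constant influx) are implemented
// directly as reaction events on compartment counts (direct Gillespie
// method, no tau-leaping). Uses R's RNG so results honour set.seed().
#include <Rcpp.h>
using namespace Rcpp;

// state layout: cnt[b][i][s], b = BrdU 0/1, i = pool, s = 0 (Ki67-low) or
// 1..n (Ki67-high Erlang stages)

// [[Rcpp::export(name = ".ssa_labelling_cpp")]]
NumericVector ssa_labelling_cpp(IntegerMatrix counts0, int P, int nstage,
                                NumericVector alpha, NumericVector delta_hi,
                                NumericVector delta_lo, double beta, double eps,
                                double pulse_end, NumericMatrix trans,
                                NumericVector phi, NumericVector times,
                                int n_reps) {
  const int S = nstage + 1;              // Ki67 slots per (pool, brdu)
  const int nT = times.size();
  NumericVector out(n_reps * nT * 5);    // total, hi, pos, hi_pos, extinct flag
  const double bn = beta * nstage;
  std::vector<long> cnt(2 * P * S);
  auto idx = [&](int b, int i, int s) { return (b * P + i) * S + s; };

  for (int rep = 0; rep < n_reps; ++rep) {
    // one independent initial state per replicate
    int col = counts0.ncol() > 1 ? rep : 0;
    for (int k = 0; k < (int)cnt.size(); ++k) cnt[k] = counts0(k, col);
    double t = 0.0;
    int it = 0;
    bool extinct = false;
    while (it < nT) {
      // total event rate
      double R = 0.0;
      for (int i = 0; i < P; ++i) {
        R += phi[i];
        for (int b = 0; b < 2; ++b) {
          for (int s = 0; s < S; ++s) {
            long c = cnt[idx(b, i, s)];
            if (c == 0) continue;
            double d = (s == 0) ? delta_lo[i] : delta_hi[i];
            double rate = alpha[i] + d;
            if (s > 0) rate += bn;
            for (int k2 = 0; k2 < P; ++k2)
              if (k2 != i) rate += trans(i, k2);
            R += rate * c;
          }
        }
      }
      if (R <= 0.0) { extinct = true; }
      double dt = extinct ? R_PosInf : R::exp_rand() / R;
      // record any sampling times passed before the next event
      while (it < nT && t + dt >= times[it]) {
        long tot = 0, hi = 0, pos = 0, hi_pos = 0;
        for (int b = 0; b < 2; ++b)
          for (int i = 0; i < P; ++i)
            for (int s = 0; s < S; ++s) {
              long c = cnt[idx(b, i, s)];
              tot += c;
              if (s > 0) hi += c;
              if (b == 1) { pos += c; if (s > 0) hi_pos += c; }
            }
        double *o = &out[(rep * nT + it) * 5];
        o[0] = (double)tot; o[1] = (double)hi; o[2] = (double)pos;
        o[3] = (double)hi_pos; o[4] = extinct ? 1.0 : 0.0;
        ++it;
      }
      if (it >= nT || extinct) break;
      t += dt;
      bool pulse = (t <= pulse_end);
      // choose event
      double u = R::unif_rand() * R;
      double acc = 0.0;
      int ev_b = -1, ev_i = -1, ev_s = -1, ev_type = -1, ev_k = -1;
      for (int i = 0; i < P && ev_type < 0; ++i) {
        acc += phi[i];
        if (u < acc) { ev_type = 4; ev_i = i; break; }  // influx
        for (int b = 0; b < 2 && ev_type < 0; ++b) {
          for (int s = 0; s < S && ev_type < 0; ++s) {
            long c = cnt[idx(b, i, s)];
            if (c == 0) continue;
            double d = (s == 0) ? delta_lo[i] : delta_hi[i];
            acc += alpha[i] * c;
            if (u < acc) { ev_type = 0; ev_b = b; ev_i = i; ev_s = s; break; }
            acc += d * c;
            if (u < acc) { ev_type = 1; ev_b = b; ev_i = i; ev_s = s; break; }
            if (s > 0) {
              acc += bn * c;
              if (u < acc) { ev_type = 2; ev_b = b; ev_i = i; ev_s = s; break; }
            }
            for (int k2 = 0; k2 < P; ++k2) {
              if (k2 == i) continue;
              acc += trans(i, k2) * c;
              if (u < acc) { ev_type = 3; ev_b = b; ev_i = i; ev_s = s; ev_k = k2; break; }
            }
          }
        }
      }
      if (ev_type < 0) continue;  // numerical slack: no event selected
      switch (ev_type) {
      case 0: {  // division: remove mother, two daughters to Ki67-high stage 1
        cnt[idx(ev_b, ev_i, ev_s)]--;
        int bd = ev_b;
        if (ev_b == 0 && pulse && R::unif_rand() < eps) bd = 1;
        cnt[idx(bd, ev_i, 1)] += 2;
        break;
      }
      case 1:  // death
        cnt[idx(ev_b, ev_i, ev_s)]--;
        break;
      case 2: {  // Ki67 stage transit
        cnt[idx(ev_b, ev_i, ev_s)]--;
        int ns = (ev_s == nstage) ? 0 : ev_s + 1;
        cnt[idx(ev_b, ev_i, ns)]++;
        break;
      }
      case 3:  // pool transition
        cnt[idx(ev_b, ev_i, ev_s)]--;
        cnt[idx(ev_b, ev_k, ev_s)]++;
        break;
      case 4: {  // influx: Ki67-high stage 1, labelled w.p. eps during pulse
        int bd = (pulse && R::unif_rand() < eps) ? 1 : 0;
        cnt[idx(bd, ev_i, 1)]++;
        break;
      }
      }
    }
  }
  out.attr("dim") = IntegerVector::create(5, nT, n_reps);
  return out;
}
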