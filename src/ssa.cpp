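#include <Rcpp.h>
using namespace Rcpp;

// Direct-method (exact) stochastic simulation kernels.  All kernels draw
// from R's RNG stream so that set.seed() in R gives bit-for-bit
// reproducibility.  Each kernel simulates one trajectory and records the
// state at the requested sample times; the R wrappers loop over cells.

// Birth-death chain.  f[n-1] is the rate of the transition n-1 -> n
// (n = 1..cap); g[n-1] is the per-molecule degradation rate at count n.
// Hitting the cap (state == cap with positive birth rate) is an error:
// the model has run away past the safety cap.
// [[Rcpp::export]]
IntegerVector ssa_birth_death_traj(NumericVector f, NumericVector g,
                                   int init, NumericVector times) {
  const int cap = f.size();
  const int nt = times.size();
  IntegerVector out(nt);
  int s = init;
  double t = 0.0;
  int k = 0;
  while (k < nt) {
    double bi = (s < cap) ? f[s] : -1.0;
    if (bi < 0.0)
      stop("state exceeded the simulation safety cap (%d molecules)", cap);
    double di = (s > 0) ? g[s - 1] * s : 0.0;
    double a0 = bi + di;
    double tnext;
    if (a0 <= 0.0) {
      tnext = R_PosInf;  // absorbed
    } else {
      tnext = t + R::exp_rand() / a0;
    }
    while (k < nt && times[k] < tnext) {
      out[k] = s;
      ++k;
    }
    if (k >= nt) break;
    t = tnext;
    if (R::unif_rand() * a0 < bi) ++s; else --s;
  }
  return out;
}

// Multi-gene one-step chain on a truncated box.  States are linearised
// with strides; `birth` and `death` are per-species propensity arrays of
// length prod(dims): birth[i][idx] is the propensity of n -> n + e_i at
// the state with linear index idx (already zero at the upper boundary),
// death likewise for n -> n - e_i.  Returns the states (m columns) at
// the sample times plus an attribute counting time spent at leaky
// boundary states (diagnostic handled in R).
// [[Rcpp::export]]
IntegerMatrix ssa_network_traj(List birth, List death,
                               IntegerVector strides, IntegerVector init_coord,
                               IntegerVector box, NumericVector times) {
  const int m = strides.size();
  const int nt = times.size();
  std::vector<NumericVector> B(m), D(m);
  for (int i = 0; i < m; ++i) {
    B[i] = as<NumericVector>(birth[i]);
    D[i] = as<NumericVector>(death[i]);
  }
  IntegerMatrix out(nt, m);
  std::vector<int> s(m);
  int idx = 0;
  for (int i = 0; i < m; ++i) {
    s[i] = init_coord[i];
    idx += s[i] * strides[i];
  }
  double t = 0.0;
  int k = 0;
  std::vector<double> prop(2 * m);
  while (k < nt) {
    double a0 = 0.0;
    for (int i = 0; i < m; ++i) {
      prop[2 * i] = B[i][idx];
      prop[2 * i + 1] = D[i][idx];
      a0 += prop[2 * i] + prop[2 * i + 1];
    }
    double tnext = (a0 <= 0.0) ? R_PosInf : t + R::exp_rand() / a0;
    while (k < nt && times[k] < tnext) {
      for (int i = 0; i < m; ++i) out(k, i) = s[i];
      ++k;
    }
    if (k >= nt) break;
    t = tnext;
    double u = R::unif_rand() * a0;
    double acc = 0.0;
    int ch = 2 * m - 1;
    for (int c = 0; c < 2 * m; ++c) {
      acc += prop[c];
      if (u < acc) { ch = c; break; }
    }
    int i = ch / 2;
    if (ch % 2 == 0) { ++s[i]; idx += strides[i]; }
    else             { --s[i]; idx -= strides[i]; }
  }
  return out;
}

// Multi-step gene-state cycle: G_1 -> G_2 -> ... -> G_k -> G_1 + M,
// M -> 0.  Stage transitions all at rate `stage_rate`; one mRNA is
// produced when stage k completes; each mRNA degrades at `deg_rate`.
// [[Rcpp::export]]
IntegerVector ssa_multistep_traj(int k_stages, double stage_rate,
                                 double deg_rate, int init_m,
                                 NumericVector times, int cap) {
  const int nt = times.size();
  IntegerVector out(nt);
  int stage = 0;        // 0-based: stage i means G_{i+1}
  int m = init_m;
  double t = 0.0;
  int k = 0;
  while (k < nt) {
    double a_stage = stage_rate;
    double a_deg = deg_rate * m;
    double a0 = a_stage + a_deg;
    double tnext = t + R::exp_rand() / a0;
    while (k < nt && times[k] < tnext) { out[k] = m; ++k; }
    if (k >= nt) break;
    t = tnext;
    if (R::unif_rand() * a0 < a_stage) {
      ++stage;
      if (stage == k_stages) {
        stage = 0;
        ++m;
        if (m > cap) stop("mRNA count exceeded the safety cap (%d)", cap);
      }
    } else {
      --m;
    }
  }
  return out;
}

// Telegraph (two-state bursting) model: gene switches on/off at rates
// k_on (off->on) and k_off (on->off); transcription at rho_on / rho_off
// depending on the gene state; per-molecule degradation at `deg`.
// [[Rcpp::export]]
IntegerVector ssa_telegraph_traj(double k_on, double k_off,
                                 double rho_on, double rho_off, double deg,
                                 int init_state, int init_m,
                                 NumericVector times, int cap) {
  const int nt = times.size();
  IntegerVector out(nt);
  int on = init_state;  // 1 = active
  int m = init_m;
  double t = 0.0;
  int k = 0;
  while (k < nt) {
    double a_sw = on ? k_off : k_on;
    double a_tx = on ? rho_on : rho_off;
    double a_dg = deg * m;
    double a0 = a_sw + a_tx + a_dg;
    double tnext = (a0 <= 0.0) ? R_PosInf : t + R::exp_rand() / a0;
    while (k < nt && times[k] < tnext) { out[k] = m; ++k; }
    if (k >= nt) break;
    t = tnext;
    double u = R::unif_rand() * a0;
    if (u < a_sw) {
      on = 1 - on;
    } else if (u < a_sw + a_tx) {
      ++m;
      if (m > cap) stop("mRNA count exceeded the safety cap (%d)", cap);
    } else {
      --m;
    }
  }
  return out;
}
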