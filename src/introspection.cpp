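// Simulation core for introspection-dynamics learning runs.
//
// Each elementary step needs the long-run payoff of a candidate strategy
// against the co-player's current strategy, i.e. the stationary distribution
// of the 4-state (memory-1) or 16-state (memory-2) round-outcome chain.
// The solve is a hand-coded Gaussian elimination on fixed-size arrays so a
// 10^6-step run costs well under a second.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static const int MAXN = 16;

// ---- stationary solve -----------------------------------------------------

// Solve v P = v, sum(v) = 1 for a row-stochastic n x n matrix P.
// Bordered system: A = P^T - I with the last row replaced by ones.
// Returns false on a (numerically) singular system.
static bool stationary(const double P[MAXN][MAXN], int n, double v[MAXN]) {
  double A[MAXN][MAXN + 1];
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < n; ++j) A[i][j] = P[j][i] - (i == j ? 1.0 : 0.0);
    A[i][n] = 0.0;
  }
  for (int j = 0; j < n; ++j) A[n - 1][j] = 1.0;
  A[n - 1][n] = 1.0;

  for (int col = 0; col < n; ++col) {
    int piv = col;
    double best = std::fabs(A[col][col]);
    for (int r = col + 1; r < n; ++r) {
      double a = std::fabs(A[r][col]);
      if (a > best) { best = a; piv = r; }
    }
    if (best < 1e-300) return false;
    if (piv != col)
      for (int j = col; j <= n; ++j) std::swap(A[piv][j], A[col][j]);
    for (int r = col + 1; r < n; ++r) {
      double f = A[r][col] / A[col][col];
      if (f == 0.0) continue;
      for (int j = col; j <= n; ++j) A[r][j] -= f * A[col][j];
    }
  }
  for (int r = n - 1; r >= 0; --r) {
    double s = A[r][n];
    for (int j = r + 1; j < n; ++j) s -= A[r][j] * v[j];
    v[r] = s / A[r][r];
  }
  double tot = 0.0;
  for (int i = 0; i < n; ++i) { if (v[i] < 0.0) v[i] = 0.0; tot += v[i]; }
  if (tot <= 0.0) return false;
  for (int i = 0; i < n; ++i) v[i] /= tot;
  return true;
}

// ---- chain construction ---------------------------------------------------

// memory-2 state index: bits (own t-2, own t-1, co t-2, co t-1), C=0 D=1
static inline int m2idx(int o2, int o1, int c2, int c1) {
  return 8 * o2 + 4 * o1 + 2 * c2 + c1;
}

// Embed raw in-space entries (length d in {1,2,4,16}) into the chain family
// with n states (4 or 16), writing n cooperation probabilities to out.
static void embed_chain(const double *raw, int d, int n, double *out) {
  double m1[4];
  if (d == 1) { m1[0] = m1[1] = m1[2] = m1[3] = raw[0]; }
  else if (d == 2) { m1[0] = raw[0]; m1[1] = raw[1]; m1[2] = raw[0]; m1[3] = raw[1]; }
  else if (d == 4) { for (int k = 0; k < 4; ++k) m1[k] = raw[k]; }
  if (n == 4) {
    for (int k = 0; k < 4; ++k) out[k] = m1[k];
    return;
  }
  if (d == 16) { for (int k = 0; k < 16; ++k) out[k] = raw[k]; return; }
  for (int o2 = 0; o2 < 2; ++o2)
    for (int o1 = 0; o1 < 2; ++o1)
      for (int c2 = 0; c2 < 2; ++c2)
        for (int c1 = 0; c1 < 2; ++c1)
          out[m2idx(o2, o1, c2, c1)] = m1[2 * o1 + c1];
}

static inline double perturb(double x, double eps) {
  return (1.0 - eps) * x + eps * (1.0 - x);
}

// Embed raw in-space entries into a (weakly) larger space, raw-to-raw.
static void raw_embed(const double *raw, int d_from, int d_to, double *out) {
  if (d_from == d_to) { for (int k = 0; k < d_to; ++k) out[k] = raw[k]; return; }
  if (d_to == 2) { out[0] = raw[0]; out[1] = raw[0]; return; }  // U -> R
  embed_chain(raw, d_from, d_to, out);  // d_to is 4 or 16
}

struct PairStats {
  double pi1, pi2, rho1, rho2;
  double v[MAXN];
  int n;
};

// Long-run statistics of a strategy pair: e1/e2 are chain-family cooperation
// probabilities (post-error), Pi1 the focal payoff vector (R,S,T,P).
static bool pair_stats(const double *e1, const double *e2, int n,
                       const double *Pi1, PairStats &st) {
  double P[MAXN][MAXN];
  if (n == 4) {
    // states CC, CD, DC, DD; own move first
    for (int i = 0; i < 2; ++i)
      for (int j = 0; j < 2; ++j) {
        int s = 2 * i + j;
        double pc = e1[2 * i + j];
        double qc = e2[2 * j + i];
        P[s][0] = pc * qc;
        P[s][1] = pc * (1 - qc);
        P[s][2] = (1 - pc) * qc;
        P[s][3] = (1 - pc) * (1 - qc);
      }
  } else {
    for (int s = 0; s < 16; ++s)
      for (int t = 0; t < 16; ++t) P[s][t] = 0.0;
    for (int o2 = 0; o2 < 2; ++o2)
      for (int o1 = 0; o1 < 2; ++o1)
        for (int c2 = 0; c2 < 2; ++c2)
          for (int c1 = 0; c1 < 2; ++c1) {
            int s = m2idx(o2, o1, c2, c1);
            double pc = e1[s];
            double qc = e2[m2idx(c2, c1, o2, o1)];
            for (int a = 0; a < 2; ++a)
              for (int b = 0; b < 2; ++b) {
                double pr = (a == 0 ? pc : 1 - pc) * (b == 0 ? qc : 1 - qc);
                P[s][m2idx(o1, a, c1, b)] += pr;
              }
          }
  }
  double v[MAXN];
  if (!stationary(P, n, v)) return false;
  double m[4] = {0, 0, 0, 0};
  if (n == 4) {
    for (int k = 0; k < 4; ++k) m[k] = v[k];
  } else {
    for (int o2 = 0; o2 < 2; ++o2)
      for (int o1 = 0; o1 < 2; ++o1)
        for (int c2 = 0; c2 < 2; ++c2)
          for (int c1 = 0; c1 < 2; ++c1)
            m[2 * o1 + c1] += v[m2idx(o2, o1, c2, c1)];
  }
  double Pi2[4] = {Pi1[0], Pi1[2], Pi1[1], Pi1[3]};
  st.pi1 = m[0] * Pi1[0] + m[1] * Pi1[1] + m[2] * Pi1[2] + m[3] * Pi1[3];
  st.pi2 = m[0] * Pi2[0] + m[1] * Pi2[1] + m[2] * Pi2[2] + m[3] * Pi2[3];
  st.rho1 = m[0] + m[1];
  st.rho2 = m[0] + m[2];
  st.n = n;
  for (int k = 0; k < n; ++k) st.v[k] = v[k];
  return true;
}

// ---- candidate sampling ---------------------------------------------------

// schemes: 0 uniform, 1 arcsine, 2 same-complexity averaging,
//          3 same-complexity extreme-biasing
static void sample_raw(int d, int scheme, double *raw) {
  if (scheme == 0) {
    for (int k = 0; k < d; ++k) raw[k] = unif_rand();
  } else if (scheme == 1) {
    for (int k = 0; k < d; ++k) {
      double u = unif_rand();
      double s = std::sin(M_PI_2 * u);
      raw[k] = s * s;  // arcsine / Beta(1/2, 1/2)
    }
  } else {
    double z[4];
    for (int k = 0; k < 4; ++k) z[k] = unif_rand();
    if (scheme == 2) {
      if (d == 4) { for (int k = 0; k < 4; ++k) raw[k] = z[k]; }
      else if (d == 2) { raw[0] = 0.5 * (z[0] + z[1]); raw[1] = 0.5 * (z[2] + z[3]); }
      else { raw[0] = 0.25 * (z[0] + z[1] + z[2] + z[3]); }
    } else {
      // keep the value farthest from 1/2; ties keep the earlier draw
      if (d == 4) { for (int k = 0; k < 4; ++k) raw[k] = z[k]; }
      else if (d == 2) {
        raw[0] = std::fabs(z[1] - 0.5) > std::fabs(z[0] - 0.5) ? z[1] : z[0];
        raw[1] = std::fabs(z[3] - 0.5) > std::fabs(z[2] - 0.5) ? z[3] : z[2];
      } else {
        double best = z[0];
        for (int k = 1; k < 4; ++k)
          if (std::fabs(z[k] - 0.5) > std::fabs(best - 0.5)) best = z[k];
        raw[0] = best;
      }
    }
  }
}

static inline double fermi(double beta, double delta) {
  double x = beta * delta;
  if (x >= 0.0) return 1.0 / (1.0 + std::exp(-x));
  double ex = std::exp(x);
  return ex / (1.0 + ex);
}

// ---- learning run ---------------------------------------------------------

struct Learner {
  int d, scheme;
  double beta, alpha;
  bool active;
  double raw[16];
};

// Infer the in-space strategy an observer of dimension d_obs adopts when
// imitating a higher-memory co-player: the unconditional observer takes the
// imitated player's stationary cooperation rate; the reactive observer takes
// effective p/q conditioned on the co-player's last move under the invariant
// distribution (viewed from the imitated player's perspective).
static void infer_strategy(int d_obs, const double *imit_e, const PairStats &st_imit,
                           double *out) {
  // st_imit: stats computed with the imitated player as the focal player
  if (d_obs == 1) { out[0] = st_imit.rho1; return; }
  double mass_c = 0, mass_d = 0, num_c = 0, num_d = 0;
  if (st_imit.n == 4) {
    mass_c = st_imit.v[0] + st_imit.v[2];         // co-player cooperated: CC, DC
    mass_d = st_imit.v[1] + st_imit.v[3];
    num_c = st_imit.v[0] * imit_e[0] + st_imit.v[2] * imit_e[2];
    num_d = st_imit.v[1] * imit_e[1] + st_imit.v[3] * imit_e[3];
  } else {
    for (int s = 0; s < 16; ++s) {
      int c1 = s & 1;
      if (c1 == 0) { mass_c += st_imit.v[s]; num_c += st_imit.v[s] * imit_e[s]; }
      else { mass_d += st_imit.v[s]; num_d += st_imit.v[s] * imit_e[s]; }
    }
  }
  out[0] = mass_c > 1e-9 ? num_c / mass_c : st_imit.rho1;
  out[1] = mass_d > 1e-9 ? num_d / mass_d : st_imit.rho1;
}

// [[Rcpp::export]]
List cpp_introspection_run(int d1, int d2, int scheme1, int scheme2,
                           NumericVector Pi1, double beta1, double beta2,
                           double alpha1, double alpha2,
                           bool active1, bool active2, int search_cap,
                           double eps, double T,
                           NumericVector init1, NumericVector init2) {
  int n = (d1 == 16 || d2 == 16) ? 16 : 4;
  Learner L[2];
  L[0] = {d1, scheme1, beta1, alpha1, active1, {0}};
  L[1] = {d2, scheme2, beta2, alpha2, active2, {0}};
  if (init1.size() == d1) for (int k = 0; k < d1; ++k) L[0].raw[k] = init1[k];
  else sample_raw(d1, scheme1, L[0].raw);
  if (init2.size() == d2) for (int k = 0; k < d2; ++k) L[1].raw[k] = init2[k];
  else sample_raw(d2, scheme2, L[1].raw);

  double Pi[4] = {Pi1[0], Pi1[1], Pi1[2], Pi1[3]};
  double e[2][MAXN], cand_raw[16], cand_e[MAXN];
  for (int i = 0; i < 2; ++i) {
    embed_chain(L[i].raw, L[i].d, n, e[i]);
    for (int k = 0; k < n; ++k) e[i][k] = perturb(e[i][k], eps);
  }
  PairStats cur;  // focal = player 1
  if (!pair_stats(e[0], e[1], n, Pi, cur))
    stop("degenerate chain in learning run (use epsilon > 0)");

  double sum_pi1 = 0, sum_pi2 = 0, sum_rho1 = 0, sum_rho2 = 0;
  double accept[2] = {0, 0};
  long long steps = (long long) T;

  for (long long t = 0; t < steps; ++t) {
    int i = unif_rand() < 0.5 ? 0 : 1;
    int j = 1 - i;
    double pi_self = (i == 0) ? cur.pi1 : cur.pi2;
    double pi_co = (i == 0) ? cur.pi2 : cur.pi1;

    bool imitate = L[i].alpha > 0.0 && unif_rand() < L[i].alpha;
    if (imitate) {
      if (L[i].d >= L[j].d) {
        // copy verbatim, embedded into the observer's space
        raw_embed(L[j].raw, L[j].d, L[i].d, cand_raw);
      } else {
        // infer an effective strategy from the imitated player's behaviour
        PairStats st_imit;
        if (i == 0) {
          // imitated player is player 2: view the pair from its side
          if (!pair_stats(e[1], e[0], n, Pi, st_imit))
            stop("degenerate chain in learning run");
        } else {
          st_imit = cur;
        }
        double imit_e[MAXN];
        embed_chain(L[j].raw, L[j].d, n, imit_e);  // pre-error strategy
        infer_strategy(L[i].d, imit_e, st_imit, cand_raw);
      }
      if (unif_rand() < fermi(L[i].beta, pi_co - pi_self)) {
        for (int k = 0; k < L[i].d; ++k) L[i].raw[k] = cand_raw[k];
        embed_chain(L[i].raw, L[i].d, n, e[i]);
        for (int k = 0; k < n; ++k) e[i][k] = perturb(e[i][k], eps);
        if (!pair_stats(e[0], e[1], n, Pi, cur))
          stop("degenerate chain in learning run");
        accept[i] += 1;
      }
    } else {
      int draws = L[i].active ? search_cap : 1;
      for (int a = 0; a < draws; ++a) {
        sample_raw(L[i].d, L[i].scheme, cand_raw);
        embed_chain(cand_raw, L[i].d, n, cand_e);
        for (int k = 0; k < n; ++k) cand_e[k] = perturb(cand_e[k], eps);
        PairStats st;
        bool ok = (i == 0) ? pair_stats(cand_e, e[1], n, Pi, st)
                           : pair_stats(e[0], cand_e, n, Pi, st);
        if (!ok) stop("degenerate chain in learning run");
        double pi_cand = (i == 0) ? st.pi1 : st.pi2;
        if (unif_rand() < fermi(L[i].beta, pi_cand - pi_self)) {
          for (int k = 0; k < L[i].d; ++k) L[i].raw[k] = cand_raw[k];
          for (int k = 0; k < n; ++k) e[i][k] = cand_e[k];
          cur = st;
          accept[i] += 1;
          break;
        }
      }
    }
    sum_pi1 += cur.pi1; sum_pi2 += cur.pi2;
    sum_rho1 += cur.rho1; sum_rho2 += cur.rho2;
  }

  NumericVector f1(L[0].d), f2(L[1].d);
  for (int k = 0; k < L[0].d; ++k) f1[k] = L[0].raw[k];
  for (int k = 0; k < L[1].d; ++k) f2[k] = L[1].raw[k];
  double Td = (double) steps;
  return List::create(
    _["avg_payoff_1"] = sum_pi1 / Td, _["avg_payoff_2"] = sum_pi2 / Td,
    _["avg_coop_1"] = sum_rho1 / Td, _["avg_coop_2"] = sum_rho2 / Td,
    _["accept_1"] = accept[0], _["accept_2"] = accept[1],
    _["final_1"] = f1, _["final_2"] = f2);
}

// Sample n fresh pairs, run t_steps of baseline introspection dynamics for
// each, and record both players' cooperation rates (Fig-2-style samples).
// [[Rcpp::export]]
NumericMatrix cpp_coop_samples(int n_samples, int d1, int d2,
                               int scheme1, int scheme2, NumericVector Pi1,
                               double beta, double eps, int t_steps) {
  int n = (d1 == 16 || d2 == 16) ? 16 : 4;
  double Pi[4] = {Pi1[0], Pi1[1], Pi1[2], Pi1[3]};
  NumericMatrix out(n_samples, 2);
  double raw[2][16], e[2][MAXN], cand_raw[16], cand_e[MAXN];
  int d[2] = {d1, d2}, scheme[2] = {scheme1, scheme2};
  for (int s = 0; s < n_samples; ++s) {
    for (int i = 0; i < 2; ++i) {
      sample_raw(d[i], scheme[i], raw[i]);
      embed_chain(raw[i], d[i], n, e[i]);
      for (int k = 0; k < n; ++k) e[i][k] = perturb(e[i][k], eps);
    }
    PairStats cur;
    if (!pair_stats(e[0], e[1], n, Pi, cur)) stop("degenerate chain");
    for (int t = 0; t < t_steps; ++t) {
      int i = unif_rand() < 0.5 ? 0 : 1;
      double pi_self = (i == 0) ? cur.pi1 : cur.pi2;
      sample_raw(d[i], scheme[i], cand_raw);
      embed_chain(cand_raw, d[i], n, cand_e);
      for (int k = 0; k < n; ++k) cand_e[k] = perturb(cand_e[k], eps);
      PairStats st;
      bool ok = (i == 0) ? pair_stats(cand_e, e[1], n, Pi, st)
                         : pair_stats(e[0], cand_e, n, Pi, st);
      if (!ok) stop("degenerate chain");
      double pi_cand = (i == 0) ? st.pi1 : st.pi2;
      if (unif_rand() < fermi(beta, pi_cand - pi_self)) {
        for (int k = 0; k < d[i]; ++k) raw[i][k] = cand_raw[k];
        for (int k = 0; k < n; ++k) e[i][k] = cand_e[k];
        cur = st;
      }
    }
    out(s, 0) = cur.rho1;
    out(s, 1) = cur.rho2;
  }
  return out;
}

// Exact pair statistics for raw in-space strategies (used for cross-checks
// between the compiled core and the R-level stationary solve).
// [[Rcpp::export]]
NumericVector cpp_pair_stats(NumericVector raw1, NumericVector raw2,
                             NumericVector Pi1, double eps) {
  int d1 = raw1.size(), d2 = raw2.size();
  int n = (d1 == 16 || d2 == 16) ? 16 : 4;
  double e1[MAXN], e2[MAXN], Pi[4] = {Pi1[0], Pi1[1], Pi1[2], Pi1[3]};
  double r1[16], r2[16];
  for (int k = 0; k < d1; ++k) r1[k] = raw1[k];
  for (int k = 0; k < d2; ++k) r2[k] = raw2[k];
  embed_chain(r1, d1, n, e1);
  embed_chain(r2, d2, n, e2);
  for (int k = 0; k < n; ++k) { e1[k] = perturb(e1[k], eps); e2[k] = perturb(e2[k], eps); }
  PairStats st;
  if (!pair_stats(e1, e2, n, Pi, st)) stop("degenerate chain");
  return NumericVector::create(_["pi1"] = st.pi1, _["pi2"] = st.pi2,
                               _["rho1"] = st.rho1, _["rho2"] = st.rho2);
}
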