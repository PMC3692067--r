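// Compiled core: single-sequence feature predictors (propensity and
// one-hidden-layer neural variants), the Metropolis Monte Carlo sweep
// engine with incremental energy updates, Needleman-Wunsch dynamic
// programming for the structural aligner, and the BLOSUM62-derived
// pairwise sequence distance matrix.
//
// Sequences are 0-based integer-coded over the package's fixed 20-letter
// alphabet; symbol 20 is the out-of-chain window pad.

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <string>

using namespace Rcpp;

static const int N_AA = 20;
static const int PAD = 20;
static const int N_SYM = 21;

// ---------------------------------------------------------------------------
// Feature predictor
// ---------------------------------------------------------------------------

struct Predictor {
  int variant;            // 0 propensity, 1 neural
  int window, hw;
  int L;
  // propensity tables: prop[s][sym], expo[sym]; window weights wts[k]
  std::vector<double> prop[3];
  std::vector<double> expo;
  std::vector<double> wts;
  std::vector<double> wsum;      // per-position in-chain weight mass
  // neural weights
  int H;
  std::vector<double> W1ss, b1ss, W2ss, b2ss;   // W1ss: H x (21*window)
  std::vector<double> W1sa, b1sa, w2sa;
  double b2sa;
  double bin_phi[3], bin_psi[3];

  // state
  std::vector<double> raw;       // propensity: 3 x L (+ rsa raw in rawsa)
  std::vector<double> rawsa;
  std::vector<double> pre_ss;    // neural: H x L
  std::vector<double> pre_sa;
  // outputs
  std::vector<double> pss;       // 3 x L
  std::vector<double> prsa;
  std::vector<double> pphi, ppsi;

  void setup(List params, int L_) {
    L = L_;
    variant = as<int>(params["variant"]);
    window = as<int>(params["window"]);
    hw = window / 2;
    NumericVector bphi = params["bin_phi"], bpsi = params["bin_psi"];
    for (int s = 0; s < 3; s++) { bin_phi[s] = bphi[s]; bin_psi[s] = bpsi[s]; }
    if (variant == 0) {
      NumericMatrix P = params["prop"];   // 3 x 20
      NumericVector E = params["expo"], W = params["wts"];
      for (int s = 0; s < 3; s++) {
        prop[s].assign(N_SYM, 0.0);
        for (int a = 0; a < N_AA; a++) prop[s][a] = P(s, a);
      }
      expo.assign(N_SYM, 0.0);
      for (int a = 0; a < N_AA; a++) expo[a] = E[a];
      wts.assign(W.begin(), W.end());
      wsum.assign(L, 0.0);
      for (int j = 0; j < L; j++)
        for (int k = 0; k < window; k++) {
          int q = j + k - hw;
          if (q >= 0 && q < L) wsum[j] += wts[k];
        }
      raw.assign(3 * L, 0.0);
      rawsa.assign(L, 0.0);
    } else {
      NumericMatrix m1 = params["W1ss"];
      H = m1.nrow();
      W1ss.assign(m1.begin(), m1.end());           // column-major H x (21*window)
      b1ss = as<std::vector<double> >(params["b1ss"]);
      NumericMatrix m2 = params["W2ss"];            // 3 x H
      W2ss.assign(m2.begin(), m2.end());
      b2ss = as<std::vector<double> >(params["b2ss"]);
      NumericMatrix m3 = params["W1sa"];
      W1sa.assign(m3.begin(), m3.end());
      b1sa = as<std::vector<double> >(params["b1sa"]);
      w2sa = as<std::vector<double> >(params["w2sa"]);
      b2sa = as<double>(params["b2sa"]);
      pre_ss.assign(H * L, 0.0);
      pre_sa.assign(H * L, 0.0);
    }
    pss.assign(3 * L, 0.0);
    prsa.assign(L, 0.0);
    pphi.assign(L, 0.0);
    ppsi.assign(L, 0.0);
  }

  inline int sym_at(const std::vector<int>& seq, int q) const {
    return (q >= 0 && q < L) ? seq[q] : PAD;
  }

  // full (re)initialization of internal state from a sequence
  void init_state(const std::vector<int>& seq) {
    if (variant == 0) {
      for (int j = 0; j < L; j++) {
        double r0 = 0, r1 = 0, r2 = 0, rs = 0;
        for (int k = 0; k < window; k++) {
          int s = sym_at(seq, j + k - hw);
          r0 += wts[k] * prop[0][s];
          r1 += wts[k] * prop[1][s];
          r2 += wts[k] * prop[2][s];
          rs += wts[k] * expo[s];
        }
        raw[3 * j] = r0; raw[3 * j + 1] = r1; raw[3 * j + 2] = r2;
        rawsa[j] = rs;
      }
    } else {
      for (int j = 0; j < L; j++) {
        for (int h = 0; h < H; h++) {
          pre_ss[j * H + h] = b1ss[h];
          pre_sa[j * H + h] = b1sa[h];
        }
        for (int k = 0; k < window; k++) {
          int s = sym_at(seq, j + k - hw);
          int col = k * N_SYM + s;
          for (int h = 0; h < H; h++) {
            pre_ss[j * H + h] += W1ss[col * H + h];
            pre_sa[j * H + h] += W1sa[col * H + h];
          }
        }
      }
    }
    for (int j = 0; j < L; j++) compute_output(j);
  }

  // outputs (pss, prsa, pphi, ppsi) at position j from internal state
  void compute_output(int j) {
    double p[3], rsa;
    if (variant == 0) {
      double tot = raw[3 * j] + raw[3 * j + 1] + raw[3 * j + 2];
      if (tot <= 0) { p[0] = p[1] = p[2] = 1.0 / 3.0; }
      else for (int s = 0; s < 3; s++) p[s] = raw[3 * j + s] / tot;
      rsa = wsum[j] > 0 ? rawsa[j] / wsum[j] : 0.5;
    } else {
      double hid[64];
      double o[3];
      for (int h = 0; h < H; h++) hid[h] = 1.0 / (1.0 + std::exp(-pre_ss[j * H + h]));
      double mx = -1e300;
      for (int s = 0; s < 3; s++) {
        o[s] = b2ss[s];
        for (int h = 0; h < H; h++) o[s] += W2ss[h * 3 + s] * hid[h];
        if (o[s] > mx) mx = o[s];
      }
      double z = 0;
      for (int s = 0; s < 3; s++) { p[s] = std::exp(o[s] - mx); z += p[s]; }
      for (int s = 0; s < 3; s++) p[s] /= z;
      double acc = b2sa;
      for (int h = 0; h < H; h++) {
        double hs = 1.0 / (1.0 + std::exp(-pre_sa[j * H + h]));
        acc += w2sa[h] * hs;
      }
      rsa = 1.0 / (1.0 + std::exp(-acc));
    }
    if (rsa < 0) rsa = 0; if (rsa > 1) rsa = 1;
    // argmax with a small tolerance favoring the earlier state, so exact
    // propensity ties resolve identically on the incremental and fresh paths
    int best = 0;
    if (p[1] > p[best] + 1e-9) best = 1;
    if (p[2] > p[best] + 1e-9) best = 2;
    pss[3 * j] = p[0]; pss[3 * j + 1] = p[1]; pss[3 * j + 2] = p[2];
    prsa[j] = rsa;
    pphi[j] = bin_phi[best];
    ppsi[j] = bin_psi[best];
  }

  // incremental state update for substituting aa_old -> aa_new at pos p;
  // affected positions are [p-hw, p+hw]. Outputs at those positions must be
  // recomputed by the caller (compute_output).
  void update_state(int p, int aa_old, int aa_new) {
    int lo = p - hw; if (lo < 0) lo = 0;
    int hi = p + hw; if (hi > L - 1) hi = L - 1;
    if (variant == 0) {
      for (int j = lo; j <= hi; j++) {
        int k = p - j + hw;
        double w = wts[k];
        raw[3 * j] += w * (prop[0][aa_new] - prop[0][aa_old]);
        raw[3 * j + 1] += w * (prop[1][aa_new] - prop[1][aa_old]);
        raw[3 * j + 2] += w * (prop[2][aa_new] - prop[2][aa_old]);
        rawsa[j] += w * (expo[aa_new] - expo[aa_old]);
      }
    } else {
      for (int j = lo; j <= hi; j++) {
        int k = p - j + hw;
        int cn = k * N_SYM + aa_new, co = k * N_SYM + aa_old;
        for (int h = 0; h < H; h++) {
          pre_ss[j * H + h] += W1ss[cn * H + h] - W1ss[co * H + h];
          pre_sa[j * H + h] += W1sa[cn * H + h] - W1sa[co * H + h];
        }
      }
    }
  }
};

// [[Rcpp::export]]
List predict_features_cpp(IntegerVector seq0, List params) {
  int L = seq0.size();
  std::vector<int> seq(seq0.begin(), seq0.end());
  Predictor pr;
  pr.setup(params, L);
  pr.init_state(seq);
  NumericMatrix ssp(L, 3);
  NumericVector rsa(L), phi(L), psi(L);
  for (int j = 0; j < L; j++) {
    for (int s = 0; s < 3; s++) ssp(j, s) = pr.pss[3 * j + s];
    rsa[j] = pr.prsa[j];
    phi[j] = pr.pphi[j];
    psi[j] = pr.ppsi[j];
  }
  return List::create(_["ss_prob"] = ssp, _["rsa"] = rsa,
                      _["phi"] = phi, _["psi"] = psi);
}

// ---------------------------------------------------------------------------
// Energy bookkeeping and the Monte Carlo engine
// ---------------------------------------------------------------------------

struct Energy {
  int L;
  std::vector<double> lo;        // L x 20 log-odds, column-major from R
  std::vector<int> ss_sc;        // 0..2
  std::vector<double> rsa_sc, phi_sc, psi_sc;
  double tw[4];                  // term weights: profile, ss, ta, sa

  std::vector<double> c_ss, c_sa, c_ta;   // per-position contributions
  double sum_ss, sum_sa, sum_ta, sum_prof;

  void setup(NumericMatrix lom, IntegerVector ss, NumericVector rsa,
             NumericVector phi, NumericVector psi, NumericVector tweights) {
    L = lom.nrow();
    lo.assign(lom.begin(), lom.end());
    ss_sc.assign(ss.begin(), ss.end());
    rsa_sc.assign(rsa.begin(), rsa.end());
    phi_sc.assign(phi.begin(), phi.end());
    psi_sc.assign(psi.begin(), psi.end());
    for (int t = 0; t < 4; t++) tw[t] = tweights[t];
    c_ss.assign(L, 0.0); c_sa.assign(L, 0.0); c_ta.assign(L, 0.0);
  }

  inline double logodds(int j, int a) const { return lo[a * L + j]; }

  static inline double wrap_diff(double a, double b) {
    double d = std::fabs(a - b);
    d -= 360.0 * std::floor(d / 360.0);
    return d > 180.0 ? 360.0 - d : d;
  }

  inline double contrib_ta(const Predictor& pr, int j) const {
    bool hp = !ISNAN(phi_sc[j]), hq = !ISNAN(psi_sc[j]);
    if (hp && hq) {
      double dp = wrap_diff(pr.pphi[j], phi_sc[j]);
      double dq = wrap_diff(pr.ppsi[j], psi_sc[j]);
      return std::sqrt(dp * dp + dq * dq) / 180.0;
    } else if (hp) {
      return wrap_diff(pr.pphi[j], phi_sc[j]) / 180.0;
    } else if (hq) {
      return wrap_diff(pr.ppsi[j], psi_sc[j]) / 180.0;
    }
    return 0.0;
  }

  void refresh(const Predictor& pr, const std::vector<int>& seq) {
    sum_ss = sum_sa = sum_ta = sum_prof = 0.0;
    for (int j = 0; j < L; j++) {
      c_ss[j] = 1.0 - pr.pss[3 * j + ss_sc[j]];
      c_sa[j] = std::fabs(pr.prsa[j] - rsa_sc[j]);
      c_ta[j] = contrib_ta(pr, j);
      sum_ss += c_ss[j]; sum_sa += c_sa[j]; sum_ta += c_ta[j];
      sum_prof -= logodds(j, seq[j]);
    }
  }

  inline double total() const {
    return (tw[0] * sum_prof + tw[1] * sum_ss + tw[2] * sum_ta + tw[3] * sum_sa) / L;
  }
};

// run one Metropolis trajectory; R manages the RNG seed (set.seed before).
// [[Rcpp::export]]
List run_trajectory_cpp(IntegerVector start_seq, NumericMatrix log_odds,
                        IntegerVector ss_sc, NumericVector rsa_sc,
                        NumericVector phi_sc, NumericVector psi_sc,
                        List pred_params, NumericVector term_weights,
                        double base_mean, double base_sd,
                        double temperature, int n_sweeps,
                        LogicalVector frozen, LogicalMatrix allowed) {
  int L = start_seq.size();
  std::vector<int> seq(start_seq.begin(), start_seq.end());
  Predictor pr;
  pr.setup(pred_params, L);
  pr.init_state(seq);
  Energy en;
  en.setup(log_odds, ss_sc, rsa_sc, phi_sc, psi_sc, term_weights);
  en.refresh(pr, seq);

  std::vector<int> mutable_pos;
  std::vector<std::vector<int> > allow(L);
  for (int j = 0; j < L; j++) {
    for (int a = 0; a < N_AA; a++) if (allowed(a, j)) allow[j].push_back(a);
    if (!frozen[j] && (int)allow[j].size() > 1) mutable_pos.push_back(j);
  }
  if (mutable_pos.empty()) stop("no mutable positions under the given constraints");
  int n_mut = mutable_pos.size();

  CharacterVector seqs(n_sweeps);
  NumericVector zs(n_sweeps);
  NumericMatrix comps(n_sweeps, 4);
  long n_acc = 0, n_att = 0;
  RNGScope scope;
  static const char* AB = "ACDEFGHIKLMNPQRSTVWY";
  std::string buf(L, 'A');
  int hw = pr.hw;
  std::vector<double> save_state(std::max(3 * (2 * hw + 1),
                                          64 * (2 * hw + 1)) + 8);
  std::vector<double> save_out(8 * (2 * hw + 1));

  for (int sweep = 0; sweep < n_sweeps; sweep++) {
    for (int att = 0; att < L; att++) {
      int p = mutable_pos[(int)(unif_rand() * n_mut) % n_mut];
      int m = allow[p].size();
      int r = (int)(unif_rand() * (m - 1)) % (m - 1);
      int aa_new = -1, cur = seq[p];
      for (int t = 0, c = 0; t < m; t++) {
        if (allow[p][t] == cur) continue;
        if (c++ == r) { aa_new = allow[p][t]; break; }
      }
      if (aa_new < 0) continue;
      n_att++;

      int lo_j = p - hw > 0 ? p - hw : 0;
      int hi_j = p + hw < L - 1 ? p + hw : L - 1;
      int nj = hi_j - lo_j + 1;
      // save affected predictor state and contributions
      int sw = (pr.variant == 0) ? 3 : pr.H;
      for (int j = lo_j, q = 0; j <= hi_j; j++, q++) {
        for (int h = 0; h < sw; h++) {
          save_state[q * sw + h] = (pr.variant == 0) ? pr.raw[3 * j + h]
                                                     : pr.pre_ss[j * pr.H + h];
        }
      }
      std::vector<double> save_sa_state(nj * (pr.variant == 0 ? 1 : pr.H));
      for (int j = lo_j, q = 0; j <= hi_j; j++, q++) {
        if (pr.variant == 0) save_sa_state[q] = pr.rawsa[j];
        else for (int h = 0; h < pr.H; h++)
          save_sa_state[q * pr.H + h] = pr.pre_sa[j * pr.H + h];
      }
      for (int j = lo_j, q = 0; j <= hi_j; j++, q++) {
        save_out[q * 8 + 0] = pr.pss[3 * j];
        save_out[q * 8 + 1] = pr.pss[3 * j + 1];
        save_out[q * 8 + 2] = pr.pss[3 * j + 2];
        save_out[q * 8 + 3] = pr.prsa[j];
        save_out[q * 8 + 4] = pr.pphi[j];
        save_out[q * 8 + 5] = pr.ppsi[j];
      }
      double old_ss = 0, old_sa = 0, old_ta = 0;
      for (int j = lo_j; j <= hi_j; j++) {
        old_ss += en.c_ss[j]; old_sa += en.c_sa[j]; old_ta += en.c_ta[j];
      }

      pr.update_state(p, cur, aa_new);
      double new_ss = 0, new_sa = 0, new_ta = 0;
      for (int j = lo_j; j <= hi_j; j++) {
        pr.compute_output(j);
        double css = 1.0 - pr.pss[3 * j + en.ss_sc[j]];
        double csa = std::fabs(pr.prsa[j] - en.rsa_sc[j]);
        double cta = en.contrib_ta(pr, j);
        en.c_ss[j] = css; en.c_sa[j] = csa; en.c_ta[j] = cta;
        new_ss += css; new_sa += csa; new_ta += cta;
      }
      double d_prof = -en.logodds(p, aa_new) + en.logodds(p, cur);
      double dE = (en.tw[0] * d_prof + en.tw[1] * (new_ss - old_ss) +
                   en.tw[2] * (new_ta - old_ta) + en.tw[3] * (new_sa - old_sa)) / L;
      double dZ = dE / base_sd;
      bool accept = (dZ <= 0) || (unif_rand() < std::exp(-dZ / temperature));
      if (accept) {
        seq[p] = aa_new;
        en.sum_prof += d_prof;
        en.sum_ss += new_ss - old_ss;
        en.sum_sa += new_sa - old_sa;
        en.sum_ta += new_ta - old_ta;
        n_acc++;
      } else {
        for (int j = lo_j, q = 0; j <= hi_j; j++, q++) {
          for (int h = 0; h < sw; h++) {
            if (pr.variant == 0) pr.raw[3 * j + h] = save_state[q * sw + h];
            else pr.pre_ss[j * pr.H + h] = save_state[q * sw + h];
          }
          if (pr.variant == 0) pr.rawsa[j] = save_sa_state[q];
          else for (int h = 0; h < pr.H; h++)
            pr.pre_sa[j * pr.H + h] = save_sa_state[q * pr.H + h];
          pr.pss[3 * j] = save_out[q * 8 + 0];
          pr.pss[3 * j + 1] = save_out[q * 8 + 1];
          pr.pss[3 * j + 2] = save_out[q * 8 + 2];
          pr.prsa[j] = save_out[q * 8 + 3];
          pr.pphi[j] = save_out[q * 8 + 4];
          pr.ppsi[j] = save_out[q * 8 + 5];
          en.c_ss[j] = 1.0 - pr.pss[3 * j + en.ss_sc[j]];
          en.c_sa[j] = std::fabs(pr.prsa[j] - en.rsa_sc[j]);
          en.c_ta[j] = en.contrib_ta(pr, j);
        }
      }
    }
    // periodic exact refresh guards against floating-point drift
    if ((sweep & 255) == 255) en.refresh(pr, seq);
    for (int j = 0; j < L; j++) buf[j] = AB[seq[j]];
    seqs[sweep] = buf;
    double e_prof = en.sum_prof / L, e_ss = en.sum_ss / L;
    double e_ta = en.sum_ta / L, e_sa = en.sum_sa / L;
    comps(sweep, 0) = e_prof; comps(sweep, 1) = e_ss;
    comps(sweep, 2) = e_ta; comps(sweep, 3) = e_sa;
    zs[sweep] = (en.total() - base_mean) / base_sd;
  }
  return List::create(_["sequences"] = seqs, _["z"] = zs,
                      _["components"] = comps,
                      _["acceptance_rate"] = (double)n_acc / (double)n_att);
}

// ---------------------------------------------------------------------------
// Needleman-Wunsch DP over a position score matrix (linear gap penalty)
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
IntegerMatrix nw_align_cpp(NumericMatrix S, double gap) {
  int n = S.nrow(), m = S.ncol();
  std::vector<double> M((n + 1) * (m + 1), 0.0);
  std::vector<unsigned char> tb((n + 1) * (m + 1), 0);  // 1 diag, 2 up, 3 left
  for (int i = 1; i <= n; i++) { M[i * (m + 1)] = i * gap; tb[i * (m + 1)] = 2; }
  for (int j = 1; j <= m; j++) { M[j] = j * gap; tb[j] = 3; }
  for (int i = 1; i <= n; i++) {
    for (int j = 1; j <= m; j++) {
      double d = M[(i - 1) * (m + 1) + j - 1] + S(i - 1, j - 1);
      double u = M[(i - 1) * (m + 1) + j] + gap;
      double l = M[i * (m + 1) + j - 1] + gap;
      double best = d; unsigned char t = 1;
      if (u > best) { best = u; t = 2; }
      if (l > best) { best = l; t = 3; }
      M[i * (m + 1) + j] = best;
      tb[i * (m + 1) + j] = t;
    }
  }
  std::vector<int> pi, pj;
  int i = n, j = m;
  while (i > 0 || j > 0) {
    unsigned char t = tb[i * (m + 1) + j];
    if (t == 1) { pi.push_back(i); pj.push_back(j); i--; j--; }
    else if (t == 2) i--;
    else j--;
  }
  int k = pi.size();
  IntegerMatrix pairs(k, 2);
  for (int q = 0; q < k; q++) {
    pairs(q, 0) = pi[k - 1 - q];
    pairs(q, 1) = pj[k - 1 - q];
  }
  return pairs;
}

// ---------------------------------------------------------------------------
// Pairwise BLOSUM62-derived distance matrix
// ---------------------------------------------------------------------------

// seq_mat: n x L integer codes (0..19); dtab: 20 x 20 per-position distances
// [[Rcpp::export]]
NumericMatrix seq_dist_matrix_cpp(IntegerMatrix seq_mat, NumericMatrix dtab) {
  int n = seq_mat.nrow(), L = seq_mat.ncol();
  std::vector<int> s(n * L);
  for (int i = 0; i < n; i++)
    for (int j = 0; j < L; j++) s[i * L + j] = seq_mat(i, j);
  double dt[400];
  for (int a = 0; a < 20; a++)
    for (int b = 0; b < 20; b++) dt[a * 20 + b] = dtab(a, b);
  NumericMatrix D(n, n);
  for (int i = 0; i < n; i++) {
    const int* si = &s[i * L];
    for (int j = i + 1; j < n; j++) {
      const int* sj = &s[j * L];
      double acc = 0;
      for (int k = 0; k < L; k++) acc += dt[si[k] * 20 + sj[k]];
      acc /= L;
      D(i, j) = acc;
      D(j, i) = acc;
    }
  }
  return D;
}
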