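#include <Rcpp.h>
#include <cstdint>
#include <cmath>
#include <vector>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// RNG: splitmix64 stream, one uniform draw per trial.  Private to the agent
// core so that runs are reproducible independently of R's RNG state, and so
// that common-random-number comparisons across parameter sets stay aligned
// (every candidate consumes exactly one draw per trial).
// ---------------------------------------------------------------------------
struct SplitMix {
  uint64_t s;
  explicit SplitMix(uint64_t seed) : s(seed) {}
  double unif() {
    s += 0x9E3779B97F4A7C15ULL;
    uint64_t z = s;
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    z ^= (z >> 31);
    // 53-bit mantissa in [0, 1)
    return (double)(z >> 11) * (1.0 / 9007199254740992.0);
  }
};

// Arm coding: 1, 2, 3 are track arms (1 and 3 outer, 2 center); 0 is the
// session-start sentinel.  State index (0-based): (prev-1)*3 + (cur-1) for
// arm/arm pairs (rows 0..8, includes the 3 never-visited same-arm rows of
// the 13x3 propensity matrix), 9 + (cur-1) for (start, arm), 12 for
// (start, start).
static inline int state_idx(int prev, int cur) {
  if (prev == 0 && cur == 0) return 12;
  if (prev == 0) return 9 + (cur - 1);
  return (prev - 1) * 3 + (cur - 1);
}

static inline bool is_neighbor(int cur, int a) {
  if (cur < 1 || cur > 3) return false;
  int d = cur - a;
  return d == 1 || d == -1;
}

// Reward-delivery algorithm.  last_outer = 0 means no outer arm visited yet
// this session (only possible when the center arm was the session's first
// visit, in which case either outer arm is rewarded).
static inline int reward_of(int cur, int choice, int last_outer) {
  if (cur != 2) return choice == 2 ? 1 : 0; // includes session start (cur==0)
  if (last_outer == 0) return 1;            // first-visit-center exception
  return choice == (last_outer == 1 ? 3 : 1) ? 1 : 0;
}

struct Agent {
  double b[13][3];
  double bi[3];
  double bn1;
  double V[13];
  double alpha, gamma, clamp;
  bool has_bi, has_bn, upd_bi, upd_bn;

  void init(double alpha_, double gamma_, double init_bias, double clamp_,
            bool has_bi_, bool has_bn_, bool upd_bi_, bool upd_bn_) {
    alpha = alpha_; gamma = gamma_; clamp = clamp_;
    has_bi = has_bi_; has_bn = has_bn_; upd_bi = upd_bi_; upd_bn = upd_bn_;
    for (int s = 0; s < 13; s++) {
      b[s][0] = init_bias; b[s][1] = 0.0; b[s][2] = init_bias;
      V[s] = 0.0;
    }
    bi[0] = has_bi ? init_bias : 0.0;
    bi[1] = 0.0;
    bi[2] = has_bi ? init_bias : 0.0;
    bn1 = 0.0;
  }

  // softmax policy over allowed arms; p[cur-1] forced to 0
  void policy(int prev, int cur, double *p) const {
    int s = state_idx(prev, cur);
    double m[3];
    for (int a = 0; a < 3; a++) {
      m[a] = b[s][a];
      if (has_bi) m[a] += bi[a];
      if (has_bn && is_neighbor(cur, a + 1)) m[a] += bn1;
    }
    double mx = -1e300;
    for (int a = 0; a < 3; a++)
      if (a + 1 != cur && m[a] > mx) mx = m[a];
    double tot = 0.0;
    for (int a = 0; a < 3; a++) {
      p[a] = (a + 1 == cur) ? 0.0 : std::exp(m[a] - mx);
      tot += p[a];
    }
    for (int a = 0; a < 3; a++) p[a] /= tot;
  }

  void update(int prev, int cur, int chosen, const double *p, double delta) {
    int s = state_idx(prev, cur);
    double ad = alpha * delta;
    double gn = 0.0;
    for (int a = 0; a < 3; a++) {
      double g = ((a + 1 == chosen) ? 1.0 : 0.0) - p[a];
      b[s][a] += ad * g;
      if (b[s][a] > clamp) b[s][a] = clamp;
      if (b[s][a] < -clamp) b[s][a] = -clamp;
      if (upd_bi) {
        bi[a] += ad * g;
        if (bi[a] > clamp) bi[a] = clamp;
        if (bi[a] < -clamp) bi[a] = -clamp;
      }
      if (is_neighbor(cur, a + 1)) gn += g;
    }
    if (upd_bn) {
      bn1 += ad * gn;
      if (bn1 > clamp) bn1 = clamp;
      if (bn1 < -clamp) bn1 = -clamp;
    }
    V[s] += ad;
  }
};

// Simulate one agent; fills per-visit arrays (length = total visits).
static void run_core(Agent &ag, SplitMix &rng, const IntegerVector &sess_len,
                     int *arm, int *rew, int *sess, double *udraws) {
  int v = 0;
  for (int si = 0; si < sess_len.size(); si++) {
    int prev = 0, cur = 0, last_outer = 0;
    int len = sess_len[si];
    for (int t = 0; t < len; t++) {
      double p[3];
      ag.policy(prev, cur, p);
      double u = rng.unif();
      if (udraws) udraws[v] = u;
      int choice = 3;
      double acc = 0.0;
      for (int a = 0; a < 3; a++) {
        acc += p[a];
        if (u < acc) { choice = a + 1; break; }
      }
      int r = reward_of(cur, choice, last_outer);
      arm[v] = choice; rew[v] = r; sess[v] = si + 1;
      int s = state_idx(prev, cur);
      int snext = state_idx(cur, choice);
      double vnext = (t == len - 1) ? 0.0 : ag.V[snext]; // session end terminal
      double delta = r + ag.gamma * vnext - ag.V[s];
      ag.update(prev, cur, choice, p, delta);
      if (choice != 2) last_outer = choice;
      prev = cur; cur = choice;
      v++;
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_rng_uniforms(int seed, int n) {
  SplitMix rng((uint64_t)(uint32_t)seed);
  NumericVector out(n);
  for (int i = 0; i < n; i++) out[i] = rng.unif();
  return out;
}

// [[Rcpp::export]]
List cpp_run_agent(double alpha, double gamma, double init_bias,
                   bool has_bi, bool has_bn, bool upd_bi, bool upd_bn,
                   int seed, IntegerVector session_lengths, double clamp,
                   bool return_u) {
  int n = 0;
  for (int i = 0; i < session_lengths.size(); i++) n += session_lengths[i];
  IntegerVector arm(n), rew(n), sess(n);
  NumericVector u(return_u ? n : 0);
  Agent ag;
  ag.init(alpha, gamma, init_bias, clamp, has_bi, has_bn, upd_bi, upd_bn);
  SplitMix rng((uint64_t)(uint32_t)seed);
  run_core(ag, rng, session_lengths, arm.begin(), rew.begin(), sess.begin(),
           return_u ? u.begin() : (double *)0);
  NumericMatrix bmat(13, 3);
  NumericVector biv(3), Vv(13);
  for (int s = 0; s < 13; s++) {
    for (int a = 0; a < 3; a++) bmat(s, a) = ag.b[s][a];
    Vv[s] = ag.V[s];
  }
  for (int a = 0; a < 3; a++) biv[a] = ag.bi[a];
  return List::create(_["arm"] = arm, _["reward"] = rew, _["session"] = sess,
                      _["u"] = u, _["b"] = bmat, _["bi"] = biv,
                      _["bn1"] = ag.bn1, _["V"] = Vv);
}

// [[Rcpp::export]]
List cpp_ensemble_raw(double alpha, double gamma, double init_bias,
                      bool has_bi, bool has_bn, IntegerVector seeds,
                      IntegerVector session_lengths, double clamp) {
  int n = 0;
  for (int i = 0; i < session_lengths.size(); i++) n += session_lengths[i];
  int R = seeds.size();
  IntegerMatrix arm(n, R), rew(n, R), sess(n, R);
  for (int r = 0; r < R; r++) {
    Agent ag;
    ag.init(alpha, gamma, init_bias, clamp, has_bi, has_bn, has_bi, has_bn);
    SplitMix rng((uint64_t)(uint32_t)seeds[r]);
    run_core(ag, rng, session_lengths, &arm(0, r), &rew(0, r), &sess(0, r),
             (double *)0);
  }
  return List::create(_["arm"] = arm, _["reward"] = rew, _["session"] = sess);
}

// Gaussian smoothing with edge-inclusive reflection padding; kernel radius
// ceil(4*sd).  Must stay in lockstep with the R implementation smooth_binary().
static std::vector<double> gsmooth(const std::vector<double> &x, double sd) {
  int n = (int)x.size();
  std::vector<double> y(n, 0.0);
  if (n == 0) return y;
  int r = (int)std::ceil(4.0 * sd);
  if (r < 1) r = 1;
  std::vector<double> w(2 * r + 1);
  double tot = 0.0;
  for (int k = -r; k <= r; k++) {
    w[k + r] = std::exp(-0.5 * (double)k * k / (sd * sd));
    tot += w[k + r];
  }
  for (int k = 0; k < 2 * r + 1; k++) w[k] /= tot;
  for (int i = 0; i < n; i++) {
    double acc = 0.0;
    for (int k = -r; k <= r; k++) {
      int j = i + k;
      while (j < 0 || j >= n) {
        if (j < 0) j = -j - 1;
        if (j >= n) j = 2 * n - 1 - j;
      }
      acc += w[k + r] * x[j];
    }
    y[i] = acc;
  }
  return y;
}

// Linear interpolation of (idx, val) onto 0..window-1, ends held flat.
static void interp_to(const std::vector<int> &idx, const std::vector<double> &val,
                      int window, double *out) {
  int k = (int)idx.size();
  if (k == 0) {
    for (int t = 0; t < window; t++) out[t] = NA_REAL;
    return;
  }
  int j = 0;
  for (int t = 0; t < window; t++) {
    if (t <= idx[0]) { out[t] = val[0]; continue; }
    if (t >= idx[k - 1]) { out[t] = val[k - 1]; continue; }
    while (idx[j + 1] < t) j++;
    double f = (double)(t - idx[j]) / (double)(idx[j + 1] - idx[j]);
    out[t] = val[j] + f * (val[j + 1] - val[j]);
  }
}

// Ensemble simulation + per-repeat smoothing/interpolation + across-repeat
// mean and SEM, all in one pass.  Returns, over the first `window` visits:
//   reward_mean/sem    smoothed reward probability curve
//   inbound_mean/sem   smoothed + interpolated inbound error curve
//   outbound_mean/sem  likewise for outbound errors
//   raw_reward_mean    unsmoothed per-visit reward probability
//   total_reward       mean per-repeat summed reward over the window
// `what` selects the work done: 0 = everything, 1 = reward curve only,
// 2 = error curves only, 3 = totals only (raw reward trace and mean total
// reward are always produced).
// [[Rcpp::export]]
List cpp_ensemble_curves(double alpha, double gamma, double init_bias,
                         bool has_bi, bool has_bn, IntegerVector seeds,
                         IntegerVector session_lengths, double sd, int window,
                         double clamp, int what) {
  bool do_reward = (what == 0 || what == 1);
  bool do_err = (what == 0 || what == 2);
  int n = 0;
  for (int i = 0; i < session_lengths.size(); i++) n += session_lengths[i];
  if (window > n) window = n;
  int R = seeds.size();
  std::vector<int> arm(n), rew(n), sess(n);
  std::vector<double> rsum(window, 0.0), rsq(window, 0.0);
  std::vector<double> isum(window, 0.0), isq(window, 0.0);
  std::vector<double> osum(window, 0.0), osq(window, 0.0);
  std::vector<double> rawsum(window, 0.0);
  double total = 0.0;
  int n_in = 0, n_out = 0;
  std::vector<double> buf(window);

  for (int r = 0; r < R; r++) {
    Agent ag;
    ag.init(alpha, gamma, init_bias, clamp, has_bi, has_bn, has_bi, has_bn);
    SplitMix rng((uint64_t)(uint32_t)seeds[r]);
    run_core(ag, rng, session_lengths, arm.data(), rew.data(), sess.data(),
             (double *)0);

    // reward curve over the analysis window (smoothing window-restricted,
    // matching the R metrics which smooth the first `window` visits)
    std::vector<double> rv(window);
    for (int t = 0; t < window; t++) rv[t] = (double)rew[t];
    for (int t = 0; t < window; t++) {
      rawsum[t] += rv[t];
      total += rv[t];
    }
    if (do_reward) {
      std::vector<double> srv = gsmooth(rv, sd);
      for (int t = 0; t < window; t++) {
        rsum[t] += srv[t]; rsq[t] += srv[t] * srv[t];
      }
    }

    if (do_err) {
      // trial types: a visit departs from the previous visit's arm (session
      // start if it is the first visit of its session); inbound unless the
      // departure arm is the center arm
      std::vector<int> iidx, oidx;
      std::vector<double> ierr, oerr;
      for (int t = 0; t < window; t++) {
        int from = (t == 0 || sess[t] != sess[t - 1]) ? 0 : arm[t - 1];
        if (from == 2) { oidx.push_back(t); oerr.push_back(1.0 - rew[t]); }
        else           { iidx.push_back(t); ierr.push_back(1.0 - rew[t]); }
      }
      if (iidx.size() >= 3) {
        std::vector<double> s1 = gsmooth(ierr, sd);
        interp_to(iidx, s1, window, buf.data());
        for (int t = 0; t < window; t++) { isum[t] += buf[t]; isq[t] += buf[t] * buf[t]; }
        n_in++;
      }
      if (oidx.size() >= 3) {
        std::vector<double> s2 = gsmooth(oerr, sd);
        interp_to(oidx, s2, window, buf.data());
        for (int t = 0; t < window; t++) { osum[t] += buf[t]; osq[t] += buf[t] * buf[t]; }
        n_out++;
      }
    }
  }

  NumericVector rm(window), rs(window), im(window), is(window), om(window),
      os(window), raw(window);
  for (int t = 0; t < window; t++) {
    rm[t] = rsum[t] / R;
    double vr = (R > 1) ? (rsq[t] - rsum[t] * rsum[t] / R) / (R - 1) : 0.0;
    rs[t] = (R > 1) ? std::sqrt(std::max(0.0, vr) / R) : 0.0;
    im[t] = n_in > 0 ? isum[t] / n_in : NA_REAL;
    double vi = (n_in > 1) ? (isq[t] - isum[t] * isum[t] / n_in) / (n_in - 1) : 0.0;
    is[t] = (n_in > 1) ? std::sqrt(std::max(0.0, vi) / n_in) : 0.0;
    om[t] = n_out > 0 ? osum[t] / n_out : NA_REAL;
    double vo = (n_out > 1) ? (osq[t] - osum[t] * osum[t] / n_out) / (n_out - 1) : 0.0;
    os[t] = (n_out > 1) ? std::sqrt(std::max(0.0, vo) / n_out) : 0.0;
    raw[t] = rawsum[t] / R;
  }
  return List::create(
      _["reward_mean"] = rm, _["reward_sem"] = rs, _["inbound_mean"] = im,
      _["inbound_sem"] = is, _["outbound_mean"] = om, _["outbound_sem"] = os,
      _["raw_reward_mean"] = raw, _["total_reward"] = total / R,
      _["n_inbound_traces"] = n_in, _["n_outbound_traces"] = n_out);
}
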