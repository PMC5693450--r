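// Sequential engine for the ten candidate learning models.
//
// Everything that must run once per trial lives here: belief updates,
// choice probabilities, whole-session replays, log-likelihoods and
// agent-vs-agent game loops. The R layer owns parameter handling,
// fitting and statistics.
//
// Payoff tables are stored flat as u[a_self*2 + a_op] with binary actions.
// A k-ToM state is a flat double vector (see layout notes at ktom_size).

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static const double A_ES = 3.0 / (M_PI * M_PI); // logistic-probit moment matching
static const double P_EPS = 1e-4;               // probability clamp
static const double FD_DELTA = 1e-4;            // replica offset for W^kappa
// replica parameter offsets (dim 0: log volatility, dim 1: log temperature)
static const double OFF[5][2] = {
  {0.0, 0.0},
  { FD_DELTA, 0.0}, {-FD_DELTA, 0.0},
  {0.0,  FD_DELTA}, {0.0, -FD_DELTA}
};

static inline double sgm(double x) {
  if (x >= 0) { double e = std::exp(-x); return 1.0 / (1.0 + e); }
  double e = std::exp(x); return e / (1.0 + e);
}
static inline double clampp(double p) {
  return std::min(1.0 - P_EPS, std::max(P_EPS, p));
}
// E[s(x)] for x ~ N(m, v), moment-matched closed form
static inline double es_gauss(double m, double v) {
  return sgm(m / std::sqrt(1.0 + A_ES * std::max(v, 0.0)));
}
// expected payoff difference dV given P(a_op = 1)
static inline double dvf(const double* u, double p) {
  return p * (u[3] - u[1]) + (1.0 - p) * (u[2] - u[0]);
}
// one 0-ToM update (Eq. 3 style): belief (m, s) about the other's log-odds
static inline void tom0_up(double& m, double& s, double vol, int a) {
  double sm = sgm(m);
  double snew = 1.0 / (1.0 / (s + vol) + sm * (1.0 - sm));
  m = m + snew * ((double)a - sm);
  s = snew;
}

// ---------------------------------------------------------------------------
// k-ToM flat state layout, for level k >= 1:
//   [0, k)                    lambda: posterior over opponent level kappa < k
//   then for kappa = 0..k-1:
//     mu[2], sig[3] (s11, s12, s22)
//     5 replica simulations of the opponent model at theta = mu + OFF[j],
//     each of size sub_size(kappa): kappa = 0 -> (m, s) of its 0-ToM tracker,
//     kappa >= 1 -> a full nested k-ToM state of size ktom_size(kappa).
// ---------------------------------------------------------------------------

static int ktom_size(int k);
static inline int sub_size(int kap) { return kap == 0 ? 2 : ktom_size(kap); }
static int ktom_size(int k) {
  int sz = k;
  for (int kap = 0; kap < k; ++kap) sz += 5 + 5 * sub_size(kap);
  return sz;
}

static void ktom_init(int k, double* st) {
  for (int i = 0; i < k; ++i) st[i] = 1.0 / k;
  double* p = st + k;
  for (int kap = 0; kap < k; ++kap) {
    p[0] = 0.0; p[1] = 0.0;            // mu
    p[2] = 1.0; p[3] = 0.0; p[4] = 1.0; // sigma = I
    p += 5;
    int ss = sub_size(kap);
    for (int j = 0; j < 5; ++j) {
      if (kap == 0) { p[0] = 0.0; p[1] = 1.0; }
      else ktom_init(kap, p);
      p += ss;
    }
  }
}

static double ktom_logodds(int k, const double* st, const double* u_own,
                           const double* u_oth, double beta, double bias);

// predicted choice log-odds of the simulated kappa-level opponent, replica j.
// u_oth is the opponent's own payoff table, u_own is mine (what the opponent
// presumes about me, one recursion level down).
static double ktom_vrep(int kap, const double* rep, const double* mu, int j,
                        const double* u_own, const double* u_oth) {
  double beta = std::exp(mu[1] + OFF[j][1]);
  if (kap == 0) {
    double pself = es_gauss(rep[0], rep[1]); // its prediction of my action
    return dvf(u_oth, pself) / beta;
  }
  return ktom_logodds(kap, rep, u_oth, u_own, beta, 0.0);
}

// per-level prediction statistics: choice log-odds at the posterior mean,
// its gradient W wrt the hidden states (central differences over the
// replica simulations) and the uncertainty-marginalised probability
// E[s(v(x))] ~ s(v(mu) / sqrt(1 + a * W' Sigma W)).
struct LevelStats { double v, w0, w1, pmarg; };

static LevelStats ktom_level_stats(int kap, const double* block,
                                   const double* u_own, const double* u_oth) {
  const double* mu = block;
  const double* sg = block + 2;
  int ss = sub_size(kap);
  double vj[5];
  for (int j = 0; j < 5; ++j)
    vj[j] = ktom_vrep(kap, block + 5 + j * ss, mu, j, u_own, u_oth);
  LevelStats out;
  out.v = vj[0];
  out.w0 = (vj[1] - vj[2]) / (2.0 * FD_DELTA);
  out.w1 = (vj[3] - vj[4]) / (2.0 * FD_DELTA);
  double qf = sg[0] * out.w0 * out.w0 + 2.0 * sg[1] * out.w0 * out.w1 +
              sg[2] * out.w1 * out.w1;
  out.pmarg = sgm(out.v / std::sqrt(1.0 + A_ES * std::max(qf, 0.0)));
  return out;
}

// level-marginal prediction P(a_op = 1)
static double ktom_pop(int k, const double* st, const double* u_own,
                       const double* u_oth) {
  const double* lam = st;
  const double* p = st + k;
  double pop = 0.0;
  for (int kap = 0; kap < k; ++kap) {
    pop += lam[kap] * ktom_level_stats(kap, p, u_own, u_oth).pmarg;
    p += 5 + 5 * sub_size(kap);
  }
  return pop;
}

static double ktom_logodds(int k, const double* st, const double* u_own,
                           const double* u_oth, double beta, double bias) {
  double pop = ktom_pop(k, st, u_own, u_oth);
  return dvf(u_own, pop) / beta + bias;
}

// full trial update (Eq. 4 style, level-weighted as printed):
// a_self is this agent's action, a_op the opponent's.
static void ktom_update(int k, double* st, int a_self, int a_op, double volk,
                        const double* u_own, const double* u_oth) {
  double* lam = st;
  std::vector<double> vc(k), W0(k), W1(k), pk(k);
  {
    const double* p = st + k;
    for (int kap = 0; kap < k; ++kap) {
      LevelStats ls = ktom_level_stats(kap, p, u_own, u_oth);
      vc[kap] = ls.v;
      W0[kap] = ls.w0;
      W1[kap] = ls.w1;
      pk[kap] = clampp(ls.pmarg);
      p += 5 + 5 * sub_size(kap);
    }
  }
  // Bayes update of the level posterior
  double tot = 0.0;
  for (int kap = 0; kap < k; ++kap) {
    lam[kap] *= (a_op == 1) ? pk[kap] : (1.0 - pk[kap]);
    tot += lam[kap];
  }
  if (tot <= 0.0 || !std::isfinite(tot)) {
    for (int kap = 0; kap < k; ++kap) lam[kap] = 1.0 / k;
  } else {
    for (int kap = 0; kap < k; ++kap) lam[kap] /= tot;
  }
  // Laplace-style update of each level's hidden-state belief
  {
    double* p = st + k;
    for (int kap = 0; kap < k; ++kap) {
      double* mu = p;
      double* sg = p + 2;
      double s11 = sg[0] + volk, s12 = sg[1], s22 = sg[2] + volk;
      double det = s11 * s22 - s12 * s12;
      if (det < 1e-12) { s11 += 1e-6; s22 += 1e-6; det = s11 * s22 - s12 * s12; }
      // precision = inv(prior cov) + s'(v) * lambda * W W^T
      double q11 = s22 / det, q12 = -s12 / det, q22 = s11 / det;
      double sp = sgm(vc[kap]) * (1.0 - sgm(vc[kap]));
      double w0 = W0[kap], w1 = W1[kap], l = lam[kap];
      q11 += sp * l * w0 * w0;
      q12 += sp * l * w0 * w1;
      q22 += sp * l * w1 * w1;
      // ridge keeps the precision invertible when the prior is very flat
      // and the trial information is rank-1
      double ridge = 1e-9 * (1.0 + q11 + q22);
      q11 += ridge; q22 += ridge;
      double qdet = q11 * q22 - q12 * q12;
      if (qdet <= 0 || !std::isfinite(qdet))
        stop("degenerate covariance in k-ToM update (level %d)", kap);
      double n11 = q22 / qdet, n12 = -q12 / qdet, n22 = q11 / qdet;
      sg[0] = n11; sg[1] = n12; sg[2] = n22;
      double innov = (double)a_op - sgm(vc[kap]);
      mu[0] += l * (n11 * w0 + n12 * w1) * innov;
      mu[1] += l * (n12 * w0 + n22 * w1) * innov;
      // soft bounds keep exp() finite without touching ordinary trajectories
      for (int i = 0; i < 2; ++i)
        mu[i] = std::max(-12.0, std::min(12.0, mu[i]));
      p += 5 + 5 * sub_size(kap);
    }
  }
  // propagate the replica opponents with the observed actions
  {
    double* p = st + k;
    for (int kap = 0; kap < k; ++kap) {
      double* mu = p;
      int ss = sub_size(kap);
      double* rep = p + 5;
      for (int j = 0; j < 5; ++j, rep += ss) {
        double volj = std::exp(mu[0] + OFF[j][0]);
        if (kap == 0) {
          // opponent's 0-ToM tracker observes MY action
          tom0_up(rep[0], rep[1], volj, a_self);
        } else {
          // nested opponent: its own action is a_op, its opponent's is a_self
          ktom_update(kap, rep, a_op, a_self, volj, u_oth, u_own);
        }
      }
      p += 5 + 5 * ss;
    }
  }
}

// ---------------------------------------------------------------------------
// Generic agent wrapper
// ---------------------------------------------------------------------------

enum ModelCode { M_BN = 0, M_WS = 1, M_RL = 2, M_TOM0 = 3, M_INF = 4, M_KTOM = 5 };

struct Cfg {
  int model, level, icomp;
  double beta, bias, vol, alpha, eta, lam;
  double u_own[4], u_oth[4];
};

struct St {
  double V0, V1;   // action values (WS, RL)
  double m, s;     // 0-ToM belief
  double pop;      // influence-learning tracker
  std::vector<double> kst;
};

static void flatten_u(const NumericMatrix& m, double* u) {
  for (int a = 0; a < 2; ++a)
    for (int b = 0; b < 2; ++b)
      u[a * 2 + b] = m(a, b);
}

static Cfg parse_cfg(const List& cfg) {
  Cfg c;
  c.model = as<int>(cfg["model"]);
  c.level = cfg.containsElementNamed("level") ? as<int>(cfg["level"]) : 0;
  c.icomp = cfg.containsElementNamed("icomp") ? as<int>(cfg["icomp"]) : 1;
  c.beta  = cfg.containsElementNamed("beta")  ? as<double>(cfg["beta"])  : 1.0;
  c.bias  = cfg.containsElementNamed("bias")  ? as<double>(cfg["bias"])  : 0.0;
  c.vol   = cfg.containsElementNamed("vol")   ? as<double>(cfg["vol"])   : 0.5;
  c.alpha = cfg.containsElementNamed("alpha") ? as<double>(cfg["alpha"]) : 0.5;
  c.eta   = cfg.containsElementNamed("eta")   ? as<double>(cfg["eta"])   : 0.5;
  c.lam   = cfg.containsElementNamed("lambda") ? as<double>(cfg["lambda"]) : 0.5;
  flatten_u(as<NumericMatrix>(cfg["u_own"]), c.u_own);
  flatten_u(as<NumericMatrix>(cfg["u_oth"]), c.u_oth);
  if (!(c.beta > 0)) stop("behavioural temperature must be positive");
  return c;
}

static void st_init(const Cfg& c, St& s) {
  s.V0 = s.V1 = 0.0;
  s.m = 0.0; s.s = 1.0;
  s.pop = 0.5;
  if (c.model == M_KTOM) {
    s.kst.assign(ktom_size(c.level), 0.0);
    ktom_init(c.level, s.kst.data());
  }
}

static double agent_p1(const Cfg& c, const St& s) {
  double dv = 0.0;
  switch (c.model) {
    case M_BN:   dv = 0.0; break;
    case M_WS:
    case M_RL:   dv = s.V1 - s.V0; break;
    case M_TOM0: dv = dvf(c.u_own, es_gauss(s.m, s.s)); break;
    case M_INF:  dv = dvf(c.u_own, s.pop); break;
    case M_KTOM: dv = dvf(c.u_own, ktom_pop(c.level, s.kst.data(), c.u_own, c.u_oth)); break;
    default: stop("unknown model code");
  }
  return sgm(dv / c.beta + c.bias);
}

static void agent_up(const Cfg& c, St& s, int a_self, int a_op) {
  double R = c.u_own[a_self * 2 + a_op];
  switch (c.model) {
    case M_BN: break;
    case M_WS: {
      double* vch = a_self == 1 ? &s.V1 : &s.V0;
      double* vot = a_self == 1 ? &s.V0 : &s.V1;
      *vch = R; *vot = -R;
      break;
    }
    case M_RL: {
      double* vch = a_self == 1 ? &s.V1 : &s.V0;
      *vch += c.alpha * (R - *vch);
      break;
    }
    case M_TOM0:
      tom0_up(s.m, s.s, c.vol, a_op);
      break;
    case M_INF: {
      double p = s.pop;
      double si = std::log(p / (1.0 - p));
      double adj = 2.0 * a_self + (2.0 * c.icomp - 1.0) * c.beta * si + c.icomp;
      p = p + c.eta * ((double)a_op - p) - c.lam * p * (1.0 - p) * adj;
      s.pop = clampp(p);
      break;
    }
    case M_KTOM:
      ktom_update(c.level, s.kst.data(), a_self, a_op, c.vol, c.u_own, c.u_oth);
      break;
  }
}

// ---------------------------------------------------------------------------
// Exported interface
// ---------------------------------------------------------------------------

// per-trial P(a_self = 1) from replaying a recorded history
// [[Rcpp::export]]
NumericVector replay_probs_cpp(List cfg, IntegerVector a_self, IntegerVector a_op) {
  Cfg c = parse_cfg(cfg);
  St s; st_init(c, s);
  int n = a_self.size();
  if (a_op.size() != n) stop("action sequences differ in length");
  NumericVector out(n);
  for (int t = 0; t < n; ++t) {
    out[t] = agent_p1(c, s);
    agent_up(c, s, a_self[t], a_op[t]);
  }
  return out;
}

// summed Bernoulli log-likelihood over sessions (state resets per session)
// [[Rcpp::export]]
double loglik_sessions_cpp(List cfg, List sess_self, List sess_op) {
  Cfg c = parse_cfg(cfg);
  double ll = 0.0;
  int ns = sess_self.size();
  for (int i = 0; i < ns; ++i) {
    IntegerVector as = sess_self[i], ao = sess_op[i];
    St s; st_init(c, s);
    int n = as.size();
    for (int t = 0; t < n; ++t) {
      double p = clampp(agent_p1(c, s));
      if (!std::isfinite(p)) stop("non-finite choice probability at trial %d", t + 1);
      ll += as[t] == 1 ? std::log(p) : std::log(1.0 - p);
      agent_up(c, s, as[t], ao[t]);
    }
  }
  return ll;
}

// simultaneous-move game between two model agents; uniform draws supplied by R
// [[Rcpp::export]]
List simulate_game_cpp(List cfgA, List cfgB, int n_trials,
                       NumericVector drawsA, NumericVector drawsB) {
  Cfg ca = parse_cfg(cfgA), cb = parse_cfg(cfgB);
  St sa, sb; st_init(ca, sa); st_init(cb, sb);
  IntegerVector aA(n_trials), aB(n_trials);
  NumericVector pA(n_trials), pB(n_trials);
  for (int t = 0; t < n_trials; ++t) {
    pA[t] = agent_p1(ca, sa);
    pB[t] = agent_p1(cb, sb);
    aA[t] = drawsA[t] < pA[t] ? 1 : 0;
    aB[t] = drawsB[t] < pB[t] ? 1 : 0;
    agent_up(ca, sa, aA[t], aB[t]);
    agent_up(cb, sb, aB[t], aA[t]);
  }
  return List::create(_["a_a"] = aA, _["a_b"] = aB, _["p_a"] = pA, _["p_b"] = pB);
}

// one model agent against a pre-recorded opponent sequence
// [[Rcpp::export]]
List play_vs_seq_cpp(List cfg, IntegerVector a_op, NumericVector draws) {
  Cfg c = parse_cfg(cfg);
  St s; st_init(c, s);
  int n = a_op.size();
  IntegerVector a(n);
  NumericVector p(n);
  for (int t = 0; t < n; ++t) {
    p[t] = agent_p1(c, s);
    a[t] = draws[t] < p[t] ? 1 : 0;
    agent_up(c, s, a[t], a_op[t]);
  }
  return List::create(_["a_self"] = a, _["p_self"] = p);
}

// [[Rcpp::export]]
NumericVector ktom_init_cpp(int level) {
  if (level < 1) stop("level must be >= 1");
  NumericVector st(ktom_size(level));
  ktom_init(level, st.begin());
  return st;
}

// [[Rcpp::export]]
int ktom_size_cpp(int level) { return ktom_size(level); }

// [[Rcpp::export]]
NumericVector ktom_step_cpp(int level, NumericVector state, int a_self, int a_op,
                            double vol, NumericMatrix u_own, NumericMatrix u_oth) {
  if (state.size() != ktom_size(level)) stop("state has wrong length for level");
  NumericVector out = clone(state);
  double uo[4], ut[4];
  flatten_u(u_own, uo); flatten_u(u_oth, ut);
  ktom_update(level, out.begin(), a_self, a_op, vol, uo, ut);
  return out;
}

// marginal prediction and per-level components of a k-ToM state
// [[Rcpp::export]]
List ktom_parts_cpp(int level, NumericVector state,
                    NumericMatrix u_own, NumericMatrix u_oth) {
  if (state.size() != ktom_size(level)) stop("state has wrong length for level");
  double uo[4], ut[4];
  flatten_u(u_own, uo); flatten_u(u_oth, ut);
  const double* st = state.begin();
  NumericVector lambda(level), pk(level);
  List mus(level), sigs(level);
  const double* p = st + level;
  for (int kap = 0; kap < level; ++kap) {
    lambda[kap] = st[kap];
    NumericVector mu = NumericVector::create(p[0], p[1]);
    NumericMatrix sg(2, 2);
    sg(0, 0) = p[2]; sg(0, 1) = p[3]; sg(1, 0) = p[3]; sg(1, 1) = p[4];
    mus[kap] = mu; sigs[kap] = sg;
    pk[kap] = ktom_level_stats(kap, p, uo, ut).pmarg;
    p += 5 + 5 * sub_size(kap);
  }
  double pop = ktom_pop(level, st, uo, ut);
  return List::create(_["level_post"] = lambda, _["state_mean"] = mus,
                      _["state_cov"] = sigs, _["p_op_by_level"] = pk,
                      _["p_op"] = pop);
}
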