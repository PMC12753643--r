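#include <Rcpp.h>
using namespace Rcpp;

// Model codes (kept in sync with R/models.R):
//   1 stim_only, 2 action_only, 3 static_omega, 4 dynamic_omega, 5 dynamic_omega_rho
// Reliability-signal codes: 1 v_cho, 2 abs_rpe, 3 abs_dv, 4 sum_v
// Parameter vector layout (length 10):
//   0 alpha_pos, 1 alpha_neg, 2 zeta, 3 beta1, 4 beta0,
//   5 omega_static, 6 omega0, 7 alpha_omega, 8 zeta_omega, 9 rho

static const double P_FLOOR = 1e-10;

struct State {
  double vs[2]; // stimulus values: A, B
  double va[2]; // action values: Left, Right
  double omega;
};

static inline double eff_omega(double omega, double rho) {
  double denom = rho * omega + (1.0 - rho) * (1.0 - omega);
  if (denom <= 0.0) return omega; // degenerate corner: continuity along rho = 0.5
  return rho * omega / denom;
}

static inline void init_state(State &st, int model, const double *par, double v_init) {
  st.vs[0] = st.vs[1] = v_init;
  st.va[0] = st.va[1] = v_init;
  if (model == 3) st.omega = par[5];
  else if (model >= 4) st.omega = par[6];
  else st.omega = NA_REAL;
}

static inline void overall_values(const State &st, int model, const double *par,
                                  int stimA_left, double &ov_l, double &ov_r) {
  int ls = stimA_left ? 0 : 1; // stimulus index shown on the left
  int rs = 1 - ls;
  switch (model) {
  case 1: ov_l = st.vs[ls]; ov_r = st.vs[rs]; break;
  case 2: ov_l = st.va[0]; ov_r = st.va[1]; break;
  case 3:
  case 4: {
    double w = st.omega;
    ov_l = st.vs[ls] * w + st.va[0] * (1.0 - w);
    ov_r = st.vs[rs] * w + st.va[1] * (1.0 - w);
    break;
  }
  default: { // 5: dynamic omega-rho
    double rho = par[9], w = st.omega;
    ov_l = st.vs[ls] * rho * w + st.va[0] * (1.0 - rho) * (1.0 - w);
    ov_r = st.vs[rs] * rho * w + st.va[1] * (1.0 - rho) * (1.0 - w);
  }
  }
}

// Value update (both systems in parallel for two-system models), reliability
// signal, and omega update. The reliability signal indexes the trial's own
// (pre-update) values -- the ones the choice was made with -- so the signed
// chosen-value difference equals RPE_action - RPE_stim on every trial.
static inline void step_update(State &st, int model, const double *par, int rel_kind,
                               int c_s, int c_a, int r,
                               double &drel, double &rpe_s, double &rpe_a,
                               double &dv_cho) {
  rpe_s = (double)r - st.vs[c_s];
  rpe_a = (double)r - st.va[c_a];
  dv_cho = st.vs[c_s] - st.va[c_a];
  drel = NA_REAL;
  if (model >= 4) {
    switch (rel_kind) {
    case 1: drel = dv_cho; break;
    case 2: drel = std::fabs(rpe_a) - std::fabs(rpe_s); break;
    case 3:
      drel = std::fabs(st.vs[0] - st.vs[1]) - std::fabs(st.va[0] - st.va[1]);
      break;
    default:
      drel = (st.vs[0] + st.vs[1]) - (st.va[0] + st.va[1]);
    }
  }
  double alpha = r == 1 ? par[0] : par[1];
  double zeta = par[2];
  if (model != 2) { // stimulus system active
    st.vs[c_s] += alpha * rpe_s;
    st.vs[1 - c_s] *= (1.0 - zeta);
  }
  if (model != 1) { // action system active
    st.va[c_a] += alpha * rpe_a;
    st.va[1 - c_a] *= (1.0 - zeta);
  }
  if (model >= 4) {
    double a_om = par[7], z_om = par[8], om0 = par[6];
    double om = st.omega;
    if (drel > 0) {
      double step = std::min(1.0, a_om * drel);
      om += step * (1.0 - om) + z_om * (om0 - om);
    } else if (drel < 0) {
      double step = std::min(1.0, a_om * (-drel));
      om += step * (0.0 - om) + z_om * (om0 - om);
    } else {
      om += z_om * (om0 - om);
    }
    // clip: the raw drive-plus-decay sum can leave [0,1] only when
    // alpha_omega + zeta_omega > 1
    st.omega = std::min(1.0, std::max(0.0, om));
  }
}

// Negative log-likelihood of observed choices for one or more sessions.
// `session` and `block` are integer run-length labels; state resets at every
// block boundary (action values optionally carried within a session).
// [[Rcpp::export]]
List cpp_session_loglik(int model, NumericVector par, int rel_kind,
                        IntegerVector session, IntegerVector block,
                        IntegerVector stimA_left, IntegerVector choose_right,
                        IntegerVector reward, double v_init, bool carry_action,
                        bool want_traj) {
  int n = block.size();
  const double *p = REAL(par);
  State st;
  init_state(st, model, p, v_init);
  double nll = 0.0;
  NumericMatrix traj = want_traj ? NumericMatrix(n, 9) : NumericMatrix(0, 0);
  for (int t = 0; t < n; ++t) {
    bool new_sess = (t == 0) || (session[t] != session[t - 1]);
    bool new_block = new_sess || (block[t] != block[t - 1]);
    if (new_block) {
      double keep_va0 = st.va[0], keep_va1 = st.va[1];
      init_state(st, model, p, v_init);
      if (carry_action && !new_sess) { st.va[0] = keep_va0; st.va[1] = keep_va1; }
    }
    double ov_l, ov_r;
    overall_values(st, model, p, stimA_left[t], ov_l, ov_r);
    double x = p[3] * (ov_r - ov_l) + p[4];
    double p_right = 1.0 / (1.0 + std::exp(-x));
    double p_obs = choose_right[t] == 1 ? p_right : 1.0 - p_right;
    if (p_obs < P_FLOOR) p_obs = P_FLOOR;
    if (p_obs > 1.0 - P_FLOOR) p_obs = 1.0 - P_FLOOR;
    nll -= std::log(p_obs);
    int ls = stimA_left[t] ? 0 : 1;
    int c_a = choose_right[t];
    int c_s = choose_right[t] ? 1 - ls : ls;
    double om_used = st.omega;
    double Om = model == 5 ? eff_omega(om_used, p[9]) : om_used;
    double drel, rpe_s, rpe_a, dv_cho;
    step_update(st, model, p, rel_kind, c_s, c_a, reward[t], drel, rpe_s, rpe_a,
                dv_cho);
    if (want_traj) {
      traj(t, 0) = ov_l; traj(t, 1) = ov_r; traj(t, 2) = p_right;
      traj(t, 3) = om_used; traj(t, 4) = Om; traj(t, 5) = drel;
      traj(t, 6) = rpe_s; traj(t, 7) = rpe_a; traj(t, 8) = dv_cho;
    }
  }
  if (want_traj) return List::create(_["nll"] = nll, _["traj"] = traj);
  return List::create(_["nll"] = nll);
}

// Generative loop for one block. Choices and rewards are drawn from R's RNG
// stream, so set.seed() in R makes the simulation reproducible.
// `better_first` indexes the initially better target: 0 = stimulus A (What
// blocks) or Left (Where blocks), 1 = stimulus B or Right. The better target
// flips for trials >= reversal.
// [[Rcpp::export]]
List cpp_sim_block(int model, NumericVector par, int rel_kind, int n_trials,
                   int reversal, double p_better, int is_what, int better_first,
                   IntegerVector stimA_left, double v_init,
                   NumericVector va_init, bool want_traj) {
  const double *p = REAL(par);
  State st;
  init_state(st, model, p, v_init);
  if (va_init.size() == 2) { st.va[0] = va_init[0]; st.va[1] = va_init[1]; }
  IntegerVector choose_right(n_trials), reward(n_trials), choice_stim(n_trials);
  NumericMatrix traj = want_traj ? NumericMatrix(n_trials, 9) : NumericMatrix(0, 0);
  for (int t = 0; t < n_trials; ++t) {
    double ov_l, ov_r;
    overall_values(st, model, p, stimA_left[t], ov_l, ov_r);
    double x = p[3] * (ov_r - ov_l) + p[4];
    double p_right = 1.0 / (1.0 + std::exp(-x));
    int ch_r = unif_rand() < p_right ? 1 : 0;
    int ls = stimA_left[t] ? 0 : 1;
    int c_s = ch_r ? 1 - ls : ls;
    int c_a = ch_r;
    int better = (t + 1) >= reversal ? 1 - better_first : better_first;
    bool match = is_what ? (c_s == better) : (c_a == better);
    double p_rew = match ? p_better : 1.0 - p_better;
    int r = unif_rand() < p_rew ? 1 : 0;
    choose_right[t] = ch_r;
    reward[t] = r;
    choice_stim[t] = c_s;
    double om_used = st.omega;
    double Om = model == 5 ? eff_omega(om_used, p[9]) : om_used;
    double drel, rpe_s, rpe_a, dv_cho;
    step_update(st, model, p, rel_kind, c_s, c_a, r, drel, rpe_s, rpe_a, dv_cho);
    if (want_traj) {
      traj(t, 0) = ov_l; traj(t, 1) = ov_r; traj(t, 2) = p_right;
      traj(t, 3) = om_used; traj(t, 4) = Om; traj(t, 5) = drel;
      traj(t, 6) = rpe_s; traj(t, 7) = rpe_a; traj(t, 8) = dv_cho;
    }
  }
  return List::create(_["choose_right"] = choose_right, _["reward"] = reward,
                      _["choice_stim"] = choice_stim, _["traj"] = traj,
                      _["va_final"] = NumericVector::create(st.va[0], st.va[1]));
}
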