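# Model registry. Codes and the parameter-vector layout are shared with the
# C++ engine (src/engine.cpp); do not reorder.
.par_layout <- c("alpha_pos", "alpha_neg", "zeta", "beta1", "beta0",
                 "omega", "omega0", "alpha_omega", "zeta_omega", "rho")

.base_pars <- c("alpha_pos", "alpha_neg", "zeta", "beta1", "beta0")
.dyn_pars <- c(.base_pars, "omega0", "alpha_omega", "zeta_omega")

.rl_models <- list(
  stim_only          = list(code = 1L, rel = 0L, pars = .base_pars),
  action_only        = list(code = 2L, rel = 0L, pars = .base_pars),
  static_omega       = list(code = 3L, rel = 0L, pars = c(.base_pars, "omega")),
  dynamic_omega_vcho   = list(code = 4L, rel = 1L, pars = .dyn_pars),
  dynamic_omega_absrpe = list(code = 4L, rel = 2L, pars = .dyn_pars),
  dynamic_omega_absdv  = list(code = 4L, rel = 3L, pars = .dyn_pars),
  dynamic_omega_sumv   = list(code = 4L, rel = 4L, pars = .dyn_pars),
  dynamic_omega_rho    = list(code = 5L, rel = 1L, pars = c(.dyn_pars, "rho"))
)

.rel_kinds <- c(v_cho = 1L, abs_rpe = 2L, abs_dv = 3L, sum_v = 4L)

#' Model identifiers
#'
#' Stable string identifiers of the implemented choice models:
#' `stim_only` and `action_only` (single-system value learners),
#' `static_omega` (two systems mixed with a fixed weight),
#' `dynamic_omega_{vcho,absrpe,absdv,sumv}` (trial-by-trial arbitration
#' driven by one of four reliability signals), and `dynamic_omega_rho`
#' (dynamic arbitration plus a baseline signal-strength ratio `rho`).
#'
#' @return Character vector of model identifiers.
#' @export
rl_model_ids <- function() names(.rl_models)

.check_model <- function(model) {
  if (!is.character(model) || length(model) != 1L || is.na(match(model, names(.rl_models))))
    stop("unknown model id: ", paste(model, collapse = ", "),
         "; see rl_model_ids()", call. = FALSE)
  .rl_models[[model]]
}

#' Parameter names and count of a model
#'
#' @param model Model identifier, see [rl_model_ids()].
#' @return `rl_param_names()`: character vector of the model's free parameter
#'   names; `rl_n_params()`: their number (the `k` entering the AIC penalty).
#' @export
rl_param_names <- function(model) .check_model(model)$pars

#' @rdname rl_param_names
#' @export
rl_n_params <- function(model) length(.check_model(model)$pars)

#' Default parameter bounds
#'
#' Box constraints used for fitting and for validating simulation parameters:
#' learning, decay and arbitration rates as well as weights and `rho` lie in
#' \[0, 1\]; the inverse temperature `beta1` in \[0, 100\]; the side bias
#' `beta0` in \[-5, 5\].
#'
#' @return A list with numeric vectors `lower` and `upper`, named by parameter.
#' @export
rl_bounds <- function() {
  lower <- c(alpha_pos = 0, alpha_neg = 0, zeta = 0, beta1 = 0, beta0 = -5,
             omega = 0, omega0 = 0, alpha_omega = 0, zeta_omega = 0, rho = 0)
  upper <- c(alpha_pos = 1, alpha_neg = 1, zeta = 1, beta1 = 100, beta0 = 5,
             omega = 1, omega0 = 1, alpha_omega = 1, zeta_omega = 1, rho = 1)
  list(lower = lower, upper = upper)
}

#' Construct and validate a model parameter set
#'
#' @param model Model identifier.
#' @param ... Named parameter values (e.g. `alpha_pos = 0.5`). All parameters
#'   of the model must be supplied unless `partial = TRUE`.
#' @param partial Allow a partial set (used for fixing parameters in fits).
#' @return Named numeric vector of class `rl_params`.
#' @examples
#' rl_params("stim_only", alpha_pos = .6, alpha_neg = .3, zeta = .2,
#'           beta1 = 10, beta0 = 0)
#' @export
rl_params <- function(model, ..., partial = FALSE) {
  info <- .check_model(model)
  vals <- unlist(list(...))
  if (length(vals) && is.null(names(vals))) stop("parameters must be named")
  extra <- setdiff(names(vals), info$pars)
  if (length(extra))
    stop("parameters not used by ", model, ": ", paste(extra, collapse = ", "))
  if (!partial) {
    missing <- setdiff(info$pars, names(vals))
    if (length(missing))
      stop("missing parameters for ", model, ": ", paste(missing, collapse = ", "))
  }
  b <- rl_bounds()
  bad <- names(vals)[vals < b$lower[names(vals)] | vals > b$upper[names(vals)]]
  if (length(bad)) stop("parameters out of bounds: ", paste(bad, collapse = ", "))
  structure(vals[intersect(info$pars, names(vals))], model = model,
            class = "rl_params")
}

# Expand a named parameter vector into the fixed 10-slot layout used in C++.
.pack_params <- function(params) {
  out <- numeric(length(.par_layout))
  names(out) <- .par_layout
  out[names(params)] <- unclass(params)
  out
}

#' Initialize the latent state of a model
#'
#' All four values (two stimulus values, two action values) start at
#' `v_init`; the arbitration weight starts at `omega0` for the dynamic models
#' or at the fixed `omega` for the static model, and is `NA` for
#' single-system models.
#'
#' @param model Model identifier.
#' @param params Named parameters (see [rl_params()]).
#' @param v_init Initial value of every stimulus/action value; the default 0.5
#'   (midpoint of the reward range) makes the initial reliability difference
#'   zero so arbitration starts unbiased.
#' @return A list with elements `v_stim` (named A/B), `v_action` (named L/R)
#'   and `omega`.
#' @export
init_state <- function(model, params, v_init = 0.5) {
  info <- .check_model(model)
  omega <- if (info$code == 3L) unname(params[["omega"]])
           else if (info$code >= 4L) unname(params[["omega0"]])
           else NA_real_
  list(v_stim = c(A = v_init, B = v_init),
       v_action = c(L = v_init, R = v_init),
       omega = omega)
}

#' Overall values of the left and right options
#'
#' Combines stimulus and action values into the overall value of the option
#' on each side. Single-system models pass through their own values; the
#' static and dynamic models weight the two systems by `omega` and
#' `1 - omega`; the `dynamic_omega_rho` model uses weights `rho * omega` and
#' `(1 - rho) * (1 - omega)`. The stimulus value mapped onto a side follows
#' the trial's stimulus placement.
#'
#' @param state Latent state as returned by [init_state()] / [update_values()].
#' @param stimA_side `"L"` or `"R"`: the side stimulus A appears on.
#' @inheritParams init_state
#' @return Named numeric vector `c(left = , right = )`.
#' @export
overall_values <- function(state, stimA_side, params, model) {
  info <- .check_model(model)
  ls <- if (stimA_side == "L") "A" else "B"
  rs <- if (stimA_side == "L") "B" else "A"
  vs <- state$v_stim
  va <- state$v_action
  switch(as.character(info$code),
    "1" = c(left = unname(vs[ls]), right = unname(vs[rs])),
    "2" = c(left = unname(va[["L"]]), right = unname(va[["R"]])),
    "5" = {
      w <- state$omega; rho <- unname(params[["rho"]])
      c(left = unname(vs[ls]) * rho * w + va[["L"]] * (1 - rho) * (1 - w),
        right = unname(vs[rs]) * rho * w + va[["R"]] * (1 - rho) * (1 - w))
    },
    { # static or dynamic omega
      w <- state$omega
      c(left = unname(vs[ls]) * w + va[["L"]] * (1 - w),
        right = unname(vs[rs]) * w + va[["R"]] * (1 - w))
    })
}

#' Softmax probability of choosing the right option
#'
#' `P(Right) = logistic(beta1 * (OV_right - OV_left) + beta0)`. Vectorized.
#'
#' @param ov_left,ov_right Overall values of the left/right options.
#' @param beta1 Inverse temperature (choice sensitivity), `>= 0`.
#' @param beta0 Side bias; positive values favor the right side.
#' @return Probability of a rightward choice.
#' @export
choice_prob <- function(ov_left, ov_right, beta1, beta0 = 0) {
  1 / (1 + exp(-(beta1 * (ov_right - ov_left) + beta0)))
}

#' Logit decomposition of the choice rule
#'
#' Decomposes the choice logit into the side bias and the per-system
#' contributions: `beta0 + w_stim * dV_stim + w_act * dV_action`, where the
#' system weights are `beta1 * omega` and `beta1 * (1 - omega)` for the
#' two-system models (`beta1 * rho * omega` and
#' `beta1 * (1 - rho) * (1 - omega)` for `dynamic_omega_rho`), and
#' `dV = V(right) - V(left)` within each system. The sum equals the direct
#' softmax logit of [choice_prob()] applied to [overall_values()].
#'
#' @inheritParams overall_values
#' @return List with `beta0`, `stim_term`, `action_term`, `logit`, `p_right`.
#' @export
logit_decomposition <- function(state, stimA_side, params, model) {
  info <- .check_model(model)
  ls <- if (stimA_side == "L") "A" else "B"
  rs <- if (stimA_side == "L") "B" else "A"
  dv_stim <- unname(state$v_stim[rs] - state$v_stim[ls])
  dv_act <- unname(state$v_action[["R"]] - state$v_action[["L"]])
  beta1 <- unname(params[["beta1"]])
  beta0 <- unname(params[["beta0"]])
  w <- switch(as.character(info$code),
    "1" = c(beta1, 0),
    "2" = c(0, beta1),
    "5" = {
      rho <- unname(params[["rho"]])
      c(beta1 * rho * state$omega, beta1 * (1 - rho) * (1 - state$omega))
    },
    c(beta1 * state$omega, beta1 * (1 - state$omega)))
  st <- w[1] * dv_stim
  at <- w[2] * dv_act
  list(beta0 = beta0, stim_term = st, action_term = at,
       logit = beta0 + st + at,
       p_right = 1 / (1 + exp(-(beta0 + st + at))))
}

#' Update stimulus and action values after feedback
#'
#' In each active system the chosen value moves toward the reward with
#' learning rate `alpha_pos` (rewarded) or `alpha_neg` (unrewarded), while
#' the unchosen value decays toward zero at rate `zeta`. Two-system models
#' update both systems in parallel from the same outcome.
#'
#' @param state Latent state.
#' @param choice_side `"L"` or `"R"`.
#' @param choice_stim `"A"` or `"B"`.
#' @param reward 0 or 1.
#' @inheritParams init_state
#' @return Updated state (the arbitration weight is untouched; see
#'   [update_omega()]).
#' @export
update_values <- function(state, choice_side, choice_stim, reward, params, model) {
  info <- .check_model(model)
  stopifnot(reward %in% c(0, 1))
  alpha <- unname(if (reward == 1) params[["alpha_pos"]] else params[["alpha_neg"]])
  zeta <- unname(params[["zeta"]])
  if (info$code != 2L) {
    un <- setdiff(c("A", "B"), choice_stim)
    state$v_stim[choice_stim] <- state$v_stim[choice_stim] +
      alpha * (reward - state$v_stim[choice_stim])
    state$v_stim[un] <- (1 - zeta) * state$v_stim[un]
  }
  if (info$code != 1L) {
    un <- setdiff(c("L", "R"), choice_side)
    state$v_action[choice_side] <- state$v_action[choice_side] +
      alpha * (reward - state$v_action[choice_side])
    state$v_action[un] <- (1 - zeta) * state$v_action[un]
  }
  state
}

#' Relative reliability of the stimulus-based over the action-based system
#'
#' Computed from a latent state; positive values indicate a more reliable
#' stimulus-based system. Variants:
#' \describe{
#'   \item{`v_cho`}{chosen stimulus value minus chosen action value. Equals
#'     `RPE_action - RPE_stim` computed from the same state (the signed-RPE
#'     identity), which holds for any reward.}
#'   \item{`abs_rpe`}{`|RPE_action| - |RPE_stim|`, with `RPE = reward - V(chosen)`.}
#'   \item{`abs_dv`}{`|V_A - V_B| - |V_L - V_R|`: value discernibility.}
#'   \item{`sum_v`}{`(V_A + V_B) - (V_L + V_R)`: summed signal strength. Note
#'     this variant ranges over \[-2, 2\] rather than \[-1, 1\].}
#' }
#'
#' In the trial loop the signal is evaluated on the trial's own values --
#' the (pre-update) state the choice was made with, indexed by the trial --
#' consistent with the prediction errors `RPE(t) = R(t) - V(t)` that drive
#' the update; this is what makes the `v_cho` / signed-RPE identity hold on
#' every simulated trial.
#'
#' @param state Latent state at the time the signal is evaluated.
#' @param choice_side,choice_stim The trial's choice.
#' @param reward 0 or 1 (used by `abs_rpe`).
#' @param kind One of `"v_cho"`, `"abs_rpe"`, `"abs_dv"`, `"sum_v"`.
#' @return The scalar relative reliability.
#' @export
relative_reliability <- function(state, choice_side, choice_stim, reward,
                                 kind = c("v_cho", "abs_rpe", "abs_dv", "sum_v")) {
  kind <- match.arg(kind)
  vs <- state$v_stim
  va <- state$v_action
  switch(kind,
    v_cho = unname(vs[choice_stim] - va[choice_side]),
    abs_rpe = abs(reward - va[[choice_side]]) - abs(reward - vs[[choice_stim]]),
    abs_dv = abs(vs[["A"]] - vs[["B"]]) - abs(va[["L"]] - va[["R"]]),
    sum_v = (vs[["A"]] + vs[["B"]]) - (va[["L"]] + va[["R"]]))
}

#' Update the arbitration weight from a reliability signal
#'
#' Positive `delta_rel` moves `omega` toward 1 (stimulus-based system) at
#' rate `alpha_omega * delta_rel`; negative values move it toward 0 at rate
#' `alpha_omega * |delta_rel|`; in addition a passive decay `zeta_omega`
#' always pulls `omega` back toward its initial value `omega0`. Two numerical
#' guards keep the weight in \[0, 1\] everywhere in the parameter box: the
#' effective step `alpha_omega * |delta_rel|` is capped at 1 (the cap only
#' binds for the `sum_v` signal, whose range exceeds \[-1, 1\]), and the
#' result is clipped to \[0, 1\] (the raw rule can overshoot only when
#' `alpha_omega + zeta_omega > 1`, an extreme corner; inside the usual
#' regime the clip is inactive and the update is exactly the drive-plus-decay
#' arithmetic).
#'
#' @param omega Current weight in \[0, 1\].
#' @param delta_rel Relative reliability (see [relative_reliability()]).
#' @param params Parameters providing `alpha_omega`, `zeta_omega`, `omega0`.
#' @return Updated weight.
#' @export
update_omega <- function(omega, delta_rel, params) {
  a <- unname(params[["alpha_omega"]])
  z <- unname(params[["zeta_omega"]])
  om0 <- unname(params[["omega0"]])
  decay <- z * (om0 - omega)
  out <- if (delta_rel > 0) omega + min(1, a * delta_rel) * (1 - omega) + decay
         else if (delta_rel < 0) omega + min(1, a * (-delta_rel)) * (0 - omega) + decay
         else omega + decay
  min(1, max(0, out))
}

#' Effective arbitration weight
#'
#' `Omega = rho * omega / (rho * omega + (1 - rho) * (1 - omega))`: the net
#' fraction of choice sensitivity owed to the stimulus-based system once the
#' baseline signal-strength ratio `rho` is taken into account. Reduces to
#' `omega` at `rho = 0.5` and to `rho` at `omega = 0.5`. At the degenerate
#' corners where the denominator vanishes the value is defined as `omega` by
#' continuity along `rho = 0.5`. Vectorized.
#'
#' @param omega Arbitration weight(s) in \[0, 1\].
#' @param rho Baseline signal-strength ratio in \[0, 1\].
#' @return Effective weight(s) in \[0, 1\].
#' @export
effective_omega <- function(omega, rho) {
  denom <- rho * omega + (1 - rho) * (1 - omega)
  ifelse(denom <= 0, omega, rho * omega / denom)
}

# --- session likelihood ----------------------------------------------------

.traj_cols <- c("ov_left", "ov_right", "p_right", "omega", "Omega", "drel",
                "rpe_stim", "rpe_action", "dv_cho")

# Encode a trials data.frame into the integer vectors the C++ engine takes.
.encode_trials <- function(data) {
  req <- c("block", "trial", "stimA_side", "choice_side", "reward")
  miss <- setdiff(req, names(data))
  if (length(miss)) stop("trials table lacks columns: ", paste(miss, collapse = ", "))
  sess <- if (all(c("subject", "session") %in% names(data)))
    as.integer(factor(paste(data$subject, data$session, sep = "\r")))
  else rep(1L, nrow(data))
  # run-length block labels within session
  blk <- as.integer(factor(paste(sess, data$block, sep = "\r")))
  list(session = sess, block = blk,
       stimA_left = as.integer(data$stimA_side == "L"),
       choose_right = as.integer(data$choice_side == "R"),
       reward = as.integer(data$reward))
}

#' Negative log-likelihood of observed choices under a model
#'
#' Sums `-log P(observed choice)` over every trial of a trials table, with
#' the latent state re-initialized at the start of each block (new stimuli
#' are introduced per block). Per-trial probabilities are clipped to
#' `[1e-10, 1 - 1e-10]` so the result is always finite. Likelihoods are in
#' natural log.
#'
#' @param model Model identifier.
#' @param params Named parameter vector for the model.
#' @param data Trials data.frame with columns `block`, `trial`, `stimA_side`,
#'   `choice_side`, `reward` (and optionally `subject`/`session`; state also
#'   resets at session boundaries).
#' @param v_init Initial value level (see [init_state()]).
#' @param carry_action Carry action values across block boundaries within a
#'   session (stimuli are novel each block, response sides are not; default
#'   resets both systems).
#' @param engine `"cpp"` (fast path) or `"r"` (reference loop built from the
#'   exported primitive operations; used for cross-checking).
#' @param want_traj Also return the per-trial latent trajectory.
#' @return If `want_traj = FALSE`, the scalar negative log-likelihood.
#'   Otherwise a list with `nll` and `traj`, a data.frame of per-trial
#'   latents (`ov_left`, `ov_right`, `p_right`, `omega`, `Omega`, `drel`,
#'   `rpe_stim`, `rpe_action`, `dv_cho`).
#' @export
session_negloglik <- function(model, params, data, v_init = 0.5,
                              carry_action = FALSE,
                              engine = c("cpp", "r"), want_traj = FALSE) {
  engine <- match.arg(engine)
  info <- .check_model(model)
  enc <- .encode_trials(data)
  if (engine == "cpp") {
    res <- cpp_session_loglik(info$code, .pack_params(params), info$rel,
                              enc$session, enc$block, enc$stimA_left,
                              enc$choose_right, enc$reward, v_init,
                              carry_action, want_traj)
    if (!want_traj) return(res$nll)
    traj <- as.data.frame(res$traj)
    names(traj) <- .traj_cols
    if (info$code < 3L) traj$omega <- traj$Omega <- NA_real_
    if (info$code == 3L) traj$drel <- NA_real_
    return(list(nll = res$nll, traj = traj))
  }
  .session_negloglik_r(model, params, data, enc, v_init, carry_action, want_traj)
}

# Reference implementation: plain R loop over the primitive operations.
.session_negloglik_r <- function(model, params, data, enc, v_init,
                                 carry_action, want_traj) {
  info <- .check_model(model)
  kind <- if (info$rel > 0L) names(.rel_kinds)[info$rel] else "v_cho"
  n <- nrow(data)
  nll <- 0
  st <- init_state(model, params, v_init)
  traj <- if (want_traj)
    as.data.frame(matrix(NA_real_, n, length(.traj_cols),
                         dimnames = list(NULL, .traj_cols)))
  for (t in seq_len(n)) {
    new_sess <- t == 1L || enc$session[t] != enc$session[t - 1L]
    if (new_sess || enc$block[t] != enc$block[t - 1L]) {
      va <- st$v_action
      st <- init_state(model, params, v_init)
      if (carry_action && !new_sess) st$v_action <- va
    }
    side_A <- if (enc$stimA_left[t] == 1L) "L" else "R"
    ov <- overall_values(st, side_A, params, model)
    p_right <- choice_prob(ov[["left"]], ov[["right"]],
                           params[["beta1"]], params[["beta0"]])
    p_obs <- if (enc$choose_right[t] == 1L) p_right else 1 - p_right
    nll <- nll - log(min(max(p_obs, 1e-10), 1 - 1e-10))
    ch_side <- if (enc$choose_right[t] == 1L) "R" else "L"
    ch_stim <- if (ch_side == side_A) "A" else "B"
    r <- enc$reward[t]
    om_used <- st$omega
    rpe_s <- r - st$v_stim[[ch_stim]]
    rpe_a <- r - st$v_action[[ch_side]]
    dv_cho <- st$v_stim[[ch_stim]] - st$v_action[[ch_side]]
    drel <- NA_real_
    if (info$code >= 4L)
      drel <- relative_reliability(st, ch_side, ch_stim, r, kind)
    st <- update_values(st, ch_side, ch_stim, r, params, model)
    if (info$code >= 4L) st$omega <- update_omega(st$omega, drel, params)
    if (want_traj) {
      Om <- if (info$code == 5L) effective_omega(om_used, params[["rho"]])
            else om_used
      traj[t, ] <- c(ov[["left"]], ov[["right"]], p_right, om_used, Om, drel,
                     rpe_s, rpe_a, dv_cho)
    }
  }
  if (want_traj) list(nll = nll, traj = traj) else nll
}
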