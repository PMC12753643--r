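# Shared fixtures, built in code.

control_params <- function(model = "dynamic_omega_rho", ...) {
  defaults <- list(alpha_pos = 0.5, alpha_neg = 0.5, zeta = 0.3, beta1 = 20,
                   beta0 = 0, omega = 0.6, omega0 = 0.374, alpha_omega = 0.2,
                   zeta_omega = 0.05, rho = 0.5)
  over <- list(...)
  defaults[names(over)] <- over
  do.call(rl_params, c(list(model), defaults[rl_param_names(model)]))
}

what_blocks <- function(n, n_trials = 80, p_better = 0.8, reversal = NULL) {
  replicate(n, make_block_spec("what_only", n_trials = n_trials,
                               p_better = p_better,
                               reversal_trial = reversal), simplify = FALSE)
}

# random latent state with values in [0, 1]
random_state <- function() {
  list(v_stim = c(A = runif(1), B = runif(1)),
       v_action = c(L = runif(1), R = runif(1)),
       omega = runif(1))
}

# quick simulated session for fitting tests
quick_session <- function(model, params, n_blocks = 10, task = "what_only",
                          seed = 1) {
  set.seed(seed)
  blocks <- replicate(n_blocks, make_block_spec(task), simplify = FALSE)
  simulate_session(model, params, blocks, seed = seed)
}
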