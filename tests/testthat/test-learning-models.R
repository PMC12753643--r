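# Per-trial dynamics and likelihoods of the model family.

test_that("state initialization follows the model", {
  p <- control_params("dynamic_omega_rho", omega0 = 0.3)
  st <- init_state("dynamic_omega_rho", p)
  expect_equal(st$omega, 0.3)
  expect_equal(unname(st$v_stim), c(0.5, 0.5))
  expect_equal(unname(st$v_action), c(0.5, 0.5))
  # symmetric initialization gives zero reliability difference on any choice
  for (k in c("v_cho", "abs_dv", "sum_v"))
    expect_equal(relative_reliability(st, "L", "A", 1, k), 0)
  st0 <- init_state("stim_only", control_params("stim_only"), v_init = 0)
  expect_equal(unname(st0$v_stim), c(0, 0))
  expect_true(is.na(st0$omega))
  expect_equal(init_state("static_omega",
                          control_params("static_omega", omega = 0.8))$omega, 0.8)
})

test_that("overall values combine the two systems by the arbitration weight", {
  p <- control_params("static_omega", omega = 0.75)
  st <- list(v_stim = c(A = 0.6, B = 0.2), v_action = c(L = 0.3, R = 0.5),
             omega = 0.75)
  ov <- overall_values(st, "L", p, "static_omega")
  expect_equal(unname(ov), c(0.6 * .75 + 0.3 * .25, 0.2 * .75 + 0.5 * .25))
  expect_equal(unname(ov), c(0.525, 0.275))
  # omega = 1: pure stimulus values regardless of action values
  st$omega <- 1
  ov1 <- overall_values(st, "L", p, "static_omega")
  expect_equal(unname(ov1), c(0.6, 0.2))
  # side mapping follows the stimulus placement
  ov_flip <- overall_values(st, "R", p, "static_omega")
  expect_equal(unname(ov_flip), c(0.2, 0.6))
})

test_that("rho = 0.5 halves the overall values but preserves choice", {
  set.seed(42)
  p_dyn <- control_params("dynamic_omega_vcho")
  p_rho <- control_params("dynamic_omega_rho", rho = 0.5)
  for (i in 1:50) {
    st <- random_state()
    side <- sample(c("L", "R"), 1)
    ov_dyn <- overall_values(st, side, p_dyn, "dynamic_omega_vcho")
    ov_rho <- overall_values(st, side, p_rho, "dynamic_omega_rho")
    expect_equal(unname(ov_rho), unname(ov_dyn) / 2, tolerance = 1e-12)
    expect_equal(choice_prob(ov_rho[1], ov_rho[2], 2 * p_dyn[["beta1"]], 0),
                 choice_prob(ov_dyn[1], ov_dyn[2], p_dyn[["beta1"]], 0),
                 tolerance = 1e-12)
  }
})

test_that("softmax choice rule and its logit decomposition agree", {
  expect_equal(choice_prob(0.5, 0.5, 10, 0), 0.5)
  expect_equal(choice_prob(0.4, 0.5, 20, 0), 1 / (1 + exp(-2)))
  expect_equal(choice_prob(0.4, 0.5, 20, 0), 0.8808, tolerance = 1e-4)
  set.seed(7)
  for (m in rl_model_ids()) {
    p <- control_params(m)
    for (i in 1:100) {
      st <- random_state()
      side <- sample(c("L", "R"), 1)
      dec <- logit_decomposition(st, side, p, m)
      ov <- overall_values(st, side, p, m)
      direct <- choice_prob(ov[["left"]], ov[["right"]], p[["beta1"]],
                            p[["beta0"]])
      expect_equal(dec$p_right, direct, tolerance = 1e-12)
      expect_equal(dec$beta0 + dec$stim_term + dec$action_term, dec$logit)
    }
  }
})

test_that("value updates use asymmetric learning rates and decay", {
  p <- control_params("stim_only", alpha_pos = 0.5, zeta = 0.3)
  st <- init_state("stim_only", p) # all values 0.5
  st2 <- update_values(st, "L", "A", 1, p, "stim_only")
  expect_equal(unname(st2$v_stim[["A"]]), 0.75) # 0.5 + 0.5*(1-0.5)
  st3 <- list(v_stim = c(A = 0.2, B = 0.8), v_action = c(L = 0.5, R = 0.5),
              omega = NA)
  st4 <- update_values(st3, "L", "A", 1, p, "stim_only")
  expect_equal(unname(st4$v_stim[["B"]]), 0.56) # 0.8 * (1 - 0.3)
  # zeta = 0 leaves the unchosen value untouched
  p0 <- control_params("stim_only", zeta = 0)
  st5 <- update_values(st3, "L", "A", 1, p0, "stim_only")
  expect_equal(unname(st5$v_stim[["B"]]), 0.8)
  # action system untouched by the stimulus-only model
  expect_equal(st4$v_action, st3$v_action)
  # two-system models update both systems in parallel
  p2 <- control_params("static_omega")
  st6 <- update_values(st3, "L", "A", 0, p2, "static_omega")
  expect_equal(unname(st6$v_action[["L"]]),
               0.5 + p2[["alpha_neg"]] * (0 - 0.5))
})

test_that("signed chosen-value difference equals the RPE difference", {
  st <- list(v_stim = c(A = 0.7, B = 0.1), v_action = c(L = 0.4, R = 0.9),
             omega = 0.5)
  expect_equal(relative_reliability(st, "L", "A", 1, "v_cho"), 0.3)
  # RPE identity on the same state: (1-0.4) - (1-0.7) = 0.3
  expect_equal(abs(1 - 0.4) - abs(1 - 0.7), 0.3)
  set.seed(11)
  for (i in 1:2000) {
    st <- random_state()
    r <- sample(0:1, 1)
    cs <- sample(c("A", "B"), 1)
    ca <- sample(c("L", "R"), 1)
    lhs <- relative_reliability(st, ca, cs, r, "v_cho")
    rpe_s <- r - st$v_stim[[cs]]
    rpe_a <- r - st$v_action[[ca]]
    expect_equal(lhs, rpe_a - rpe_s, tolerance = 1e-12)
    expect_true(lhs >= -1 && lhs <= 1)
  }
})

test_that("arbitration weight update matches the reliability-gated rule", {
  p <- control_params("dynamic_omega_vcho", alpha_omega = 0.2,
                      zeta_omega = 0.05, omega0 = 0.3)
  expect_equal(update_omega(0.5, 0.2, p), 0.5 + 0.2 * 0.2 * 0.5 + 0.05 * (0.3 - 0.5))
  expect_equal(update_omega(0.5, 0.2, p), 0.51)
  # fixed point: omega at omega0 with no reliability signal
  expect_equal(update_omega(0.3, 0, p), 0.3)
  # negative signal moves toward zero
  expect_lt(update_omega(0.5, -0.4, p), 0.5)
  # bounds preserved over random in-bounds updates, including sum_v-scale signals
  set.seed(13)
  for (i in 1:20000) {
    pr <- control_params("dynamic_omega_vcho", alpha_omega = runif(1),
                         zeta_omega = runif(1), omega0 = runif(1))
    om <- update_omega(runif(1), runif(1, -2, 2), pr)
    expect_true(om >= 0 && om <= 1)
  }
})

test_that("effective weight reduces correctly and is monotone", {
  expect_equal(effective_omega(0.37, 0.5), 0.37)
  expect_equal(effective_omega(0.5, 0.61), 0.61)
  expect_equal(effective_omega(1, 0.3), 1)
  expect_equal(effective_omega(0, 0.9), 0)
  # degenerate corners resolved by continuity
  expect_equal(effective_omega(1, 0), 1)
  expect_equal(effective_omega(0, 1), 0)
  om <- seq(0.05, 0.95, by = 0.05)
  expect_true(all(diff(effective_omega(om, 0.7)) > 0))
  expect_true(all(diff(effective_omega(0.3, om)) > 0))
})

test_that("chance-level parameters give the chance likelihood", {
  p <- control_params("stim_only", beta1 = 0, beta0 = 0)
  sim <- quick_session("stim_only", control_params("stim_only"), n_blocks = 3)
  nll <- session_negloglik("stim_only", p, sim$trials)
  expect_equal(nll, 3 * 80 * log(2), tolerance = 1e-10)
})

test_that("C++ and R likelihood engines agree for every model", {
  for (m in rl_model_ids()) {
    p <- control_params(m)
    sim <- quick_session(m, p, n_blocks = 3, task = "what_where",
                         seed = match(m, rl_model_ids()))
    a <- session_negloglik(m, p, sim$trials, want_traj = TRUE)
    b <- session_negloglik(m, p, sim$trials, engine = "r", want_traj = TRUE)
    expect_equal(a$nll, b$nll, tolerance = 1e-9)
    expect_equal(a$traj$p_right, b$traj$p_right, tolerance = 1e-9)
    expect_equal(a$traj$omega, b$traj$omega, tolerance = 1e-9)
    expect_equal(a$traj$drel, b$traj$drel, tolerance = 1e-9)
  }
})

test_that("model nesting yields identical choice probabilities", {
  sim <- quick_session("dynamic_omega_rho", control_params(), n_blocks = 13,
                       task = "what_where", seed = 5)
  trials <- sim$trials # 1040 observed trials to evaluate on
  traj_p <- function(m, p) session_negloglik(m, p, trials,
                                             want_traj = TRUE)$traj$p_right
  base <- list(alpha_pos = .6, alpha_neg = .35, zeta = .25, beta1 = 12,
               beta0 = .4)
  # static omega at the corners reproduces the single-system models
  p_stim <- do.call(rl_params, c(list("stim_only"), base))
  p_act <- do.call(rl_params, c(list("action_only"), base))
  p_w1 <- do.call(rl_params, c(list("static_omega"), base, list(omega = 1)))
  p_w0 <- do.call(rl_params, c(list("static_omega"), base, list(omega = 0)))
  expect_equal(traj_p("static_omega", p_w1), traj_p("stim_only", p_stim),
               tolerance = 1e-12)
  expect_equal(traj_p("static_omega", p_w0), traj_p("action_only", p_act),
               tolerance = 1e-12)
  # frozen arbitration reduces the dynamic model to the static one
  p_frozen <- do.call(rl_params, c(list("dynamic_omega_vcho"), base,
                                   list(omega0 = .42, alpha_omega = 0,
                                        zeta_omega = 0)))
  p_stat <- do.call(rl_params, c(list("static_omega"), base, list(omega = .42)))
  expect_equal(traj_p("dynamic_omega_vcho", p_frozen),
               traj_p("static_omega", p_stat), tolerance = 1e-12)
  # rho = 0.5 with doubled inverse temperature reproduces the dynamic model
  dyn <- c(base, list(omega0 = .42, alpha_omega = .2, zeta_omega = .05))
  p_dyn <- do.call(rl_params, c(list("dynamic_omega_vcho"), dyn))
  p_rho <- do.call(rl_params, c(list("dynamic_omega_rho"),
                                modifyList(dyn, list(beta1 = 24)),
                                list(rho = 0.5)))
  expect_equal(traj_p("dynamic_omega_rho", p_rho),
               traj_p("dynamic_omega_vcho", p_dyn), tolerance = 1e-12)
})

test_that("latent quantities stay in their ranges during simulation", {
  for (m in c("dynamic_omega_vcho", "dynamic_omega_sumv", "dynamic_omega_rho")) {
    sim <- quick_session(m, control_params(m), n_blocks = 25,
                         task = "what_where", seed = 99)
    tr <- sim$traj
    expect_true(all(tr$omega >= 0 & tr$omega <= 1))
    expect_true(all(tr$Omega >= 0 & tr$Omega <= 1))
    expect_true(all(tr$p_right > 0 & tr$p_right < 1))
    if (m != "dynamic_omega_sumv")
      expect_true(all(abs(tr$drel) <= 1))
  }
})

test_that("likelihood is deterministic and favors the generating parameters", {
  p <- control_params("dynamic_omega_rho", rho = 0.6)
  sim <- quick_session("dynamic_omega_rho", p, n_blocks = 25, seed = 123,
                       task = "what_where")
  n1 <- session_negloglik("dynamic_omega_rho", p, sim$trials)
  n2 <- session_negloglik("dynamic_omega_rho", p, sim$trials)
  expect_identical(n1, n2)
  # perturbed parameters fit worse on average (evaluated on one big sample)
  p_pert <- control_params("dynamic_omega_rho", rho = 0.6, alpha_pos = 0.9,
                           beta1 = 5)
  expect_lt(n1, session_negloglik("dynamic_omega_rho", p_pert, sim$trials))
})
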