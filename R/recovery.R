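# Simulation experiments: parameter recovery, model recovery, the
# ERDS-interaction simulation, and the lesion-mimicking parameter grid.

# Plausible generating ranges for parameter recovery: uniform over the part
# of the parameter box where this task family actually operates (very low
# inverse temperatures produce pure-noise sessions, extreme rates produce
# degenerate value traces).
.recovery_ranges <- function(model) {
  r <- list(alpha_pos = c(0.2, 0.8), alpha_neg = c(0.2, 0.8),
            zeta = c(0.05, 0.5), beta1 = c(5, 30), beta0 = c(-1, 1),
            omega = c(0.1, 0.9), omega0 = c(0.1, 0.7),
            alpha_omega = c(0.05, 0.4), zeta_omega = c(0.01, 0.15),
            rho = c(0.3, 0.7))
  r[rl_param_names(model)]
}

.sample_params <- function(model, ranges = .recovery_ranges(model)) {
  vals <- vapply(ranges, function(r) runif(1, r[1], r[2]), 0)
  do.call(rl_params, c(list(model), as.list(vals)))
}

.random_blocks <- function(n, task) {
  replicate(n, make_block_spec(task), simplify = FALSE)
}

#' Parameter recovery for a model
#'
#' Samples generating parameters per session, simulates each session on a
#' fresh random block environment, refits the generating model by maximum
#' likelihood, and reports per-parameter (true, recovered) pairs with their
#' correlation and mean bias.
#'
#' For the `dynamic_omega_rho` model the procedure mirrors the two-stage
#' subject-level treatment of the baseline ratio: sessions are grouped into
#' subjects, `rho` is a per-subject constant (drawn once per subject,
#' session-varying for all other parameters), stage 1 fits each subject's
#' sessions jointly to recover `rho`, and stage 2 refits every session with
#' `rho` fixed at the subject's stage-1 value. `rho` recovery pairs are then
#' per subject; all other pairs per session.
#'
#' @param model Model identifier.
#' @param n_sessions Number of simulated sessions.
#' @param blocks_per_session Blocks per session (default 20).
#' @param task Task variant of the simulated environments.
#' @param n_starts Optimizer starts per refit.
#' @param seed Integer seed (sub-seeds per session are derived from it).
#' @param ranges Optional named list of generating ranges, else plausible
#'   defaults.
#' @param sessions_per_subject Session grouping for the two-stage `rho`
#'   procedure (`dynamic_omega_rho` only).
#' @return Object of class `rl_recovery`: `pairs` (long data.frame of
#'   parameter, unit, true, recovered), `correlation` and `bias` (named per
#'   parameter).
#' @export
parameter_recovery <- function(model = "dynamic_omega_rho", n_sessions = 30L,
                               blocks_per_session = 20L, task = "what_where",
                               n_starts = 20L, seed = 1L, ranges = NULL,
                               sessions_per_subject = 5L) {
  if (is.null(ranges)) ranges <- .recovery_ranges(model)
  pars <- rl_param_names(model)
  two_stage <- model == "dynamic_omega_rho"
  sess_pars <- if (two_stage) setdiff(pars, "rho") else pars
  truth <- est <- matrix(NA_real_, n_sessions, length(sess_pars),
                         dimnames = list(NULL, sess_pars))
  if (two_stage) {
    n_subj <- ceiling(n_sessions / sessions_per_subject)
    subj_of <- rep(seq_len(n_subj), each = sessions_per_subject)[seq_len(n_sessions)]
    rho_true <- rho_est <- numeric(n_subj)
  } else {
    subj_of <- seq_len(n_sessions)
  }
  sims <- vector("list", n_sessions)
  for (i in seq_len(n_sessions)) {
    set.seed(.subseed(seed, i))
    p_true <- .sample_params(model, ranges)
    if (two_stage) {
      # rho is a subject-level constant: redraw it once per subject
      set.seed(.subseed(seed, 0L, subj_of[i]))
      rho_true[subj_of[i]] <- runif(1, ranges$rho[1], ranges$rho[2])
      set.seed(.subseed(seed, i, 1L))
      p_true[["rho"]] <- rho_true[subj_of[i]]
    }
    blocks <- .random_blocks(blocks_per_session, task)
    sims[[i]] <- simulate_session(model, p_true, blocks,
                                  subject_id = sprintf("s%02d", subj_of[i]),
                                  session_id = i)$trials
    truth[i, ] <- unclass(p_true)[sess_pars]
  }
  if (two_stage) {
    for (s in seq_len(n_subj)) {
      idx <- which(subj_of == s)
      set.seed(.subseed(seed, 0L, s, 1L))
      joint <- fit_rl(do.call(rbind, sims[idx]), model, n_starts = n_starts)
      rho_est[s] <- unname(coef(joint)[["rho"]])
      for (i in idx) {
        set.seed(.subseed(seed, i, 2L))
        fit <- fit_rl(sims[[i]], model, n_starts = n_starts,
                      fixed = c(rho = rho_est[s]))
        est[i, ] <- coef(fit)[sess_pars]
      }
    }
  } else {
    for (i in seq_len(n_sessions)) {
      set.seed(.subseed(seed, i, 2L))
      est[i, ] <- coef(fit_rl(sims[[i]], model, n_starts = n_starts))[sess_pars]
    }
  }
  pairs <- do.call(rbind, lapply(sess_pars, function(p)
    data.frame(parameter = p, unit = sprintf("session%02d", seq_len(n_sessions)),
               true = truth[, p], recovered = est[, p],
               stringsAsFactors = FALSE)))
  correlation <- vapply(sess_pars, function(p) cor(truth[, p], est[, p]), 0)
  bias <- vapply(sess_pars, function(p) mean(est[, p] - truth[, p]), 0)
  if (two_stage) {
    pairs <- rbind(pairs, data.frame(
      parameter = "rho", unit = sprintf("subject%02d", seq_len(n_subj)),
      true = rho_true, recovered = rho_est, stringsAsFactors = FALSE))
    correlation <- c(correlation, rho = cor(rho_true, rho_est))
    bias <- c(bias, rho = mean(rho_est - rho_true))
  }
  structure(list(model = model, pairs = pairs, correlation = correlation,
                 bias = bias, n_sessions = n_sessions), class = "rl_recovery")
}

#' @export
print.rl_recovery <- function(x, ...) {
  cat(sprintf("Parameter recovery for '%s' over %d sessions\n",
              x$model, x$n_sessions))
  print(round(rbind(correlation = x$correlation, bias = x$bias), 3))
  invisible(x)
}

#' Subject-level recovery of the baseline ratio rho
#'
#' Simulates one subject (a single `dynamic_omega_rho` parameter set, hence
#' one `rho`) across several sessions, then recovers `rho` with the
#' two-stage procedure of [fit_rho_subject()].
#'
#' @param true_params Generating parameters (defaults to a control-like set
#'   with `rho = 0.4`).
#' @param n_sessions,blocks_per_session Subject shape.
#' @param task Task variant.
#' @param n_starts Optimizer starts.
#' @param seed Integer seed.
#' @return List with `rho_true`, `rho_hat`, `abs_error` and the stage
#'   results.
#' @export
recover_rho_subject <- function(true_params = NULL, n_sessions = 10L,
                                blocks_per_session = 20L,
                                task = "what_where", n_starts = 20L,
                                seed = 1L) {
  if (is.null(true_params))
    true_params <- rl_params("dynamic_omega_rho",
                             alpha_pos = 0.5, alpha_neg = 0.5, zeta = 0.3,
                             beta1 = 20, beta0 = 0, omega0 = 0.374,
                             alpha_omega = 0.2, zeta_omega = 0.05, rho = 0.4)
  sessions <- lapply(seq_len(n_sessions), function(j) {
    set.seed(.subseed(seed, 1L, j))
    blocks <- .random_blocks(blocks_per_session, task)
    simulate_session("dynamic_omega_rho", true_params, blocks,
                     session_id = j)$trials
  })
  data <- do.call(rbind, sessions)
  res <- fit_rho_subject(data, n_starts = n_starts, seed = .subseed(seed, 2L))
  list(rho_true = unname(true_params[["rho"]]), rho_hat = res$rho,
       abs_error = abs(res$rho - unname(true_params[["rho"]])),
       stage1 = res$stage1, session_fits = res$session_fits)
}

#' Model recovery by AIC
#'
#' Simulates sessions from each candidate model with parameters drawn
#' uniformly from the documented bounds (inverse temperature from a
#' plausible 1..40 range), fits every candidate to every simulated session,
#' selects per session by AIC (ties toward fewer parameters), and
#' aggregates the generating-model x selected-model confusion matrix of
#' proportions (rows sum to 1). Generating models are allocated to sessions
#' in (shuffled) equal proportions.
#'
#' @param models Candidate model identifiers (at least two).
#' @param n_reps Total number of simulated sessions.
#' @param blocks_per_session Blocks per session (default 30).
#' @param task Task variant.
#' @param n_starts Optimizer starts per fit.
#' @param seed Integer seed.
#' @return Object of class `rl_model_recovery`: `confusion` (matrix of row
#'   proportions), `counts`, `selected` (per-rep record).
#' @export
model_recovery <- function(models = c("stim_only", "action_only", "static_omega"),
                           n_reps = 200L, blocks_per_session = 30L,
                           task = "what_where", n_starts = 5L, seed = 1L) {
  if (length(models) < 2L) stop("need at least two models")
  for (m in models) .check_model(m)
  b <- rl_bounds()
  gen_ranges <- function(model) {
    r <- lapply(rl_param_names(model), function(p) c(b$lower[[p]], b$upper[[p]]))
    names(r) <- rl_param_names(model)
    r$beta1 <- c(1, 40)
    r
  }
  set.seed(.subseed(seed, 0L))
  gen <- sample(rep_len(models, n_reps))
  sel <- character(n_reps)
  for (i in seq_len(n_reps)) {
    set.seed(.subseed(seed, i))
    p_true <- .sample_params(gen[i], gen_ranges(gen[i]))
    blocks <- .random_blocks(blocks_per_session, task)
    sim <- simulate_session(gen[i], p_true, blocks, session_id = i)
    fits <- lapply(models, function(m)
      fit_rl(sim$trials, m, n_starts = n_starts))
    tab <- model_selection_table(fits)
    sel[i] <- tab$model[tab$best]
  }
  counts <- table(factor(gen, levels = models), factor(sel, levels = models))
  confusion <- sweep(unclass(counts), 1, pmax(rowSums(counts), 1L), "/")
  structure(list(models = models, confusion = confusion, counts = counts,
                 selected = data.frame(generating = gen, selected = sel,
                                       stringsAsFactors = FALSE)),
            class = "rl_model_recovery")
}

#' @export
print.rl_model_recovery <- function(x, ...) {
  cat("Model recovery confusion matrix (rows: generating; cols: AIC-selected)\n")
  print(round(x$confusion, 3))
  invisible(x)
}

#' Simulated interaction between stimulus- and action-dimension ERDS
#'
#' For each generating model, simulates a cohort of subjects playing
#' What-only blocks, computes per-block ERDS on both dimensions, and
#' regresses `ERDS_action` on the subject-mean-centered `ERDS_stim` with
#' per-subject intercepts. A negative slope reproduces the competitive
#' interaction between the two learning systems; single-system generators
#' are expected to yield a weaker (less negative) slope than two-system
#' generators. Environments and seeds are matched across generators.
#'
#' @param models Generating model identifiers.
#' @param n_subjects,blocks_per_subject Cohort shape per generator.
#' @param seed Integer seed.
#' @param base,jitter_sd Optional named overrides of the subject-level
#'   parameter distribution (means and spreads).
#' @return Object of class `rl_erds_interaction`: `slopes` (named per
#'   model), `tables` (per-model block-level ERDS data).
#' @export
erds_interaction_sim <- function(models = c("stim_only", "static_omega",
                                            "dynamic_omega_rho"),
                                 n_subjects = 8L, blocks_per_subject = 60L,
                                 seed = 1L, base = NULL, jitter_sd = NULL) {
  base_d <- c(alpha_pos = 0.5, alpha_neg = 0.5, zeta = 0.3, beta1 = 10,
              beta0 = 0, omega = 0.6, omega0 = 0.374, alpha_omega = 0.2,
              zeta_omega = 0.05, rho = 0.5)
  jitter_d <- c(alpha_pos = 0.1, alpha_neg = 0.1, zeta = 0.05, beta1 = 2,
                beta0 = 0.1, omega = 0.15, omega0 = 0.1, alpha_omega = 0.05,
                zeta_omega = 0.01, rho = 0.05)
  if (!is.null(base)) base_d[names(base)] <- base
  if (!is.null(jitter_sd)) jitter_d[names(jitter_sd)] <- jitter_sd
  base <- base_d
  jitter_sd <- jitter_d
  b <- rl_bounds()
  slopes <- setNames(numeric(length(models)), models)
  tables <- setNames(vector("list", length(models)), models)
  for (m in models) {
    pars <- rl_param_names(m)
    rows <- list()
    for (s in seq_len(n_subjects)) {
      set.seed(.subseed(seed, s)) # same subject draws for every generator
      vals <- vapply(pars, function(p)
        .rtrunc(1, base[[p]], jitter_sd[[p]], b$lower[[p]], b$upper[[p]]), 0)
      params <- do.call(rl_params, c(list(m), as.list(vals)))
      blocks <- .random_blocks(blocks_per_subject, "what_only")
      sim <- simulate_session(m, params, blocks, subject_id = paste0("s", s))
      tab <- erds_by_block(sim$trials)
      rows[[s]] <- tab
    }
    tab <- do.call(rbind, rows)
    tab$erds_stim_c <- tab$erds_stim -
      ave(tab$erds_stim, tab$subject, FUN = mean)
    fit <- lm(erds_action ~ erds_stim_c + factor(subject), data = tab)
    slopes[m] <- coef(fit)[["erds_stim_c"]]
    tables[[m]] <- tab
  }
  structure(list(slopes = slopes, tables = tables),
            class = "rl_erds_interaction")
}

#' @export
print.rl_erds_interaction <- function(x, ...) {
  cat("ERDS_action ~ centered ERDS_stim slope by generating model:\n")
  print(round(x$slopes, 4))
  invisible(x)
}

#' Lesion-mimicking simulation grid
#'
#' Simulates the `dynamic_omega_rho` model over a grid of initial
#' arbitration weights `omega0`, baseline ratios `rho`, and inverse
#' temperatures `beta1`, holding the remaining parameters at the reference
#' values `alpha_pos = alpha_neg = 0.5`, `beta0 = 0`, `zeta = 0.3`,
#' `alpha_omega = 0.2`, `zeta_omega = 0.05` (overridable via `fixed`). Each
#' cell simulates `n_blocks` What blocks with a fixed reversal trial and
#' reports the mean `omega` and `Omega` trajectories, the mean post-reversal
#' arbitration-rate difference `delta_psi`, and the mean probability of
#' choosing the currently better option, `P(Better)`. Low `omega0` mimics
#' amygdala lesions; low `rho` mimics ventral-striatum lesions. With
#' `n_trials = 200`, `reversal = 100` the grid reproduces the long
#' stimulus-learning variant used to map arbitration regimes.
#'
#' @param omega0,rho,beta1 Grid axes (crossed).
#' @param alpha_pos,alpha_neg,zeta,alpha_omega,zeta_omega Fixed parameters.
#' @param n_blocks Simulated blocks per cell (2000 is a desk-scale default;
#'   10000 reproduces the full protocol).
#' @param n_trials,reversal,p_better Block environment of every cell.
#' @param seed Integer seed; cells use derived sub-seeds so the grid is
#'   reproducible and parallelizable by cell.
#' @return Object of class `rl_grid`: `cells` (data.frame with one row per
#'   cell: axes, `delta_psi`, `psi_plus`, `psi_minus`, `p_better_mean`,
#'   late-acquisition and post-reversal performance) and `trajectories`
#'   (list of per-cell mean `omega`/`Omega` trajectories).
#' @export
lesion_grid_sim <- function(omega0 = c(0.179, 0.276, 0.374), rho = 0.5,
                            beta1 = 20, alpha_pos = 0.5, alpha_neg = 0.5,
                            zeta = 0.3, alpha_omega = 0.2, zeta_omega = 0.05,
                            n_blocks = 2000L, n_trials = 80L, reversal = 40L,
                            p_better = 0.8, seed = 1L) {
  grid <- expand.grid(omega0 = omega0, rho = rho, beta1 = beta1,
                      KEEP.OUT.ATTRS = FALSE)
  cells <- vector("list", nrow(grid))
  trajectories <- vector("list", nrow(grid))
  for (g in seq_len(nrow(grid))) {
    params <- rl_params("dynamic_omega_rho",
                        alpha_pos = alpha_pos, alpha_neg = alpha_neg,
                        zeta = zeta, beta1 = grid$beta1[g], beta0 = 0,
                        omega0 = grid$omega0[g], alpha_omega = alpha_omega,
                        zeta_omega = zeta_omega, rho = grid$rho[g])
    # cell sub-seed derived from the cell's coordinates, not its position,
    # so single cells can be re-run (or parallelized) reproducibly
    set.seed(.subseed(seed, round(grid$omega0[g] * 1000),
                      round(grid$rho[g] * 1000), round(grid$beta1[g] * 10)))
    om_sum <- Om_sum <- numeric(n_trials)
    dpsi <- pplus <- pminus <- numeric(n_blocks)
    pb_sum <- numeric(n_trials)
    info <- .check_model("dynamic_omega_rho")
    packed <- .pack_params(params)
    for (bl in seq_len(n_blocks)) {
      better_first <- sample(0:1, 1L)
      stimA_left <- .draw_sides(n_trials)
      res <- cpp_sim_block(info$code, packed, info$rel, n_trials, reversal,
                           p_better, 1L, better_first, stimA_left, 0.5,
                           numeric(0), TRUE)
      om_sum <- om_sum + res$traj[, 4]
      Om_sum <- Om_sum + res$traj[, 5]
      dp <- delta_psi_post_reversal(res$traj[, 5], reversal)
      dpsi[bl] <- dp$delta_psi
      pplus[bl] <- dp$psi_plus
      pminus[bl] <- dp$psi_minus
      better_now <- ifelse(seq_len(n_trials) >= reversal,
                           1L - better_first, better_first)
      pb_sum <- pb_sum + (res$choice_stim == better_now)
    }
    pb_traj <- pb_sum / n_blocks
    late_acq <- mean(pb_traj[max(1L, reversal - 10L):(reversal - 1L)])
    post_rev <- mean(pb_traj[min(n_trials, reversal + 10L):n_trials])
    cells[[g]] <- data.frame(omega0 = grid$omega0[g], rho = grid$rho[g],
                             beta1 = grid$beta1[g], n_blocks = n_blocks,
                             delta_psi = mean(dpsi), psi_plus = mean(pplus),
                             psi_minus = mean(pminus),
                             p_better_mean = mean(pb_traj),
                             p_better_late_acq = late_acq,
                             p_better_post_rev = post_rev)
    trajectories[[g]] <- list(omega = om_sum / n_blocks,
                              Omega = Om_sum / n_blocks,
                              p_better = pb_traj)
  }
  structure(list(cells = do.call(rbind, cells), trajectories = trajectories,
                 reversal = reversal, n_trials = n_trials),
            class = "rl_grid")
}

#' @export
print.rl_grid <- function(x, ...) {
  cat(sprintf("Simulation grid (%d cells, %d trials/block, reversal at %d)\n",
              nrow(x$cells), x$n_trials, x$reversal))
  print(round(x$cells, 4))
  invisible(x)
}
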