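# Synthetic task environments and generative agents.

.schedules <- c(0.8, 0.7, 0.6)

#' Draw a block environment
#'
#' Builds one block of the probabilistic reversal task: the reward schedule
#' is drawn uniformly from 80/20, 70/30, 60/40; the reversal trial uniformly
#' from the integers 30..50 (inclusive); for the What/Where task the block
#' type is What or Where with equal probability (the What-only task has only
#' What blocks); and the initially better target (stimulus A/B for What
#' blocks, side L/R for Where blocks) is drawn uniformly. Contingencies flip
#' for trials at and after the reversal trial.
#'
#' @param task `"what_only"` or `"what_where"`.
#' @param n_trials Trials per block (default 80).
#' @param p_better,reversal_trial,block_type,better_id Optional overrides of
#'   the random draws (e.g. `p_better = 1` for a deterministic test block).
#' @return A list of class `block_spec` with fields `task`, `block_type`,
#'   `p_better`, `reversal_trial`, `n_trials`, `better_id`.
#' @export
make_block_spec <- function(task = c("what_only", "what_where"), n_trials = 80,
                            p_better = NULL, reversal_trial = NULL,
                            block_type = NULL, better_id = NULL) {
  task <- match.arg(task)
  if (is.null(block_type))
    block_type <- if (task == "what_only") "what" else sample(c("what", "where"), 1L)
  if (task == "what_only" && block_type != "what")
    stop("what_only task has only what blocks")
  if (is.null(p_better)) p_better <- sample(.schedules, 1L)
  if (is.null(reversal_trial)) reversal_trial <- sample(30:50, 1L)
  if (is.null(better_id))
    better_id <- if (block_type == "what") sample(c("A", "B"), 1L)
                 else sample(c("L", "R"), 1L)
  ok_ids <- if (block_type == "what") c("A", "B") else c("L", "R")
  if (!better_id %in% ok_ids)
    stop("better_id must be one of ", paste(ok_ids, collapse = "/"),
         " for a ", block_type, " block")
  structure(list(task = task, block_type = block_type, p_better = p_better,
                 reversal_trial = as.integer(reversal_trial),
                 n_trials = as.integer(n_trials), better_id = better_id),
            class = "block_spec")
}

#' @export
print.block_spec <- function(x, ...) {
  cat(sprintf("<block_spec> %s %s block, %d trials, %d/%d schedule, reversal at %d, better = %s\n",
              x$task, x$block_type, x$n_trials, round(100 * x$p_better),
              round(100 * (1 - x$p_better)), x$reversal_trial, x$better_id))
  invisible(x)
}

#' Draw a reward outcome for one trial
#'
#' Identifies the currently better target -- `better_id` before the reversal
#' trial, the other target at and after it -- and returns 1 with probability
#' `p_better` if the choice matches it on the block's relevant dimension
#' (chosen stimulus for What blocks, chosen side for Where blocks), else
#' with probability `1 - p_better`.
#'
#' @param spec A [make_block_spec()] environment.
#' @param trial 1-based trial index.
#' @param choice_side `"L"` or `"R"`.
#' @param choice_stim `"A"` or `"B"`.
#' @return 0 or 1.
#' @export
sample_reward <- function(spec, trial, choice_side, choice_stim) {
  if (trial < 1 || trial > spec$n_trials)
    stop("trial ", trial, " outside 1..", spec$n_trials)
  flip <- trial >= spec$reversal_trial
  if (spec$block_type == "what") {
    better <- if (flip) setdiff(c("A", "B"), spec$better_id) else spec$better_id
    match <- choice_stim == better
  } else {
    better <- if (flip) setdiff(c("L", "R"), spec$better_id) else spec$better_id
    match <- choice_side == better
  }
  p <- if (match) spec$p_better else 1 - spec$p_better
  as.integer(runif(1) < p)
}

# Side assignment for stimulus A over a block: i.i.d. fair coin by default,
# or an exactly balanced shuffle.
.draw_sides <- function(n, balance = FALSE) {
  if (balance) {
    half <- n %/% 2
    sample(c(rep(1L, half), rep(0L, n - half)))
  } else as.integer(runif(n) < 0.5)
}

.block_records <- function(res, spec, stimA_left = NULL) {
  n <- spec$n_trials
  sides <- c("L", "R")
  data.frame(trial = seq_len(n),
             task = spec$task, block_type = spec$block_type,
             p_better = spec$p_better, reversal_trial = spec$reversal_trial,
             stimA_side = sides[2L - stimA_left],
             choice_side = sides[res$choose_right + 1L],
             choice_stim = c("A", "B")[res$choice_stim + 1L],
             reward = res$reward,
             better_id = spec$better_id,
             stringsAsFactors = FALSE)
}

#' Simulate an agent playing a session of blocks
#'
#' Runs the generative loop of any model in the family over a list of block
#' environments: per trial, stimulus sides are assigned, the choice is drawn
#' from the model's softmax probability, the reward from the block's
#' schedule, and the latent state updated. The state is re-initialized at
#' each block start. The simulation is a pure function of
#' `(model, params, blocks, seed)`.
#'
#' @param model Model identifier.
#' @param params Named parameters.
#' @param blocks A list of [make_block_spec()] environments.
#' @param seed Optional integer seed (set before any drawing).
#' @param subject_id,session_id Identifiers stamped on the output rows.
#' @param v_init Initial value level.
#' @param carry_action Carry action values across blocks within the session.
#' @param balance_sides Exactly counterbalance stimulus sides within each
#'   block instead of the default i.i.d. fair assignment.
#' @return A list with `trials` (data.frame in the trial-table schema plus a
#'   `better_id` column) and `traj` (data.frame of per-trial latents with
#'   matching `block`/`trial` keys).
#' @export
simulate_session <- function(model, params, blocks, seed = NULL,
                             subject_id = "s1", session_id = 1L,
                             v_init = 0.5, carry_action = FALSE,
                             balance_sides = FALSE) {
  if (!is.null(seed)) set.seed(seed)
  if (inherits(blocks, "block_spec")) blocks <- list(blocks)
  va <- NULL
  recs <- traj <- vector("list", length(blocks))
  for (b in seq_along(blocks)) {
    spec <- blocks[[b]]
    stimA_left <- .draw_sides(spec$n_trials, balance_sides)
    info <- .check_model(model)
    better_first <- if (spec$block_type == "what") {
      if (spec$better_id == "A") 0L else 1L
    } else if (spec$better_id == "L") 0L else 1L
    res <- cpp_sim_block(info$code, .pack_params(params), info$rel,
                         spec$n_trials, spec$reversal_trial, spec$p_better,
                         as.integer(spec$block_type == "what"), better_first,
                         stimA_left, v_init,
                         if (carry_action && !is.null(va)) va else numeric(0),
                         TRUE)
    va <- res$va_final
    rec <- .block_records(res, spec, stimA_left)
    rec <- cbind(subject = subject_id, session = session_id, block = b,
                 rec, stringsAsFactors = FALSE)
    recs[[b]] <- rec
    tr <- as.data.frame(res$traj)
    names(tr) <- .traj_cols
    if (info$code < 3L) tr$omega <- tr$Omega <- NA_real_
    if (info$code == 3L) tr$drel <- NA_real_
    traj[[b]] <- cbind(subject = subject_id, session = session_id, block = b,
                       trial = seq_len(spec$n_trials), tr,
                       stringsAsFactors = FALSE)
  }
  list(trials = do.call(rbind, recs), traj = do.call(rbind, traj))
}

#' Whether each trial's choice hit the currently better option
#'
#' @param trials A simulated trials table carrying `better_id`.
#' @return Logical vector, `TRUE` where the choice matched the currently
#'   better target (contingencies flipped at and after `reversal_trial`).
#' @export
chose_better <- function(trials) {
  if (is.null(trials$better_id)) stop("trials table lacks better_id")
  flip <- trials$trial >= trials$reversal_trial
  is_what <- trials$block_type == "what"
  other <- function(id, pair) ifelse(id == pair[1], pair[2], pair[1])
  better_stim <- ifelse(flip, other(trials$better_id, c("A", "B")), trials$better_id)
  better_side <- ifelse(flip, other(trials$better_id, c("L", "R")), trials$better_id)
  ifelse(is_what, trials$choice_stim == better_stim,
         trials$choice_side == better_side)
}

# Deterministic sub-seed for (seed, subject, session); keeps cohorts
# reproducible piecewise. Stays below 2^31 - 1.
.subseed <- function(seed, i, j = 0L, k = 0L) {
  as.integer((seed * 1000003 + i * 10007 + j * 101 + k) %% 2147483647)
}

#' Group-level parameter distributions for synthetic cohorts
#'
#' Default `dynamic_omega_rho` parameter distributions emulating the three
#' experimental groups: controls, amygdala-lesioned (reduced initial
#' arbitration weight `omega0`) and ventral-striatum-lesioned (reduced
#' baseline ratio `rho`). Group means for `omega0` follow the fitted group
#' means (control 0.374, amygdala 0.179, VS 0.276); `rho` is 0.6 for
#' controls (fitted control values sit above 0.5, e.g. 0.61 in the worked
#' example block) and for the amygdala group (whose `rho` is not reduced --
#' its deficit is the low `omega0`), and 0.4 for the VS group; remaining
#' means sit at the reference values used throughout the simulation
#' experiments.
#'
#' @param group `"control"`, `"amygdala"` or `"vs"`.
#' @return List with numeric vectors `mean` and `sd` over the model
#'   parameters.
#' @export
lesion_group_params <- function(group = c("control", "amygdala", "vs")) {
  group <- match.arg(group)
  mean <- c(alpha_pos = 0.5, alpha_neg = 0.5, zeta = 0.3, beta1 = 20,
            beta0 = 0, omega0 = 0.374, alpha_omega = 0.2, zeta_omega = 0.05,
            rho = 0.6)
  sd <- c(alpha_pos = 0.08, alpha_neg = 0.08, zeta = 0.05, beta1 = 4,
          beta0 = 0.2, omega0 = 0.12, alpha_omega = 0.05, zeta_omega = 0.015,
          rho = 0.08)
  if (group == "amygdala") mean[["omega0"]] <- 0.179
  if (group == "vs") { mean[["omega0"]] <- 0.276; mean[["rho"]] <- 0.4 }
  list(mean = mean, sd = sd)
}

#' Specify a synthetic cohort
#'
#' @param group Experimental group; sets the default parameter distributions
#'   via [lesion_group_params()].
#' @param n_subjects,n_sessions,blocks_per_session Cohort shape. The default
#'   20 blocks per session matches the task's typical session length.
#' @param task Task variant for every session.
#' @param model Generating model.
#' @param mean,sd Optional overrides of the group parameter distributions
#'   (named, truncated-normal over the parameter bounds).
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(group = c("control", "amygdala", "vs"),
                        n_subjects = 4L, n_sessions = 10L,
                        blocks_per_session = 20L,
                        task = c("what_where", "what_only"),
                        model = "dynamic_omega_rho",
                        mean = NULL, sd = NULL) {
  group <- match.arg(group)
  task <- match.arg(task)
  .check_model(model)
  d <- lesion_group_params(group)
  if (!is.null(mean)) d$mean[names(mean)] <- mean
  if (!is.null(sd)) d$sd[names(sd)] <- sd
  pars <- rl_param_names(model)
  structure(list(group = group, n_subjects = as.integer(n_subjects),
                 n_sessions = as.integer(n_sessions),
                 blocks_per_session = as.integer(blocks_per_session),
                 task = task, model = model,
                 mean = d$mean[pars], sd = d$sd[pars]),
            class = "cohort_spec")
}

# Truncated-normal draw by rejection within the parameter bounds.
.rtrunc <- function(n, mean, sd, lo, hi) {
  if (mean < lo || mean > hi) stop("distribution mean outside bounds")
  out <- numeric(n)
  need <- seq_len(n)
  for (it in 1:1000) {
    out[need] <- rnorm(length(need), mean, sd)
    need <- which(out < lo | out > hi)
    if (!length(need)) return(out)
  }
  stop("infeasible parameter distribution (mass outside bounds)")
}

#' Generate a synthetic cohort with known ground truth
#'
#' Samples one parameter set per subject from the group distributions (the
#' baseline ratio `rho` is a per-subject constant across sessions), then
#' simulates every session of every subject. Sub-seeds per
#' (subject, session) are derived deterministically from `seed`, so the
#' cohort is reproducible piecewise.
#'
#' @param spec A [cohort_spec()].
#' @param seed Integer seed.
#' @return List with `trials` (all sessions bound together), `truth`
#'   (data.frame of per-subject generating parameters, one `rho` per
#'   subject) and `spec`.
#' @export
generate_cohort <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "cohort_spec"))
  b <- rl_bounds()
  pars <- names(spec$mean)
  if (spec$n_subjects == 0L)
    return(list(trials = NULL, truth = NULL, spec = spec))
  set.seed(.subseed(seed, 0L))
  truth <- sapply(pars, function(p)
    .rtrunc(spec$n_subjects, spec$mean[[p]], spec$sd[[p]], b$lower[[p]], b$upper[[p]]))
  truth <- as.data.frame(matrix(truth, nrow = spec$n_subjects,
                                dimnames = list(NULL, pars)))
  subj_ids <- sprintf("%s%02d", substr(spec$group, 1, 2), seq_len(spec$n_subjects))
  truth <- cbind(subject = subj_ids, group = spec$group, truth,
                 stringsAsFactors = FALSE)
  all_trials <- vector("list", spec$n_subjects * spec$n_sessions)
  idx <- 0L
  for (i in seq_len(spec$n_subjects)) {
    params <- do.call(rl_params, c(list(spec$model), as.list(truth[i, pars])))
    for (j in seq_len(spec$n_sessions)) {
      set.seed(.subseed(seed, i, j))
      blocks <- replicate(spec$blocks_per_session,
                          make_block_spec(spec$task), simplify = FALSE)
      sim <- simulate_session(spec$model, params, blocks,
                              subject_id = subj_ids[i], session_id = j)
      idx <- idx + 1L
      all_trials[[idx]] <- sim$trials
    }
  }
  list(trials = do.call(rbind, all_trials), truth = truth, spec = spec)
}

# --- trial-table I/O -------------------------------------------------------

.schema_cols <- c("subject", "session", "block", "trial", "task", "block_type",
                  "p_better", "reversal_trial", "stimA_side", "choice_side",
                  "choice_stim", "reward")

#' Validate a trial table against the interchange schema
#'
#' Checks required columns, enum codes, reward in \{0, 1\}, the reversal
#' range, and the consistency of `choice_stim` with
#' `(choice_side, stimA_side)` (the chosen stimulus is A exactly when the
#' chosen side is the side A appeared on). Offending rows are reported by
#' row number.
#'
#' @param data Trial table data.frame.
#' @return Invisibly, `data`.
#' @export
validate_trials <- function(data) {
  miss <- setdiff(.schema_cols, names(data))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  if (nrow(data) == 0L) return(invisible(data))
  bad_row <- function(ok, what) {
    if (any(!ok)) stop("invalid ", what, " in rows: ",
                       paste(head(which(!ok), 10), collapse = ", "), call. = FALSE)
  }
  bad_row(data$task %in% c("what_only", "what_where"), "task")
  bad_row(data$block_type %in% c("what", "where"), "block_type")
  bad_row(!(data$task == "what_only" & data$block_type != "what"),
          "block_type (what_only task must have what blocks)")
  bad_row(data$stimA_side %in% c("L", "R"), "stimA_side")
  bad_row(data$choice_side %in% c("L", "R"), "choice_side")
  bad_row(data$choice_stim %in% c("A", "B"), "choice_stim")
  bad_row(data$reward %in% c(0L, 1L), "reward")
  bad_row(data$p_better > 0.5 & data$p_better <= 1, "p_better")
  bad_row(is.finite(data$reversal_trial) & data$reversal_trial >= 1,
          "reversal_trial")
  expected <- ifelse(data$choice_side == data$stimA_side, "A", "B")
  bad_row(data$choice_stim == expected,
          "choice_stim (inconsistent with choice_side/stimA_side)")
  invisible(data)
}

#' Read a cohort specification from a YAML config
#'
#' The file mirrors the [cohort_spec()] arguments, e.g.
#' ```yaml
#' group: amygdala
#' n_subjects: 4
#' n_sessions: 10
#' blocks_per_session: 20
#' task: what_where
#' mean:
#'   omega0: 0.18
#' ```
#'
#' @param path Path to the YAML file.
#' @return A `cohort_spec`.
#' @export
read_cohort_yaml <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the yaml package is required to read YAML configs")
  cfg <- yaml::read_yaml(path)
  allowed <- c("group", "n_subjects", "n_sessions", "blocks_per_session",
               "task", "model", "mean", "sd")
  bad <- setdiff(names(cfg), allowed)
  if (length(bad)) stop("unknown config fields: ", paste(bad, collapse = ", "))
  for (f in c("mean", "sd")) if (!is.null(cfg[[f]])) cfg[[f]] <- unlist(cfg[[f]])
  do.call(cohort_spec, cfg)
}

#' Read / write trial tables
#'
#' The interchange format is a UTF-8 CSV with a header row and exactly the
#' columns `subject, session, block, trial, task, block_type, p_better,
#' reversal_trial, stimA_side, choice_side, choice_stim, reward` (enums
#' `L`/`R`, `A`/`B`, `what`/`where`, `what_only`/`what_where`; reward 0/1).
#' `write_trials()` drops any extra columns (such as the simulator's
#' `better_id`); the written schema columns round-trip losslessly.
#'
#' @param path File path.
#' @param data Trial table (validated before writing).
#' @return `read_trials()`: the validated data.frame (empty with the schema
#'   columns for a header-only file). `write_trials()`: invisibly, `path`.
#' @export
read_trials <- function(path) {
  data <- read.csv(path, stringsAsFactors = FALSE, colClasses = list(
    subject = "character", stimA_side = "character",
    choice_side = "character", choice_stim = "character"))
  validate_trials(data)
  data[, .schema_cols]
}

#' @rdname read_trials
#' @export
write_trials <- function(data, path) {
  validate_trials(data)
  write.csv(data[, .schema_cols], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
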