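# Maximum-likelihood fitting, AIC model selection, and block-wise
# cross-validation.

#' McFadden pseudo-R-squared against the chance model
#'
#' `1 - sum(LL_model) / sum(LL_null)` where the null model predicts every
#' binary choice at chance, i.e. `LL_null = n_trials * ln(0.5)` per block.
#' The log base cancels in the ratio.
#'
#' @param neg_loglik Per-block negative log-likelihoods (natural log).
#' @param n_trials Trials per block (recycled; default 80).
#' @return The pseudo-R-squared (0 for a chance-level model, 1 for perfect
#'   prediction).
#' @export
mcfadden_r2 <- function(neg_loglik, n_trials = 80L) {
  n_trials <- rep_len(n_trials, length(neg_loglik))
  1 - sum(neg_loglik) / (sum(n_trials) * log(2))
}

.block_sizes <- function(data) {
  key <- interaction(data$subject, data$session, data$block, drop = TRUE)
  as.integer(table(key)[unique(key)])
}

#' Fit a choice model to trial data by maximum likelihood
#'
#' Minimizes the session negative log-likelihood with bounded quasi-Newton
#' (`L-BFGS-B`) local searches started from `n_starts` uniform-random points
#' inside the parameter box (plus the box midpoint), returning the best
#' solution. One parameter set is fitted to all supplied trials, with the
#' latent state resetting at every block (and session) boundary -- pass one
#' session to fit per session, or a whole subject for joint fits.
#'
#' @param data Trial table (see [read_trials()] for the schema).
#' @param model Model identifier, see [rl_model_ids()].
#' @param n_starts Number of random starts (20 is a desk-scale default; 100
#'   reproduces the full protocol).
#' @param fixed Optional named vector of parameters to pin (excluded from
#'   optimization and from the AIC parameter count), e.g. `c(rho = 0.61)`.
#' @param bounds Parameter box, defaults to [rl_bounds()].
#' @param v_init,carry_action Passed to [session_negloglik()].
#' @param seed Optional seed controlling the random starts.
#' @param starts Optional matrix of start values (rows = starts, columns in
#'   the order of the free parameters), replacing the random starts.
#' @param control Passed to [stats::optim()] (on top of `maxit = 500`).
#' @return An object of class `rl_fit` with `print()`, `summary()`,
#'   `coef()`, `logLik()`, `AIC()`, `predict()`, `residuals()`,
#'   `simulate()` and `plot()` methods.
#' @examples
#' \donttest{
#' blocks <- replicate(5, make_block_spec("what_only"), simplify = FALSE)
#' p <- rl_params("stim_only", alpha_pos = .6, alpha_neg = .3, zeta = .2,
#'                beta1 = 10, beta0 = 0)
#' sim <- simulate_session("stim_only", p, blocks, seed = 1)
#' fit <- fit_rl(sim$trials, "stim_only", n_starts = 5, seed = 1)
#' coef(fit)
#' }
#' @export
fit_rl <- function(data, model = "dynamic_omega_rho", n_starts = 20L,
                   fixed = NULL, bounds = rl_bounds(), v_init = 0.5,
                   carry_action = FALSE, seed = NULL, starts = NULL,
                   control = list()) {
  info <- .check_model(model)
  if (is.null(data) || nrow(data) == 0L) stop("empty trial table")
  if (!is.null(seed)) set.seed(seed)
  pars <- info$pars
  if (!is.null(fixed)) {
    bad <- setdiff(names(fixed), pars)
    if (length(bad)) stop("fixed parameters not in model: ",
                          paste(bad, collapse = ", "))
  }
  free <- setdiff(pars, names(fixed))
  if (!length(free)) stop("no free parameters")
  lo <- bounds$lower[free]
  hi <- bounds$upper[free]
  enc <- .encode_trials(data)
  full <- numeric(length(.par_layout))
  names(full) <- .par_layout
  if (!is.null(fixed)) full[names(fixed)] <- fixed
  objective <- function(theta) {
    full[free] <- theta
    v <- tryCatch(
      cpp_session_loglik(info$code, full, info$rel, enc$session, enc$block,
                         enc$stimA_left, enc$choose_right, enc$reward,
                         v_init, carry_action, FALSE)$nll,
      error = function(e) Inf)
    if (!is.finite(v)) 1e12 else v
  }
  if (is.null(starts)) {
    mid <- (lo + hi) / 2
    starts <- if (n_starts == 1L) rbind(mid)
      else rbind(mid,
                 matrix(runif((n_starts - 1L) * length(free)),
                        ncol = length(free)) %*% diag(hi - lo, length(free)) +
                   matrix(lo, n_starts - 1L, length(free), byrow = TRUE))
  } else {
    starts <- matrix(starts, ncol = length(free))
  }
  best <- NULL
  ctrl <- modifyList(list(maxit = 500L), control)
  for (s in seq_len(nrow(starts))) {
    res <- tryCatch(
      optim(starts[s, ], objective, method = "L-BFGS-B", lower = lo,
            upper = hi, control = ctrl),
      error = function(e) NULL)
    if (is.null(res)) next
    if (is.null(best) || res$value < best$value) {
      best <- res
      best$start <- s
    }
  }
  if (is.null(best)) stop("optimizer failed on all starts")
  coefs <- full
  coefs[free] <- best$par
  coefs <- coefs[pars]
  k <- length(free)
  nll <- best$value
  sizes <- .block_sizes(data)
  out <- list(call = match.call(), model = model, coefficients = coefs,
              free = free, fixed = fixed, neg_loglik = nll,
              aic = 2 * k + 2 * nll, k = k,
              mcfadden_r2 = 1 - nll / (sum(sizes) * log(2)),
              n_trials = nrow(data), n_blocks = length(sizes),
              n_starts = nrow(starts), best_start = best$start,
              converged = best$convergence == 0L,
              data = data, v_init = v_init, carry_action = carry_action,
              bounds = bounds)
  class(out) <- "rl_fit"
  out
}

#' @export
print.rl_fit <- function(x, digits = 4, ...) {
  cat(sprintf("Maximum-likelihood fit of the '%s' model\n", x$model))
  cat(sprintf("  %d trials in %d blocks; %d starts (best: #%d, %s)\n",
              x$n_trials, x$n_blocks, x$n_starts, x$best_start,
              if (x$converged) "converged" else "not converged"))
  cat(sprintf("  -LL = %.*f   AIC = %.*f   McFadden R2 = %.*f\n",
              digits, x$neg_loglik, digits, x$aic, digits, x$mcfadden_r2))
  cat("Coefficients:\n")
  print(round(x$coefficients, digits))
  if (!is.null(x$fixed))
    cat("  (fixed: ", paste(names(x$fixed), collapse = ", "), ")\n", sep = "")
  invisible(x)
}

#' @export
coef.rl_fit <- function(object, ...) object$coefficients

#' @export
logLik.rl_fit <- function(object, ...) {
  structure(-object$neg_loglik, df = object$k, nobs = object$n_trials,
            class = "logLik")
}

#' @export
summary.rl_fit <- function(object, ...) {
  structure(list(fit = object,
                 per_block = .per_block_nll(object)), class = "summary.rl_fit")
}

.per_block_nll <- function(fit, data = NULL) {
  data <- if (is.null(data)) fit$data else data
  key <- interaction(data$subject, data$session, data$block, drop = TRUE)
  sapply(split(data, key)[unique(as.character(key))], function(b)
    session_negloglik(fit$model, fit$coefficients, b, v_init = fit$v_init))
}

#' @export
print.summary.rl_fit <- function(x, ...) {
  print(x$fit)
  pb <- x$per_block
  cat(sprintf("Per-block -LL: mean %.3f, range [%.3f, %.3f] over %d blocks\n",
              mean(pb), min(pb), max(pb), length(pb)))
  invisible(x)
}

#' Predict choice probabilities or latent trajectories
#'
#' @param object An `rl_fit`.
#' @param newdata Optional trial table (defaults to the fitted data).
#' @param type `"response"` for the per-trial probability of a rightward
#'   choice, `"trajectory"` for the full per-trial latent trajectory
#'   (overall values, choice probability, arbitration weights, reliability
#'   signal, prediction errors).
#' @param ... Unused.
#' @return Numeric vector or data.frame, matching `newdata` rows.
#' @export
predict.rl_fit <- function(object, newdata = NULL,
                           type = c("response", "trajectory"), ...) {
  type <- match.arg(type)
  data <- if (is.null(newdata)) object$data else newdata
  res <- session_negloglik(object$model, object$coefficients, data,
                           v_init = object$v_init,
                           carry_action = object$carry_action,
                           want_traj = TRUE)
  if (type == "response") res$traj$p_right
  else cbind(data[, intersect(c("subject", "session", "block", "trial"),
                              names(data)), drop = FALSE], res$traj)
}

#' @export
fitted.rl_fit <- function(object, ...) predict(object, type = "response")

#' @export
residuals.rl_fit <- function(object, type = c("response", "pearson"), ...) {
  type <- match.arg(type)
  p <- predict(object, type = "response")
  y <- as.integer(object$data$choice_side == "R")
  if (type == "response") y - p else (y - p) / sqrt(p * (1 - p))
}

#' Simulate new choice data from a fitted model
#'
#' Replays the fitted block environments (schedule, reversal trial, block
#' type) with fresh choices and rewards generated by the fitted parameters.
#' If the fitted data carry no `better_id` column (it is not part of the
#' interchange schema), the initially better target of each block is drawn
#' uniformly.
#'
#' @param object An `rl_fit`.
#' @param nsim Number of replicate datasets.
#' @param seed Optional seed.
#' @param ... Unused.
#' @return A list of `nsim` trial tables.
#' @export
simulate.rl_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  data <- object$data
  key <- interaction(data$subject, data$session, data$block, drop = TRUE)
  blocks <- lapply(split(data, key)[unique(as.character(key))], function(b) {
    make_block_spec(task = b$task[1], n_trials = nrow(b),
                    p_better = b$p_better[1],
                    reversal_trial = b$reversal_trial[1],
                    block_type = b$block_type[1],
                    better_id = if (!is.null(b$better_id)) b$better_id[1])
  })
  lapply(seq_len(nsim), function(i)
    simulate_session(object$model, object$coefficients, blocks,
                     subject_id = as.character(data$subject[1]),
                     session_id = data$session[1],
                     v_init = object$v_init,
                     carry_action = object$carry_action)$trials)
}

#' @export
plot.rl_fit <- function(x, n_anchor = 20L, smooth_window = 5L, ...) {
  traj <- predict(x, type = "trajectory")
  has_omega <- !all(is.na(traj$Omega))
  y <- if (has_omega) traj$Omega else traj$p_right
  key <- interaction(x$data$subject, x$data$session, x$data$block, drop = TRUE)
  al <- align_and_smooth(split(y, key),
                         reversal = tapply(x$data$reversal_trial, key, `[`, 1),
                         n_anchor = n_anchor, smooth_window = smooth_window)
  plot(al, ylab = if (has_omega) expression(Omega) else "P(right)", ...)
  invisible(x)
}

# --- two-stage subject-level rho -------------------------------------------

#' Two-stage per-subject estimation of the baseline ratio
#'
#' Stage 1 fits the `dynamic_omega_rho` model jointly to all of a subject's
#' sessions (one parameter set); only the baseline signal-strength ratio
#' `rho` is kept, as it is assumed constant for a subject. Stage 2 refits
#' every session separately with `rho` fixed at the stage-1 value.
#'
#' @param data All trials of one subject (multiple sessions).
#' @param n_starts Random starts per fit.
#' @param seed Optional seed.
#' @param ... Passed to [fit_rl()].
#' @return List with `rho`, `stage1` (the joint `rl_fit`) and
#'   `session_fits` (named list of per-session `rl_fit`s, all carrying the
#'   same fixed `rho`).
#' @export
fit_rho_subject <- function(data, n_starts = 20L, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  stage1 <- fit_rl(data, "dynamic_omega_rho", n_starts = n_starts, ...)
  rho <- unname(coef(stage1)[["rho"]])
  fits <- lapply(split(data, data$session), function(s)
    fit_rl(s, "dynamic_omega_rho", n_starts = n_starts,
           fixed = c(rho = rho), ...))
  list(rho = rho, stage1 = stage1, session_fits = fits)
}

# --- cross-validation ------------------------------------------------------

#' Repeated k-fold block-wise cross-validation
#'
#' Per repeat, blocks are randomly partitioned into `k` folds of as-equal-as-
#' possible size; each fold serves once as the held-out set while one
#' parameter set is fitted to the remaining blocks, and the held-out
#' negative log-likelihood is evaluated per block. Every block is tested
#' exactly once per repeat. The summary score is the mean per-block held-out
#' negative log-likelihood over all repeats.
#'
#' @param data Trial table of one subject.
#' @param model Model identifier.
#' @param k Number of folds (default 5).
#' @param repeats Number of random re-partitions (50 reproduces the full
#'   protocol; 10 is a desk-scale default).
#' @param n_starts Random starts per training fit.
#' @param seed Optional seed.
#' @param ... Passed to [fit_rl()].
#' @return An object of class `rl_cv`: `table` (per repeat/fold/block
#'   held-out -LL and trial count), `mean_negloglik` (mean per-block),
#'   `mean_mcfadden`.
#' @export
crossval_rl <- function(data, model, k = 5L, repeats = 10L, n_starts = 10L,
                        seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  key <- interaction(data$subject, data$session, data$block, drop = TRUE)
  blocks <- unique(as.character(key))
  n_blk <- length(blocks)
  if (n_blk < k) stop("fewer blocks (", n_blk, ") than folds (", k, ")")
  rows <- list()
  for (r in seq_len(repeats)) {
    fold <- sample(rep_len(seq_len(k), n_blk))
    for (f in seq_len(k)) {
      test_blocks <- blocks[fold == f]
      train <- data[!(as.character(key) %in% test_blocks), , drop = FALSE]
      fit <- fit_rl(train, model, n_starts = n_starts, ...)
      for (tb in test_blocks) {
        bd <- data[as.character(key) == tb, , drop = FALSE]
        nll <- session_negloglik(model, coef(fit), bd,
                                 v_init = fit$v_init)
        rows[[length(rows) + 1L]] <- data.frame(
          repeat_ = r, fold = f, block = tb, neg_loglik = nll,
          n_trials = nrow(bd), stringsAsFactors = FALSE)
      }
    }
  }
  tab <- do.call(rbind, rows)
  structure(list(model = model, k = k, repeats = repeats, table = tab,
                 mean_negloglik = mean(tab$neg_loglik),
                 mean_mcfadden = 1 - sum(tab$neg_loglik) /
                   (sum(tab$n_trials) * log(2))),
            class = "rl_cv")
}

#' @export
print.rl_cv <- function(x, ...) {
  cat(sprintf("%d-fold CV (%d repeats) of '%s': mean per-block -LL = %.3f, McFadden R2 = %.3f\n",
              x$k, x$repeats, x$model, x$mean_negloglik, x$mean_mcfadden))
  invisible(x)
}

#' AIC model-selection table
#'
#' @param fits A (named) list of `rl_fit` objects fitted to the same data.
#' @return Data.frame with one row per model (`model`, `k`, `neg_loglik`,
#'   `aic`, `delta_aic`, `best`), ties broken toward fewer parameters.
#' @export
model_selection_table <- function(fits) {
  tab <- data.frame(
    model = vapply(fits, function(f) f$model, ""),
    k = vapply(fits, function(f) as.integer(f$k), 0L),
    neg_loglik = vapply(fits, function(f) f$neg_loglik, 0),
    aic = vapply(fits, function(f) f$aic, 0),
    stringsAsFactors = FALSE)
  ord <- order(tab$aic, tab$k)
  tab$delta_aic <- tab$aic - tab$aic[ord[1]]
  tab$best <- seq_len(nrow(tab)) == ord[1]
  rownames(tab) <- NULL
  tab
}
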