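# Entropy of reward-dependent strategy (ERDS) and derived metrics.
# Entropies are in bits (log base 2); empirical plug-in frequencies with the
# 0 * log 0 := 0 convention, no smoothing.

#' Stay/switch series conditioned on previous reward
#'
#' For one block of trials, codes each trial from the second onward as stay
#' (1) or switch (0) on the requested dimension -- stimulus identity
#' (`choice_stim`) or action (`choice_side`) -- together with the previous
#' trial's reward. The first trial has no predecessor and is masked invalid.
#'
#' @param trials Data.frame of one block's trials (columns `choice_stim`,
#'   `choice_side`, `reward`), in trial order.
#' @param dimension `"stimulus"` or `"action"`.
#' @return Data.frame of class `stay_reward_series` with columns `trial`,
#'   `stay`, `prev_reward`, `valid`.
#' @export
stay_reward_series <- function(trials, dimension = c("stimulus", "action")) {
  dimension <- match.arg(dimension)
  n <- nrow(trials)
  if (n < 2L) stop("need at least 2 trials")
  ch <- if (dimension == "stimulus") trials$choice_stim else trials$choice_side
  stay <- c(NA_integer_, as.integer(ch[-1L] == ch[-n]))
  prev_rew <- c(NA_integer_, as.integer(trials$reward[-n]))
  structure(data.frame(trial = seq_len(n), stay = stay,
                       prev_reward = prev_rew,
                       valid = c(FALSE, rep(TRUE, n - 1L))),
            class = c("stay_reward_series", "data.frame"),
            dimension = dimension)
}

# binary entropy in bits, 0 log 0 := 0
.h2 <- function(p) {
  ifelse(p <= 0 | p >= 1, 0, -p * log2(p) - (1 - p) * log2(1 - p))
}

#' ERDS from stay/switch-by-reward counts
#'
#' The conditional Shannon entropy (bits) of the stay/switch strategy given
#' the previous reward:
#' `H(str | rew) = P(win) H2(P(stay | win)) + P(lose) H2(P(stay | lose))`.
#' Zero for a deterministic feedback-driven strategy (e.g. perfect
#' win-stay/lose-switch); 1 bit when staying is a fair coin independent of
#' reward. When only one reward branch occurs, the result is the entropy of
#' that single branch.
#'
#' @param stay_win,switch_win,stay_lose,switch_lose Joint counts.
#' @return ERDS in bits, in \[0, 1\].
#' @export
erds_from_counts <- function(stay_win, switch_win, stay_lose, switch_lose) {
  n <- stay_win + switch_win + stay_lose + switch_lose
  if (n == 0) stop("no valid trials")
  p_win <- (stay_win + switch_win) / n
  p_lose <- 1 - p_win
  h_win <- if (p_win > 0) .h2(stay_win / (stay_win + switch_win)) else 0
  h_lose <- if (p_lose > 0) .h2(stay_lose / (stay_lose + switch_lose)) else 0
  p_win * h_win + p_lose * h_lose
}

#' ERDS of a stay/reward series
#'
#' @param series A [stay_reward_series()] (invalid trials are dropped), or a
#'   data.frame with `stay`, `prev_reward`, and optionally `valid` columns.
#' @return A list of class `erds_result`: `erds` (bits), and the joint
#'   `counts` (stay/switch x win/lose) it was computed from.
#' @export
erds <- function(series) {
  ok <- if (!is.null(series$valid)) series$valid else rep(TRUE, nrow(series))
  ok <- ok & !is.na(series$stay) & !is.na(series$prev_reward)
  if (!any(ok)) stop("no valid trials")
  s <- series$stay[ok]
  r <- series$prev_reward[ok]
  counts <- c(stay_win = sum(s == 1 & r == 1), switch_win = sum(s == 0 & r == 1),
              stay_lose = sum(s == 1 & r == 0), switch_lose = sum(s == 0 & r == 0))
  structure(list(erds = do.call(erds_from_counts, as.list(counts)),
                 counts = counts), class = "erds_result")
}

#' @export
print.erds_result <- function(x, ...) {
  cat(sprintf("ERDS = %.4f bits  (stay/win %d, switch/win %d, stay/lose %d, switch/lose %d)\n",
              x$erds, x$counts[1], x$counts[2], x$counts[3], x$counts[4]))
  invisible(x)
}

# ERDS value (scalar) of a block on one dimension; NA if no valid trials in
# the supplied window.
.erds_value <- function(stay, prev_rew) {
  ok <- !is.na(stay) & !is.na(prev_rew)
  if (!any(ok)) return(NA_real_)
  erds_from_counts(sum(stay[ok] == 1 & prev_rew[ok] == 1),
                   sum(stay[ok] == 0 & prev_rew[ok] == 1),
                   sum(stay[ok] == 1 & prev_rew[ok] == 0),
                   sum(stay[ok] == 0 & prev_rew[ok] == 0))
}

#' Sliding-window strategy dominance labels
#'
#' For every trial whose trailing window of `window` trials lies fully
#' inside its block, computes ERDS on the stimulus and action dimensions
#' over that window and labels the trial `stim_dominant` if
#' `ERDS_stim < ERDS_action`, `action_dominant` if the reverse holds, and
#' `tie` otherwise (ties are typically excluded downstream). The window is
#' trailing (causal) and never crosses block boundaries; trials with an
#' incomplete window get `NA` labels.
#'
#' @param trials Trial table (any number of subjects/sessions/blocks).
#' @param window Window length in trials (default 10, minimum 2).
#' @return `trials` with added columns `erds_stim_w`, `erds_action_w`,
#'   `dominance`.
#' @export
sliding_dominance <- function(trials, window = 10L) {
  if (window < 2L) stop("window must be >= 2")
  key <- interaction(trials$subject, trials$session, trials$block, drop = TRUE)
  out_s <- out_a <- rep(NA_real_, nrow(trials))
  for (blk in split(seq_len(nrow(trials)), key)) {
    b <- trials[blk, ]
    ss <- stay_reward_series(b, "stimulus")
    sa <- stay_reward_series(b, "action")
    n <- nrow(b)
    for (t in seq_len(n)) {
      if (t < window) next
      idx <- (t - window + 1L):t
      idx <- idx[idx >= 2L] # first trial of the block has no stay flag
      out_s[blk[t]] <- .erds_value(ss$stay[idx], ss$prev_reward[idx])
      out_a[blk[t]] <- .erds_value(sa$stay[idx], sa$prev_reward[idx])
    }
  }
  lab <- rep(NA_character_, nrow(trials))
  done <- !is.na(out_s) & !is.na(out_a)
  lab[done] <- ifelse(out_s[done] < out_a[done], "stim_dominant",
                      ifelse(out_a[done] < out_s[done], "action_dominant", "tie"))
  trials$erds_stim_w <- out_s
  trials$erds_action_w <- out_a
  trials$dominance <- lab
  trials
}

#' Per-block ERDS table
#'
#' One row per (subject, session, block) with ERDS on both dimensions and
#' their difference `delta_erds = erds_stim - erds_action` (negative values
#' indicate a more consistent stimulus-based strategy).
#'
#' @param trials Trial table.
#' @return Data.frame with columns `subject`, `session`, `block`,
#'   `block_type`, `p_better`, `erds_stim`, `erds_action`, `delta_erds`.
#' @export
erds_by_block <- function(trials) {
  key <- interaction(trials$subject, trials$session, trials$block, drop = TRUE)
  rows <- lapply(split(seq_len(nrow(trials)), key), function(blk) {
    b <- trials[blk, ]
    es <- erds(stay_reward_series(b, "stimulus"))$erds
    ea <- erds(stay_reward_series(b, "action"))$erds
    data.frame(subject = b$subject[1], session = b$session[1],
               block = b$block[1], block_type = b$block_type[1],
               p_better = b$p_better[1], erds_stim = es, erds_action = ea,
               delta_erds = es - ea, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$subject, out$session, out$block), , drop = FALSE]
}
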