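# Effective arbitration rates, trajectory alignment, and the group
# permutation test.

#' Effective arbitration rates from an Omega trajectory
#'
#' Decomposes the per-trial change of the effective arbitration weight into
#' normalized steps toward the stimulus-based system
#' (`psi_plus = [dOmega]+ / (1 - Omega)`) and toward the action-based system
#' (`psi_minus = [dOmega]- / (0 - Omega)`), mirroring the form of a learning
#' rate. At most one of the two is nonzero per trial; both are zero when
#' `Omega` does not change. At the boundary values `Omega = 1` (no headroom
#' upward) and `Omega = 0` (none downward) the corresponding rate is defined
#' as 0. Plugging the rates back into the update form reconstructs the
#' trajectory exactly.
#'
#' @param omega_eff Numeric vector, the per-trial `Omega` in \[0, 1\].
#' @return Data.frame with `trial` (1..n-1), `psi_plus`, `psi_minus`; the
#'   rate at row `t` maps `Omega[t]` to `Omega[t + 1]`.
#' @export
effective_rates <- function(omega_eff) {
  n <- length(omega_eff)
  if (n < 2L) stop("need at least two trials of Omega")
  if (any(omega_eff < 0 | omega_eff > 1, na.rm = TRUE))
    stop("Omega outside [0, 1]")
  d <- diff(omega_eff)
  om <- omega_eff[-n]
  psi_plus <- ifelse(d > 0, ifelse(om >= 1, 0, pmax(d, 0) / (1 - om)), 0)
  psi_minus <- ifelse(d < 0, ifelse(om <= 0, 0, -pmin(d, 0) / om), 0)
  data.frame(trial = seq_len(n - 1L), psi_plus = psi_plus,
             psi_minus = psi_minus)
}

#' Post-reversal difference of arbitration rates
#'
#' Means of `psi_plus` and `psi_minus` over the trials at and after the
#' reversal, and their difference `delta_psi = mean(psi_plus) -
#' mean(psi_minus)`. Positive values indicate net arbitration toward the
#' stimulus-based system after the reversal.
#'
#' @param omega_eff Per-trial `Omega` of one block.
#' @param reversal_trial The block's reversal trial (1-based).
#' @return List with `psi_plus`, `psi_minus` (post-reversal means) and
#'   `delta_psi`.
#' @export
delta_psi_post_reversal <- function(omega_eff, reversal_trial) {
  n <- length(omega_eff)
  if (reversal_trial < 1 || reversal_trial >= n)
    stop("reversal_trial outside the block")
  rates <- effective_rates(omega_eff)
  post <- rates$trial >= reversal_trial
  pp <- mean(rates$psi_plus[post])
  pm <- mean(rates$psi_minus[post])
  list(psi_plus = pp, psi_minus = pm, delta_psi = pp - pm)
}

# moving average with partial windows at the edges (centered)
.movavg <- function(x, w) {
  if (w <= 1L || length(x) < 2L) return(x)
  half <- (w - 1L) %/% 2L
  n <- length(x)
  vapply(seq_len(n), function(i) {
    idx <- max(1L, i - half):min(n, i + half + (w - 1L) %% 2L)
    mean(x[idx], na.rm = TRUE)
  }, 0)
}

#' Align per-trial quantities across blocks and smooth
#'
#' Re-indexes each block's per-trial series onto a common axis by
#' concatenating `n_anchor` trials forward from the block start, `n_anchor`
#' forward from the reversal, and `n_anchor` backward from the block end
#' (accounting for the random reversal position), then averages across
#' blocks and smooths with a centered moving window applied separately
#' within each segment -- so the acquisition phase (start segment) never
#' leaks into the reversal phase (reversal and end segments), and no
#' smoothing crosses the segment joints. Blocks too short around an anchor
#' contribute masked (NA) entries.
#'
#' @param x A list of numeric vectors (one per block) or a blocks x trials
#'   matrix.
#' @param reversal Integer vector of reversal trials, one per block.
#' @param n_anchor Trials taken per anchor (default 20).
#' @param smooth_window Moving-average window (default 5); 1 disables
#'   smoothing.
#' @return Object of class `aligned_trajectory`: `mean` and `se` (length
#'   `3 * n_anchor`, smoothed), `raw_mean` (unsmoothed), `aligned` (blocks x
#'   `3 * n_anchor` matrix), `segment` (factor: `start`, `reversal`, `end`),
#'   `phase` (factor: `acquisition`, `reversal`).
#' @export
align_and_smooth <- function(x, reversal, n_anchor = 20L, smooth_window = 5L) {
  if (is.matrix(x)) x <- split(x, row(x))
  if (length(x) != length(reversal))
    stop("need one reversal trial per block")
  L <- 3L * n_anchor
  aligned <- matrix(NA_real_, length(x), L)
  for (b in seq_along(x)) {
    v <- x[[b]]
    n <- length(v)
    take <- function(idx) ifelse(idx >= 1L & idx <= n, v[pmax(pmin(idx, n), 1L)], NA_real_)
    aligned[b, ] <- c(take(seq_len(n_anchor)),
                      take(reversal[b] + 0:(n_anchor - 1L)),
                      take((n - n_anchor + 1L):n))
  }
  raw_mean <- colMeans(aligned, na.rm = TRUE)
  se <- apply(aligned, 2, function(col) {
    col <- col[!is.na(col)]
    if (length(col) < 2L) NA_real_ else sd(col) / sqrt(length(col))
  })
  seg <- factor(rep(c("start", "reversal", "end"), each = n_anchor),
                levels = c("start", "reversal", "end"))
  sm <- raw_mean
  for (s in levels(seg)) sm[seg == s] <- .movavg(raw_mean[seg == s], smooth_window)
  structure(list(mean = sm, se = se, raw_mean = raw_mean, aligned = aligned,
                 segment = seg,
                 phase = factor(ifelse(seg == "start", "acquisition", "reversal"),
                                levels = c("acquisition", "reversal")),
                 n_anchor = n_anchor, smooth_window = smooth_window),
            class = "aligned_trajectory")
}

#' @export
plot.aligned_trajectory <- function(x, ylab = "value", xlab = "aligned trial",
                                    col = "black", band = TRUE, ...) {
  n <- length(x$mean)
  graphics::plot(seq_len(n), x$mean, type = "n", ylab = ylab, xlab = xlab, ...)
  if (band && !all(is.na(x$se))) {
    ok <- !is.na(x$se)
    graphics::polygon(c(which(ok), rev(which(ok))),
                      c((x$mean + x$se)[ok], rev((x$mean - x$se)[ok])),
                      col = grDevices::adjustcolor(col, 0.2), border = NA)
  }
  for (s in levels(x$segment)) {
    idx <- which(x$segment == s)
    graphics::lines(idx, x$mean[idx], col = col, lwd = 2)
  }
  graphics::abline(v = x$n_anchor + c(0.5, x$n_anchor + 0.5), lty = 3)
  invisible(x)
}

#' Two-sided permutation test for a two-group mean difference
#'
#' Tests the difference of group means by randomly shuffling the group
#' assignment. The p-value is the proportion of permuted |statistic| values
#' at least as extreme as the observed one, counting the observed labeling
#' itself (so the p-value is never 0):
#' `p = (1 + #extreme) / (n_perm + 1)`.
#'
#' @param values Numeric vector (one value per subject).
#' @param groups Group labels (exactly two distinct values).
#' @param n_perm Number of random shuffles (default 10000).
#' @param seed Optional seed.
#' @return List with `p_value`, `observed` (mean of group 1 minus mean of
#'   group 2, groups in factor-level order), and `perm` (the permuted
#'   statistics).
#' @export
permutation_test_groups <- function(values, groups, n_perm = 10000L,
                                    seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  groups <- factor(groups)
  if (nlevels(groups) != 2L) stop("need exactly two groups")
  if (min(table(groups)) < 1L) stop("each group needs at least one value")
  g1 <- levels(groups)[1]
  stat <- function(g) mean(values[g == g1]) - mean(values[g != g1])
  obs <- stat(groups)
  perm <- vapply(seq_len(n_perm), function(i) stat(sample(groups)), 0)
  p <- (1 + sum(abs(perm) >= abs(obs))) / (n_perm + 1)
  list(p_value = p, observed = obs, perm = perm)
}
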