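# Task environments, reward generation, and the synthetic cohort generator.

test_that("block specs are drawn from the task's distributions", {
  set.seed(1)
  expect_true(all(replicate(200, make_block_spec("what_only")$block_type) == "what"))
  n <- 10000
  specs <- replicate(n, make_block_spec("what_where"), simplify = FALSE)
  rev <- vapply(specs, `[[`, 0L, "reversal_trial")
  expect_true(all(rev >= 30 & rev <= 50))
  # uniform over the 21 possible reversal trials: each bin within 3 binomial SDs
  expected <- n / 21
  sd3 <- 3 * sqrt(n * (1 / 21) * (20 / 21))
  counts <- table(factor(rev, levels = 30:50))
  expect_true(all(abs(counts - expected) <= sd3))
  # block type a fair coin
  frac_what <- mean(vapply(specs, `[[`, "", "block_type") == "what")
  expect_lt(abs(frac_what - 0.5), 3 * sqrt(0.25 / n))
  # schedules uniform over the three values
  pb <- vapply(specs, `[[`, 0, "p_better")
  expect_true(all(pb %in% c(0.8, 0.7, 0.6)))
  expect_true(all(abs(table(pb) - n / 3) <= 3 * sqrt(n * (1 / 3) * (2 / 3))))
})

test_that("rewards follow the schedule and flip at the reversal trial", {
  spec <- make_block_spec("what_only", p_better = 1, reversal_trial = 40,
                          better_id = "A")
  set.seed(2)
  expect_true(all(replicate(50, sample_reward(spec, 10, "L", "A")) == 1))
  expect_true(all(replicate(50, sample_reward(spec, 40, "L", "A")) == 0))
  spec8 <- make_block_spec("what_only", p_better = 0.8, reversal_trial = 40,
                           better_id = "A")
  n <- 10000
  r_pre <- replicate(n, sample_reward(spec8, 5, "R", "A"))
  expect_lt(abs(mean(r_pre) - 0.8), 3 * sqrt(0.8 * 0.2 / n))
  # where block: previously better side at the reversal trial pays 1 - p
  specw <- make_block_spec("what_where", block_type = "where", p_better = 0.8,
                           reversal_trial = 40, better_id = "L")
  r_at <- replicate(n, sample_reward(specw, 40, "L", "A"))
  expect_lt(abs(mean(r_at) - 0.2), 3 * sqrt(0.2 * 0.8 / n))
  # where blocks pay on side regardless of stimulus
  r_stim <- replicate(2000, sample_reward(specw, 5, "L", sample(c("A", "B"), 1)))
  expect_lt(abs(mean(r_stim) - 0.8), 3 * sqrt(0.8 * 0.2 / 2000))
  expect_error(sample_reward(spec, 81, "L", "A"), "outside")
})

test_that("flat softmax yields unbiased sides and simulation is reproducible", {
  p <- control_params("stim_only", beta1 = 0, beta0 = 0)
  sim <- quick_session("stim_only", p, n_blocks = 125, seed = 3)
  n <- nrow(sim$trials)
  expect_equal(n, 10000)
  expect_lt(abs(mean(sim$trials$choice_side == "R") - 0.5), 3 * sqrt(0.25 / n))
  # bit-identical repetition under the same seed
  blocks <- what_blocks(4)
  s1 <- simulate_session("dynamic_omega_rho", control_params(), blocks, seed = 77)
  s2 <- simulate_session("dynamic_omega_rho", control_params(), blocks, seed = 77)
  expect_identical(s1, s2)
})

test_that("a pure stimulus learner acquires the better option", {
  # oracle: the single-system update rule is tested independently above;
  # the static two-system model at omega = 1 must reproduce its learning.
  p <- control_params("static_omega", omega = 1, beta1 = 20)
  set.seed(4)
  hits <- 0L
  trials <- 0L
  for (b in 1:2000) {
    blocks <- what_blocks(1)
    sim <- simulate_session("static_omega", p, blocks)
    late <- sim$trials[sim$trials$trial >= 20 & sim$trials$trial < 30, ]
    hits <- hits + sum(chose_better(late))
    trials <- trials + nrow(late)
  }
  expect_gt(hits / trials, 0.7)
})

test_that("stimulus-side assignment is independent of the reward process", {
  p <- control_params("dynamic_omega_rho")
  sim <- quick_session("dynamic_omega_rho", p, n_blocks = 60, seed = 5)
  tr <- sim$trials
  # conditional on the chosen stimulus, side carries no reward information
  for (cs in c("A", "B")) {
    sub <- tr[tr$choice_stim == cs, ]
    r <- cor(as.integer(sub$stimA_side == "L"), sub$reward)
    expect_lt(abs(r), 4 / sqrt(nrow(sub)))
  }
  expect_lt(abs(mean(tr$stimA_side == "L") - 0.5), 3 * sqrt(0.25 / nrow(tr)))
  # balanced option: exact within-block counterbalance
  set.seed(6)
  simb <- simulate_session("stim_only", control_params("stim_only"),
                           what_blocks(5), balance_sides = TRUE)
  per_block <- tapply(simb$trials$stimA_side == "L", simb$trials$block, sum)
  expect_true(all(per_block == 40))
})

test_that("cohort generation respects group structure and ground truth", {
  expect_null(generate_cohort(cohort_spec("control", n_subjects = 0))$trials)
  spec_a <- cohort_spec("amygdala", n_subjects = 20, n_sessions = 1,
                        blocks_per_session = 1)
  spec_c <- cohort_spec("control", n_subjects = 20, n_sessions = 1,
                        blocks_per_session = 1)
  coh_a <- generate_cohort(spec_a, seed = 7)
  coh_c <- generate_cohort(spec_c, seed = 8)
  expect_lt(mean(coh_a$truth$omega0), mean(coh_c$truth$omega0))
  expect_lt(mean(generate_cohort(cohort_spec("vs", n_subjects = 20,
                                             n_sessions = 1,
                                             blocks_per_session = 1),
                                 seed = 9)$truth$rho),
            mean(coh_c$truth$rho))
  # exactly one rho per subject
  expect_equal(nrow(coh_c$truth), 20)
  expect_equal(anyDuplicated(coh_c$truth$subject), 0)
  # shape: subjects x sessions x blocks x trials
  coh <- generate_cohort(cohort_spec("control", n_subjects = 2, n_sessions = 2,
                                     blocks_per_session = 3), seed = 10)
  expect_equal(nrow(coh$trials), 2 * 2 * 3 * 80)
  expect_true(all(table(coh$trials$subject) == 2 * 3 * 80))
  # infeasible distribution is rejected
  expect_error(generate_cohort(cohort_spec("control", mean = c(rho = 2))),
               "bounds|mean")
})

test_that("trial tables round-trip through the CSV schema", {
  coh <- generate_cohort(cohort_spec("control", n_subjects = 2, n_sessions = 1,
                                     blocks_per_session = 2), seed = 11)
  path <- tempfile(fileext = ".csv")
  write_trials(coh$trials, path)
  back <- read_trials(path)
  schema <- c("subject", "session", "block", "trial", "task", "block_type",
              "p_better", "reversal_trial", "stimA_side", "choice_side",
              "choice_stim", "reward")
  expect_equal(back, coh$trials[, schema], ignore_attr = TRUE)
  # corrupted stimulus identity is caught with its row number
  bad <- coh$trials
  bad$choice_stim[3] <- ifelse(bad$choice_stim[3] == "A", "B", "A")
  expect_error(validate_trials(bad), "rows: 3")
  # header-only file reads as an empty table
  writeLines(paste(schema, collapse = ","), path)
  empty <- read_trials(path)
  expect_equal(nrow(empty), 0)
  expect_equal(names(empty), schema)
  expect_error(validate_trials(data.frame(subject = 1)), "missing columns")
})

test_that("cohort specs load from YAML configs", {
  path <- tempfile(fileext = ".yaml")
  writeLines(c("group: amygdala", "n_subjects: 4", "n_sessions: 2",
               "blocks_per_session: 3", "task: what_where",
               "mean:", "  omega0: 0.18"), path)
  spec <- read_cohort_yaml(path)
  expect_s3_class(spec, "cohort_spec")
  expect_equal(spec$group, "amygdala")
  expect_equal(spec$n_subjects, 4L)
  expect_equal(unname(spec$mean[["omega0"]]), 0.18)
  writeLines("unknown_field: 1", path)
  expect_error(read_cohort_yaml(path), "unknown config fields")
})
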