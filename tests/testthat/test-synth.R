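test_that("generation is deterministic under a fixed seed", {
  cfg <- sim_config(n_users = 10L, seed = 1L)
  s1 <- simulate_cohort(cfg, streams = TRUE)
  s2 <- simulate_cohort(cfg, streams = TRUE)
  expect_identical(s1$users, s2$users)
  expect_identical(s1$truth, s2$truth)
  expect_identical(s1$streams, s2$streams)
})

test_that("degenerate probabilities behave as stated", {
  u <- generate_users(sim_config(n_users = 50L, p_used = 0, seed = 2L))
  expect_false(any(u$used_flag))
  cfg <- sim_config(n_users = 50L, zero_inflation = 1, seed = 2L)
  truth <- generate_outcomes(generate_users(cfg), cfg)
  expect_true(all(truth$visit_hours == 0L))
  expect_true(all(truth$log_outcome == 0))
})

test_that("marginals are calibrated to within 3 binomial SEs at n = 5000", {
  cfg <- sim_config(n_users = 5000L, seed = 7L)
  u <- generate_users(cfg)
  se <- function(p) sqrt(p * (1 - p) / nrow(u))
  expect_lt(abs(mean(u$used_flag) - cfg$p_used), 3 * se(cfg$p_used))
  shares <- prop.table(table(u$consumption_level))
  for (lev in names(cfg$consumption_probs)) {
    p <- cfg$consumption_probs[[lev]]
    expect_lt(abs(shares[[lev]] - p), 3 * se(p))
  }
  expect_true(all(u$adoption_month %in% month_seq("2019-04", "2019-09")))
})

test_that("null model reduces to user + month fixed effects exactly", {
  cfg <- sim_config(n_users = 20L, true_dynamic_effects = numeric(),
                    noise_sd = 0, zero_inflation = 0, seed = 3L)
  truth <- generate_outcomes(generate_users(cfg), cfg)
  # eta minus the month effect must be constant within user
  resid <- truth$eta - cfg$month_fe[truth$month_pos]
  dev <- tapply(resid, truth$user_id, function(x) max(x) - min(x))
  expect_lt(max(dev), 1e-12)
})

test_that("injected effects appear as the used/non-used log-outcome gap", {
  # sample-mean contrast oracle at r = 2, homogeneous-effect design
  cfg <- recovery_config(n_users = 30000L, p_used = 0.5,
                         effects = c(`1` = -0.058, `2` = -0.131,
                                     `3` = -0.184), seed = 11L)
  truth <- generate_outcomes(generate_users(cfg), cfg)
  at_r2 <- truth[truth$event_time == 2L, ]
  gap <- mean(at_r2$log_outcome[at_r2$used_flag]) -
    mean(at_r2$log_outcome[!at_r2$used_flag])
  expect_lt(abs(gap - (-0.131)), 0.03)
})

test_that("reference-period effects and invalid windows are rejected", {
  expect_error(sim_config(true_dynamic_effects = c(`0` = -0.1, `1` = -0.2)),
               "r = 0")
  expect_error(sim_config(adoption_window = c("2018-04", "2019-09")),
               "month grid")
  expect_error(sim_config(p_used = 1.2), "probability")
  expect_error(sim_config(pretrend_effects = c(`2` = -0.1)), "negative")
})

test_that("epoch streams realize target hours under the 2-epoch rule", {
  cfg <- sim_config(n_users = 1L, run_length_mix = c(2L, 3L), seed = 4L)
  truth <- data.table::data.table(
    user_id = 1L, month = "2019-05", visit_hours = c(5L),
    occupation_tag = "none")
  st <- generate_epoch_streams(truth, cfg)
  runs <- find_runs(st)
  expect_true(all(runs$len >= 2L))
  expect_identical(sum(runs$len), 5L)

  # zero target emits nothing
  truth0 <- data.table::data.table(user_id = 1L, month = "2019-05",
                                   visit_hours = 0L, occupation_tag = "none")
  expect_identical(nrow(generate_epoch_streams(truth0, cfg)), 0L)

  # singleton-only mix: raw hours match but nothing qualifies
  cfg1 <- sim_config(n_users = 1L, run_length_mix = 1L, seed = 4L)
  st1 <- generate_epoch_streams(truth, cfg1)
  runs1 <- find_runs(st1)
  expect_identical(nrow(st1), 5L)
  expect_true(all(runs1$len == 1L))
  expect_identical(sum(runs1$len[runs1$len >= 2L]), 0L)
})

test_that("run decomposition always produces qualifying runs summing to target", {
  set.seed(99)
  for (H in c(2:12, 20L, 40L, 173L)) {
    lens <- mhdid:::decompose_runs(H, 2:6)
    expect_true(all(lens >= 2L))
    expect_identical(sum(lens), as.integer(H))
  }
  expect_error(mhdid:::decompose_runs(1L, 2:6), "run of >= 2")
})

test_that("over-capacity targets are rejected", {
  cfg <- sim_config(n_users = 1L, seed = 5L)
  truth <- data.table::data.table(user_id = 1L, month = "2019-02",
                                  visit_hours = 24L * 28L + 1L,
                                  occupation_tag = "none")
  expect_error(generate_epoch_streams(truth, cfg), "exceed hours in month")
})

test_that("physicians and drivers get extra hospital epochs injected", {
  cfg <- sim_config(n_users = 1L, seed = 6L)
  truth <- data.table::data.table(user_id = 1:2, month = "2019-05",
                                  visit_hours = 0L,
                                  occupation_tag = c("none", "physician"))
  st <- generate_epoch_streams(truth, cfg)
  expect_identical(nrow(st[st$user_id == 1L, ]), 0L)
  expect_identical(nrow(st[st$user_id == 2L, ]), cfg$excluded_extra_hours)
})
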