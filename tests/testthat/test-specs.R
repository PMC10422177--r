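test_that("the dynamic DD spec has the reported terms plus end caps", {
  spec <- build_dd(cohort_window())
  expect_identical(spec$regressors,
                   c("ev_pre", "ev_m2", "ev_m1", "ev_p1", "ev_p2", "ev_p3",
                     "ev_post"))
  expect_identical(spec$fe, c("user_id", "month"))
  expect_identical(spec$cluster, "user_id")
  expect_identical(length(build_dd(include_caps = FALSE)$regressors), 5L)
})

test_that("the DDD spec interacts every event term with the used flag", {
  spec <- build_ddd(cohort_window())
  expect_identical(sum(startsWith(spec$regressors, "used_x_")), 7L)
  expect_identical(spec$fe, c("user_id", "month:used_flag"))
})

test_that("model specs round-trip through YAML", {
  spec <- build_ddd(cohort_window())
  expect_identical(spec_from_yaml(spec_to_yaml(spec)), spec)
  path <- tempfile(fileext = ".yaml")
  spec_to_yaml(spec, path)
  expect_identical(spec_from_yaml(path), spec)
})

test_that("moderation horizons shift and truncate the outcome correctly", {
  months <- month_seq("2019-01", "2019-12")
  cfg <- sim_config(n_users = 30L, seed = 9L)
  truth <- generate_outcomes(generate_users(cfg), cfg)
  truth$app_count_centered <- truth$installed_app_count -
    mean(truth$installed_app_count[!duplicated(truth$user_id)])
  mp0 <- moderation_panel(truth, 0L, months)
  expect_identical(mp0$y_lead, mp0$log_outcome)
  mp3 <- moderation_panel(truth, 3L, months)
  expect_identical(nrow(mp3), 30L * 9L)  # 12-month window, horizon 3
  expect_true(all(table(mp3$user_id) == 9L))
  # shifted outcome really is the value three months later
  u1 <- mp3[mp3$user_id == truth$user_id[1] & mp3$month == "2019-02", ]
  y5 <- truth[truth$user_id == truth$user_id[1] & truth$month == "2019-05", ]
  expect_identical(u1$y_lead, y5$log_outcome)
  expect_error(moderation_panel(truth, 12L, months), "exceeds")
})

test_that("moderation specs use the stated references and controls", {
  m2 <- build_moderation(moderation_spec("consumption_level"))
  expect_true(all(c("post_x_cons_medium", "post_x_cons_high") %in%
                    m2$regressors))
  expect_false("cons_low" %in% m2$regressors)      # low is the reference
  m3 <- build_moderation(moderation_spec("city_tier"))
  expect_true(all(paste0("post_x_tier_", 1:3) %in% m3$regressors))
  expect_false("tier_4" %in% m3$regressors)        # tier 4 is the reference
  expect_identical(m2$fe, "month")                 # observables mode
  mfe <- build_moderation(moderation_spec("app_count",
                                          controls_mode = "user_fe"))
  expect_identical(mfe$fe, c("user_id", "month"))
  expect_false("cons_medium" %in% mfe$regressors)  # absorbed by user FE
})

test_that("categorical moderator indicators plus reference partition each row", {
  months <- month_seq("2019-01", "2019-12")
  cfg <- sim_config(n_users = 40L, seed = 10L)
  truth <- generate_outcomes(generate_users(cfg), cfg)
  truth$app_count_centered <- 0
  mp <- moderation_panel(truth, 3L, months)
  cons_ref <- 1L - mp$cons_medium - mp$cons_high
  expect_true(all(cons_ref %in% c(0L, 1L)))
  expect_true(all(mp$cons_medium + mp$cons_high + cons_ref == 1L))
  tier_sum <- mp$tier_1 + mp$tier_2 + mp$tier_3 + (mp$city_tier == 4L)
  expect_true(all(tier_sum == 1L))
})

test_that("pretrend report: zero leads give a zero Wald statistic", {
  fit <- structure(list(
    coefficients = c(ev_m2 = 0, ev_m1 = 0, ev_p1 = -0.05),
    vcov = diag(c(1e-4, 1e-4, 1e-4)) |>
      (\(v) {dimnames(v) <- rep(list(c("ev_m2", "ev_m1", "ev_p1")), 2); v})(),
    se = c(ev_m2 = 0.01, ev_m1 = 0.01, ev_p1 = 0.01),
    ci_low = c(-0.02, -0.02, -0.07), ci_high = c(0.02, 0.02, -0.03),
    p_value = c(1, 1, 0)), class = "fe_fit")
  fit$spec <- model_spec("y", names(fit$coefficients), fe = "user_id")
  rep0 <- pretrend_report(fit, cohort_window())
  expect_identical(rep0$wald, 0)
  expect_match(rep0$verdict, "no pre-trend")
  expect_gte(rep0$wald, 0)
})

test_that("pretrend report flags an injected lead effect on real fits", {
  window <- cohort_window()
  cfg <- recovery_config(n_users = 8000L, pretrend = c(`-1` = -0.05),
                         seed = 12L)
  pan <- event_time_dummies(generate_outcomes(generate_users(cfg), cfg),
                            window)
  fit <- fe_fit(build_dd(window), pan)
  rep1 <- pretrend_report(fit, window)
  expect_lt(rep1$p_value, 0.05)
  expect_match(rep1$verdict, "pre-trend detected")
  no_leads <- fit
  no_leads$coefficients <- fit$coefficients[c("ev_p1", "ev_p2")]
  expect_error(pretrend_report(no_leads, window), "no lead")
})
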