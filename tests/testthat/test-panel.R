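months12 <- month_seq("2019-01", "2019-12")

make_users <- function(n, adoption = rep(month_seq("2019-04", "2019-09"),
                                         length.out = n)) {
  data.table::data.table(
    user_id = seq_len(n), adoption_month = adoption,
    used_flag = rep(c(TRUE, FALSE), length.out = n),
    occupation_tag = "none",
    consumption_level = factor(rep(c("low", "medium", "high"),
                                   length.out = n),
                               levels = c("low", "medium", "high")),
    city_tier = rep(1:4, length.out = n),
    installed_app_count = rep(c(10L, 40L), length.out = n),
    multi_category_adopter = FALSE)
}

make_visits <- function(users, hours = 3L) {
  data.table::CJ(user_id = users$user_id, month = months12)[
    , `:=`(visit_hours = hours, visit_days = 1L)][]
}

test_that("event time is the signed month difference from adoption", {
  users <- make_users(2L, adoption = c("2019-05", "2019-04"))
  pan <- build_panel(make_visits(users), users, cohort_window(), months12)
  expect_identical(pan[pan$user_id == 1L & pan$month == "2019-08", ]$event_time, 3L)
  expect_identical(pan[pan$user_id == 2L & pan$month == "2019-01", ]$event_time, -3L)
  expect_identical(pan[pan$user_id == 1L & pan$month == "2019-05", ]$post_flag, 0L)
  expect_identical(pan[pan$user_id == 1L & pan$month == "2019-06", ]$post_flag, 1L)
})

test_that("panel has one row per retained user and month", {
  users <- make_users(10L)
  pan <- build_panel(make_visits(users), users, cohort_window(), months12)
  expect_identical(nrow(pan), 120L)
  expect_identical(pan$log_outcome, rep(log1p(3), 120L))
})

test_that("users adopting outside the cohort window are dropped", {
  users <- make_users(6L)
  short <- cohort_window("2019-05", "2019-08")
  pan_full <- build_panel(make_visits(users), users, cohort_window(), months12)
  pan_short <- build_panel(make_visits(users), users, short, months12)
  expect_true(all(unique(pan_short$user_id) %in% unique(pan_full$user_id)))
  expect_lt(data.table::uniqueN(pan_short$user_id),
            data.table::uniqueN(pan_full$user_id))
  expect_true(all(pan_short$adoption_month %in%
                    month_seq("2019-05", "2019-08")))
})

test_that("missing adoption months and out-of-window months error", {
  users <- make_users(2L)
  users$adoption_month[1] <- NA_character_
  expect_error(build_panel(make_visits(make_users(2L)), users,
                           cohort_window(), months12), "adoption month")
  bad_visits <- make_visits(make_users(2L))
  bad_visits$month[1] <- "2020-01"
  expect_error(build_panel(bad_visits, make_users(2L), cohort_window(),
                           months12), "outside the data window")
})

test_that("event-time indicators partition every row exactly once", {
  users <- make_users(12L)
  window <- cohort_window()
  pan <- event_time_dummies(
    build_panel(make_visits(users), users, window, months12), window)
  terms <- attr(pan, "event_terms")
  expect_identical(terms, c("ev_pre", "ev_m2", "ev_m1", "ev_p1", "ev_p2",
                            "ev_p3", "ev_post"))
  ind <- as.matrix(pan[, terms, with = FALSE])
  active <- rowSums(ind)
  # reference rows (r = 0) activate nothing; all others exactly one
  expect_identical(unname(active[pan$event_time == 0L]),
                   rep(0, sum(pan$event_time == 0L)))
  expect_identical(unname(active[pan$event_time != 0L]),
                   rep(1, sum(pan$event_time != 0L)))
  # spot checks
  expect_true(all(pan[pan$event_time == 2L, ]$ev_p2 == 1L))
  expect_true(all(pan[pan$event_time == -7L, ]$ev_pre == 1L))
  expect_true(all(pan[pan$event_time == 5L, ]$ev_post == 1L))
})

test_that("DDD interactions are zero for never-used rows and match dummies for used", {
  users <- make_users(8L)
  window <- cohort_window()
  pan <- add_ddd_terms(event_time_dummies(
    build_panel(make_visits(users), users, window, months12), window))
  expect_true(all(
    as.matrix(pan[!pan$used_flag, attr(pan, "ddd_terms"), with = FALSE]) == 0L))
  used_r2 <- pan[pan$used_flag & pan$event_time == 2L, ]
  expect_true(all(used_r2$used_x_ev_p2 == 1L))
  expect_true(all(
    used_r2[, setdiff(attr(pan, "ddd_terms"), "used_x_ev_p2"),
            with = FALSE] == 0L))
})

test_that("DDD terms require both subgroups", {
  users <- make_users(4L)
  users$used_flag <- TRUE
  window <- cohort_window()
  pan <- event_time_dummies(
    build_panel(make_visits(users), users, window, months12), window)
  expect_error(add_ddd_terms(pan), "nonempty")
})
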