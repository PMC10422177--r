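# a small seeded panel with user/month structure and arbitrary regressors
small_panel <- function(n_users = 6L, n_months = 5L, seed = 1L) {
  set.seed(seed)
  pan <- data.table::CJ(user_id = seq_len(n_users),
                        month = sprintf("2019-%02d", seq_len(n_months)))
  pan$used_flag <- pan$user_id <= n_users %/% 2L
  pan$x1 <- rnorm(nrow(pan))
  pan$x2 <- rnorm(nrow(pan))
  gamma <- rnorm(n_users)[pan$user_id]
  delta <- rnorm(n_months)[as.integer(substr(pan$month, 6, 7))]
  pan$y <- 1.5 * pan$x1 - 0.5 * pan$x2 + gamma + delta + rnorm(nrow(pan), 0, 0.3)
  pan
}

test_that("single-dimension demeaning is exact within-group centering in one sweep", {
  pan <- small_panel()
  dm <- fe_demean(pan, c("y", "x1"), "user_id")
  expect_identical(dm$sweeps, 1L)
  cell_means <- rowsum(dm$M, pan$user_id) / tabulate(pan$user_id)
  expect_lt(max(abs(cell_means)), 1e-12)
  # matches the closed form
  expect_equal(dm$M[, "x1"], pan$x1 - ave(pan$x1, pan$user_id), ignore_attr = TRUE)
})

test_that("balanced two-way demeaning equals the closed form", {
  # 4 users x 3 months, balanced
  pan <- small_panel(4L, 3L, seed = 2L)
  dm <- fe_demean(pan, "y", c("user_id", "month"))
  closed <- pan$y - ave(pan$y, pan$user_id) - ave(pan$y, pan$month) + mean(pan$y)
  expect_equal(as.numeric(dm$M[, 1L]), closed, tolerance = 1e-10)
})

test_that("columns constant within cells are absorbed and flagged", {
  pan <- small_panel()
  pan$const_u <- as.numeric(pan$user_id %% 2L)  # function of user only
  dm <- fe_demean(pan, "const_u", "user_id")
  expect_lt(max(abs(dm$M)), 1e-12)
  spec <- model_spec("y", c("x1", "const_u"), fe = c("user_id", "month"))
  expect_error(fe_fit(spec, pan), "absorbed by the fixed effects")
})

test_that("a pure fixed-effects outcome fits to zero coefficients", {
  pan <- small_panel()
  gamma <- rnorm(6L)[pan$user_id]
  delta <- rnorm(5L)[as.integer(substr(pan$month, 6, 7))]
  pan$y0 <- gamma + delta
  spec <- model_spec("y0", c("x1", "x2"), fe = c("user_id", "month"),
                     demean_tol = 1e-12)
  fit <- fe_fit(spec, pan)
  expect_lt(max(abs(fit$coefficients)), 1e-8)
})

test_that("demeaned OLS matches dummy-variable OLS and its cluster sandwich", {
  pan <- small_panel(6L, 5L, seed = 3L)
  spec <- model_spec("y", c("x1", "x2"), fe = c("user_id", "month"),
                     demean_tol = 1e-12)
  fit <- fe_fit(spec, pan)
  orc <- fit_dummy_ols(spec, pan)
  expect_equal(fit$coefficients, orc$coef, tolerance = 1e-8)
  expect_equal(fit$se, orc$se, tolerance = 1e-8)
})

test_that("the hand-rolled sandwich agrees with sandwich::vcovCL", {
  skip_if_not_installed("sandwich")
  pan <- small_panel(8L, 6L, seed = 4L)
  spec <- model_spec("y", c("x1", "x2"), fe = c("user_id", "month"),
                     demean_tol = 1e-12, dof = "conventional")
  fit <- fe_fit(spec, pan)
  lmfit <- stats::lm(y ~ x1 + x2 + factor(user_id) + factor(month), data = pan)
  V <- sandwich::vcovCL(lmfit, cluster = pan$user_id, type = "HC1")
  expect_equal(unname(fit$se), unname(sqrt(diag(V))[c("x1", "x2")]),
               tolerance = 1e-8)
})

test_that("degenerate designs raise informative errors", {
  pan <- small_panel()
  pan$x1_dup <- pan$x1
  expect_error(fe_fit(model_spec("y", c("x1", "x1_dup"), fe = "user_id"), pan),
               "collinear")
  one_cluster <- small_panel()
  one_cluster$user_id <- 1L
  expect_error(fe_fit(model_spec("y", "x1", fe = "month",
                                 cluster = "user_id"), one_cluster),
               "2 clusters")
  # singleton-only FE dimension absorbs everything
  pan$row_id <- seq_len(nrow(pan))
  expect_error(fe_fit(model_spec("y", "x1", fe = "row_id"), pan), "singleton")
  expect_error(fe_fit(model_spec("y", "nope", fe = "user_id"), pan),
               "lacks column")
})

test_that("absorbing a dimension equals including its dummies explicitly", {
  # Frisch-Waugh consistency
  pan <- small_panel(5L, 4L, seed = 5L)
  months <- sort(unique(pan$month))
  for (m in months[-1L]) {
    pan[[paste0("m_", m)]] <- as.numeric(pan$month == m)
  }
  dums <- paste0("m_", months[-1L])
  fit_absorbed <- fe_fit(model_spec("y", c("x1", "x2"),
                                    fe = c("user_id", "month"),
                                    demean_tol = 1e-12), pan)
  fit_dummies <- fe_fit(model_spec("y", c("x1", "x2", dums), fe = "user_id"),
                        pan)
  expect_equal(fit_absorbed$coefficients[c("x1", "x2")],
               fit_dummies$coefficients[c("x1", "x2")], tolerance = 1e-8)
})

test_that("fit diagnostics are coherent", {
  pan <- small_panel(10L, 6L, seed = 6L)
  fit <- fe_fit(model_spec("y", c("x1", "x2"), fe = c("user_id", "month")),
                pan)
  expect_identical(fit$n_obs, 60L)
  expect_identical(fit$n_clusters, 10L)
  expect_lte(fit$n_clusters, fit$n_obs)
  expect_equal(fit$k_absorbed, 10L + 6L - 1L)
  V <- fit$vcov
  expect_equal(V, t(V))
  expect_true(all(eigen(V, only.values = TRUE)$values > -1e-12))
  expect_equal(unname(fit$ci_low), unname(fit$coefficients - 1.96 * fit$se))
  expect_true(fit$r_squared <= 1 && fit$r_squared_within <= 1)
})
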