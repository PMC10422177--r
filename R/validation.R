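# Monte-Carlo validation studies: parameter recovery for the DDD estimator,
# null calibration, immunity of the DDD contrast to adoption-timed shocks
# shared by both subgroups, pre-trend test power, moderation-ordering
# recovery, visit-rule checks and the stream round trip. These run the same
# exported machinery end to end on generated data with known truth.

#' Estimand-preserving recovery design
#'
#' A simulation configuration for estimator-validation studies: no zero
#' inflation, homogeneous effects (moderator multipliers off), no occupation
#' tags, and a high baseline so that the integer-hour realization of the
#' latent log outcome is essentially lossless. Under this design the
#' population value of the DDD coefficient equals the injected effect, which
#' is what a parameter-recovery study must hold fixed.
#'
#' @param n_users Cohort size.
#' @param p_used Probability an adopter is in the used subgroup.
#' @param effects Injected dynamic effects (default: the three-month ramp
#'   -0.058, -0.131, -0.184).
#' @param pretrend Injected pre-adoption effects applied to all adopters.
#' @param seed Root seed.
#' @return A [sim_config()].
#' @export
recovery_config <- function(n_users = 5000L, p_used = 0.3,
                            effects = c(`1` = -0.058, `2` = -0.131,
                                        `3` = -0.184),
                            pretrend = numeric(), seed = 1L) {
  sim_config(n_users = n_users, p_used = p_used,
             true_dynamic_effects = effects,
             pretrend_effects = pretrend,
             baseline_log_hours = 3.5, user_fe_sd = 0.5, noise_sd = 0.4,
             zero_inflation = 0,
             moderator_effect_map = moderator_map_off(),
             exclusion_rates = c(physician = 0, driver = 0),
             multi_category_rate = 0,
             seed = seed)
}

# per-replication seed below 2^31, derived from the study seed
rep_seed <- function(seed, study, rep) stage_seed(seed, paste0(study, rep))

# event dummies + DDD interactions straight from the latent truth panel
ddd_panel_from_truth <- function(truth, window) {
  add_ddd_terms(event_time_dummies(truth, window))
}

#' DDD parameter-recovery study
#'
#' Repeatedly generates a cohort under the recovery design, fits the DDD
#' specification, and compares the estimated `used_x_ev_p*` coefficients with
#' the injected truth: Monte-Carlo bias and 95% CI coverage per event time.
#'
#' @param n_reps Replications.
#' @param n_users,p_used,effects Passed to [recovery_config()].
#' @param seed Study seed.
#' @param demean_tol Demeaning tolerance for the fits.
#' @return List with `draws` (one row per replication x event time) and
#'   `summary` (bias, coverage and mean SE per event time).
#' @export
study_ddd_recovery <- function(n_reps = 200L, n_users = 5000L, p_used = 0.3,
                               effects = c(`1` = -0.058, `2` = -0.131,
                                           `3` = -0.184),
                               seed = 1L, demean_tol = 1e-8) {
  window <- cohort_window()
  spec <- build_ddd(window)
  spec$demean_tol <- demean_tol
  rs <- as.integer(names(effects))
  terms <- paste0("used_x_", event_term_name(rs))
  draws <- vector("list", n_reps)
  for (i in seq_len(n_reps)) {
    cfg <- recovery_config(n_users = n_users, p_used = p_used,
                           effects = effects,
                           seed = rep_seed(seed, "rec", i))
    pan <- ddd_panel_from_truth(generate_outcomes(generate_users(cfg), cfg),
                                window)
    fit <- fe_fit(spec, pan)
    draws[[i]] <- data.table::data.table(
      rep = i, r = rs,
      estimate = unname(fit$coefficients[terms]),
      se = unname(fit$se[terms]),
      truth = unname(effects),
      covered = unname(fit$ci_low[terms] <= effects &
                         effects <= fit$ci_high[terms])
    )
  }
  draws <- data.table::rbindlist(draws)
  summary <- draws[, .(bias = mean(estimate - truth),
                       coverage = mean(covered),
                       mean_se = mean(se)), by = r]
  list(draws = draws, summary = summary)
}

#' Null-calibration study
#'
#' Same design with all effects zero: the per-coefficient rejection rate of
#' the nominal 5% test should be 5% up to binomial noise.
#'
#' @inheritParams study_ddd_recovery
#' @return List with `rates` (rejection rate per DDD term) and `n_reps`.
#' @export
study_null_calibration <- function(n_reps = 500L, n_users = 5000L,
                                   p_used = 0.3, seed = 2L,
                                   demean_tol = 1e-8) {
  window <- cohort_window()
  spec <- build_ddd(window)
  spec$demean_tol <- demean_tol
  terms <- paste0("used_x_", window_terms(window, include_caps = FALSE))
  rej <- matrix(NA, n_reps, length(terms),
                dimnames = list(NULL, terms))
  for (i in seq_len(n_reps)) {
    cfg <- recovery_config(n_users = n_users, p_used = p_used,
                           effects = numeric(),
                           seed = rep_seed(seed, "null", i))
    pan <- ddd_panel_from_truth(generate_outcomes(generate_users(cfg), cfg),
                                window)
    fit <- fe_fit(spec, pan)
    rej[i, ] <- fit$p_value[terms] < 0.05
  }
  list(rates = colMeans(rej), n_reps = n_reps)
}

#' DDD immunity to subgroup-shared adoption-timed shocks
#'
#' Adds a shock at one post-adoption event time to the outcomes of *all*
#' adopters (used and never-used alike) and refits. Such a shock coincides
#' with adoption timing but does not differ between the subgroups, so it moves
#' the DD event-study coefficient while leaving every DDD interaction
#' untouched: the base event-time indicators absorb it.
#'
#' @param n_users Cohort size.
#' @param shock Log-scale shock size (default 0.1).
#' @param shock_r Event time receiving the shock (default 2).
#' @param seed Seed.
#' @return List with `ddd_max_shift` (largest absolute change over the DDD
#'   terms), `dd_shift` (change of the DD coefficient at `shock_r`) and the
#'   shock used.
#' @export
study_ddd_immunity <- function(n_users = 2000L, shock = 0.1, shock_r = 2L,
                               seed = 3L) {
  window <- cohort_window()
  cfg <- recovery_config(n_users = n_users, seed = stage_seed(seed, "imm"))
  pan <- ddd_panel_from_truth(generate_outcomes(generate_users(cfg), cfg),
                              window)
  dd <- build_dd(window)
  ddd <- build_ddd(window)
  fit_dd <- fe_fit(dd, pan)
  fit_ddd <- fe_fit(ddd, pan)
  pan2 <- data.table::copy(pan)
  pan2[, log_outcome := log_outcome + shock * (event_time == shock_r)]
  fit_dd2 <- fe_fit(dd, pan2)
  fit_ddd2 <- fe_fit(ddd, pan2)
  dterms <- attr(pan, "ddd_terms")
  list(
    ddd_max_shift = max(abs(fit_ddd2$coefficients[dterms] -
                              fit_ddd$coefficients[dterms])),
    dd_shift = unname(fit_dd2$coefficients[event_term_name(shock_r)] -
                        fit_dd$coefficients[event_term_name(shock_r)]),
    shock = shock
  )
}

#' Pre-trend test power study
#'
#' Generates cohorts with an injected lead effect applied to all adopters and
#' reports how often the joint Wald test on the DD lead coefficients flags it
#' at the 5% level.
#'
#' @param n_reps Replications.
#' @param n_users Cohort size (default 20000).
#' @param lead_effect Named pre-trend map, e.g. `c("-1" = -0.02)`; empty for
#'   the null arm.
#' @param seed Study seed.
#' @return Fraction of replications with a pre-trend verdict (p < 0.05).
#' @export
study_pretrend_power <- function(n_reps = 50L, n_users = 20000L,
                                 lead_effect = c(`-1` = -0.02), seed = 4L) {
  window <- cohort_window()
  spec <- build_dd(window)
  flagged <- logical(n_reps)
  for (i in seq_len(n_reps)) {
    cfg <- recovery_config(n_users = n_users, pretrend = lead_effect,
                           seed = rep_seed(seed, "pre", i))
    pan <- event_time_dummies(generate_outcomes(generate_users(cfg), cfg),
                              window)
    rep_ <- pretrend_report(fe_fit(spec, pan), window)
    flagged[i] <- rep_$p_value < 0.05
  }
  mean(flagged)
}

#' Moderation-ordering recovery study
#'
#' Injects consumption-level effect multipliers ordered low < medium < high
#' into a cohort of active users and checks, per replication, that the
#' estimated Post x High interaction is more negative than Post x Medium.
#'
#' @param n_reps Replications.
#' @param n_users Cohort size.
#' @param multipliers Ordered consumption multipliers.
#' @param seed Study seed.
#' @return Fraction of replications with the correct ordering.
#' @export
study_moderation_ordering <- function(n_reps = 100L, n_users = 3000L,
                                      multipliers = c(low = 0.5, medium = 1,
                                                      high = 1.5),
                                      seed = 5L) {
  map <- moderator_map_off()
  map$consumption_level <- multipliers
  mspec <- moderation_spec("consumption_level")
  spec <- build_moderation(mspec)
  ok <- logical(n_reps)
  for (i in seq_len(n_reps)) {
    cfg <- sim_config(
      n_users = n_users, p_used = 1,
      true_dynamic_effects = default_dynamic_effects(),
      baseline_log_hours = 3.5, user_fe_sd = 0.5, noise_sd = 0.4,
      zero_inflation = 0, moderator_effect_map = map,
      exclusion_rates = c(physician = 0, driver = 0),
      multi_category_rate = 0, seed = rep_seed(seed, "mod", i))
    truth <- generate_outcomes(generate_users(cfg), cfg)
    truth[, app_count_centered := installed_app_count -
            mean(installed_app_count[!duplicated(user_id)])]
    mp <- moderation_panel(truth, mspec$horizon, cfg$months)
    fit <- fe_fit(spec, mp)
    ok[i] <- fit$coefficients["post_x_cons_high"] <
      fit$coefficients["post_x_cons_medium"]
  }
  mean(ok)
}

# Independent brute-force scan: total hours in maximal runs of length >= k,
# given the sorted at-hospital hour indices of one user-month. A plain loop,
# deliberately unrelated to the vectorized run finder.
brute_force_qualifying_hours <- function(h, k) {
  if (length(h) == 0L) return(0L)
  h <- sort(h)
  tot <- 0L
  run <- 1L
  for (i in seq_along(h)[-1L]) {
    if (h[i] == h[i - 1L] + 1L) {
      run <- run + 1L
    } else {
      if (run >= k) tot <- tot + run
      run <- 1L
    }
  }
  if (run >= k) tot <- tot + run
  tot
}

#' Visit-rule check on random streams
#'
#' Generates random sparse epoch streams spanning a two-month window, computes
#' monthly qualifying hours under k = 1..4 with [monthly_visits()], and
#' verifies (a) agreement with an independent brute-force scan and (b)
#' monotonicity in the threshold, with k = 1 equal to the raw hour count.
#'
#' @param n_streams Number of random streams.
#' @param seed Seed.
#' @return List with `oracle_mismatches` and `monotonicity_violations`
#'   (both should be 0) and `n_streams`.
#' @export
check_visit_rules <- function(n_streams = 1000L, seed = 6L) {
  set.seed(stage_seed(seed, "rules"))
  months <- c("2019-01", "2019-02")
  users <- data.table::data.table(user_id = 1L, occupation_tag = "none")
  h0 <- month_start("2019-01")
  n_hours <- 24L * (31L + 28L)
  mism <- 0L
  viol <- 0L
  for (s in seq_len(n_streams)) {
    n_on <- sample(0:60, 1L)
    hrs <- sort(sample(seq_len(n_hours) - 1L, n_on))
    stream <- data.table::data.table(
      user_id = 1L, hour_ts = h0 + hrs * 3600, at_hospital = TRUE)
    got <- sapply(1:4, function(k) {
      mv <- monthly_visits(stream, users, visit_rule(k), months)
      stats::setNames(mv$visit_hours, mv$month)
    })
    # brute force per month (runs split at the boundary)
    jan <- hrs[hrs < 24L * 31L]
    feb <- hrs[hrs >= 24L * 31L]
    want <- sapply(1:4, function(k) {
      c(`2019-01` = brute_force_qualifying_hours(jan, k),
        `2019-02` = brute_force_qualifying_hours(feb, k))
    })
    if (!isTRUE(all.equal(unname(got), unname(want)))) mism <- mism + 1L
    if (any(got[, 4L] > got[, 3L] | got[, 3L] > got[, 2L] |
              got[, 2L] > got[, 1L])) viol <- viol + 1L
    if (any(got[, 1L] != c(length(jan), length(feb)))) viol <- viol + 1L
  }
  list(oracle_mismatches = mism, monotonicity_violations = viol,
       n_streams = n_streams)
}

#' Stream round trip
#'
#' Simulates a cohort whose epoch streams use only runs of >= 2 epochs and
#' verifies that the monthly hours reconstructed by the visits module equal
#' the latent truth exactly for every retained user-month.
#'
#' @param n_users Cohort size.
#' @param seed Seed.
#' @return List with `max_abs_error` (should be 0) and the number of
#'   user-months compared.
#' @export
check_roundtrip <- function(n_users = 200L, seed = 7L) {
  cfg <- sim_config(n_users = n_users, zero_inflation = 0.5,
                    run_length_mix = 2:6, seed = stage_seed(seed, "rt"))
  sim <- simulate_cohort(cfg, streams = TRUE)
  mv <- monthly_visits(sim$streams, sim$users, visit_rule(2), cfg$months)
  cmp <- mv[sim$truth, on = c("user_id", "month"), nomatch = NULL]
  list(max_abs_error = max(abs(cmp$visit_hours - cmp$i.visit_hours)),
       n_compared = nrow(cmp))
}

#' Oracle-equivalence study
#'
#' On small randomized panels (at most 50 users x 12 months) fits the DD, DDD
#' and moderation specifications twice: with the alternating-projection engine
#' and with explicit dummy-variable OLS plus a hand-assembled cluster
#' sandwich. Reports the largest absolute discrepancy in coefficients and SEs.
#'
#' @param n_panels Number of randomized panels.
#' @param seed Seed.
#' @param demean_tol Demeaning tolerance used for the engine fits (tight, so
#'   the comparison isolates algorithmic agreement).
#' @return List with `max_coef_diff`, `max_se_diff` and `n_panels`.
#' @export
study_oracle_equivalence <- function(n_panels = 25L, seed = 8L,
                                     demean_tol = 1e-12) {
  set.seed(stage_seed(seed, "oracle"))
  window <- cohort_window()
  max_cd <- 0
  max_sd <- 0
  for (i in seq_len(n_panels)) {
    n_users <- sample(20:50, 1L)
    kind <- c("dd", "ddd", "mod")[(i - 1L) %% 3L + 1L]
    cfg <- recovery_config(
      n_users = n_users, p_used = 0.5,
      effects = c(`1` = stats::runif(1, -0.3, 0), `2` = stats::runif(1, -0.3, 0),
                  `3` = stats::runif(1, -0.3, 0)),
      seed = rep_seed(seed, "orc", i))
    truth <- generate_outcomes(generate_users(cfg), cfg)
    if (kind == "mod") {
      truth[, app_count_centered := installed_app_count -
              mean(installed_app_count[!duplicated(user_id)])]
      pan <- moderation_panel(truth, 3L, cfg$months)
      spec <- build_moderation(moderation_spec("consumption_level"))
    } else {
      pan <- ddd_panel_from_truth(truth, window)
      spec <- if (kind == "dd") build_dd(window) else build_ddd(window)
    }
    spec$demean_tol <- demean_tol
    fit <- fe_fit(spec, pan)
    orc <- fit_dummy_ols(spec, pan)
    max_cd <- max(max_cd, max(abs(fit$coefficients - orc$coef)))
    max_sd <- max(max_sd, max(abs(fit$se - orc$se)))
  }
  list(max_coef_diff = max_cd, max_se_diff = max_sd, n_panels = n_panels)
}
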