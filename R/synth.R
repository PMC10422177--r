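# Synthetic cohort generator: staggered app adoption, a used vs
# installed-never-used adopter split, zero-inflated monthly hospital hours with
# user and calendar-month heterogeneity, and dynamic post-adoption effects on
# the log scale that apply only to the used subgroup. Ground truth is known, so
# every downstream stage (visit construction, panel, estimators) is testable.

#' Default injected dynamic treatment effects
#'
#' A three-month ramp on the log(1 + hours) scale followed by a plateau:
#' reductions of 5.8%, 13.1% and 18.4% one, two and three months after
#' adoption, held at the three-month level thereafter. Event time 0 (the
#' adoption month) is the reference period and never carries an effect.
#'
#' @param r_max Largest post-adoption event time to carry the plateau.
#' @return Named numeric vector mapping event time to log-scale effect.
#' @export
default_dynamic_effects <- function(r_max = 8L) {
  ramp <- c(`1` = -0.058, `2` = -0.131, `3` = -0.184)
  if (r_max <= 3L) return(ramp[as.integer(names(ramp)) <= r_max])
  plateau <- rep(-0.184, r_max - 3L)
  names(plateau) <- as.character(4:r_max)
  c(ramp, plateau)
}

#' Default moderator effect multipliers
#'
#' Multipliers applied to the injected dynamic effects per moderator level.
#' Higher consumption and higher-tier cities amplify the reduction; in
#' low-tier cities the multiplier turns slightly negative, flipping the sign
#' of the effect. Digital literacy (installed-app count) enters through a
#' slope per standard deviation of the mean-centred app count.
#'
#' @return A list with elements `consumption_level`, `city_tier`,
#'   `app_count_per_sd`.
#' @export
default_moderator_map <- function() {
  list(
    consumption_level = c(low = 0.5, medium = 1.0, high = 1.5),
    city_tier = c(`1` = 1.5, `2` = 1.4, `3` = -0.1, `4` = -0.2),
    app_count_per_sd = 0.2
  )
}

#' Moderator multipliers switched off
#'
#' All categorical multipliers 1 and a zero app-count slope, so the injected
#' dynamic effects are homogeneous across users. Used by the parameter-recovery
#' studies, where the estimand must equal the injected effect exactly.
#'
#' @return A list in the same shape as [default_moderator_map()].
#' @export
moderator_map_off <- function() {
  list(
    consumption_level = c(low = 1, medium = 1, high = 1),
    city_tier = c(`1` = 1, `2` = 1, `3` = 1, `4` = 1),
    app_count_per_sd = 0
  )
}

#' Simulation configuration
#'
#' Defines the study conditions the generator emulates: a Jan-Dec calendar
#' window with adoption concentrated Apr-Sep, a small used subgroup among
#' adopters, zero-inflated monthly hospital hours, and dynamic log-scale
#' treatment effects confined to the used subgroup.
#'
#' @param n_users Number of adopters to simulate.
#' @param months Ordered month grid (`"YYYY-MM"`), default 2019-01..2019-12.
#' @param adoption_window First and last admissible adoption month.
#' @param p_used Probability an adopter ever uses the app (default 0.08,
#'   matching a used share of 21,444 / 267,651 adopters).
#' @param true_dynamic_effects Named map event time -> log-scale effect,
#'   applied only to the used subgroup. `r = 0` is reserved as the reference.
#' @param pretrend_effects Named map (negative event times) -> log-scale
#'   effect applied to *all* adopters: an adoption-timed confound shared by the
#'   used and never-used subgroups, which a DD picks up and a DDD nets out.
#' @param baseline_log_hours Grand mean of the latent log(1 + hours) scale.
#' @param user_fe_sd SD of the user fixed effect gamma_i.
#' @param month_fe Numeric vector of calendar-month fixed effects delta_t
#'   (length of `months`).
#' @param noise_sd SD of the idiosyncratic error.
#' @param zero_inflation Probability a user-month has no hospital contact at
#'   all, independent of treatment.
#' @param moderator_effect_map Multipliers on the treatment effects, see
#'   [default_moderator_map()].
#' @param exclusion_rates Named fractions of users tagged `physician` and
#'   `driver` (occupations excluded when building the outcome).
#' @param excluded_extra_hours Extra monthly at-hospital hours injected into
#'   the epoch streams of physician/driver users, so the exclusion rule is
#'   observable.
#' @param multi_category_rate Fraction of users flagged as adopters of more
#'   than one app category (removed by [exclude_multi_category()]).
#' @param city_tier_probs Marginal probabilities of city tiers 1-4.
#' @param consumption_probs Marginal probabilities of low/medium/high
#'   consumption (default 0.40/0.40/0.20).
#' @param app_count_meanlog,app_count_sdlog Log-normal parameters of the
#'   installed-app count (defaults match a mean of ~35.7 and SD of ~29.8).
#' @param run_length_mix Admissible hospital-stay run lengths (hours) used
#'   when realizing monthly hours as epoch runs. Either all >= 2 (qualifying
#'   runs; monthly reconstruction under the 2-epoch rule is exact) or all
#'   == 1 (singleton runs, a deliberate mismatch fixture).
#' @param seed Root integer seed; every stage derives its own stream from it.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_users = 5000L,
                       months = month_seq("2019-01", "2019-12"),
                       adoption_window = c("2019-04", "2019-09"),
                       p_used = 0.08,
                       true_dynamic_effects = default_dynamic_effects(),
                       pretrend_effects = numeric(),
                       baseline_log_hours = 1.5,
                       user_fe_sd = 1.0,
                       month_fe = 0.1 * cos(2 * pi * (seq_along(months) - 1) / 12),
                       noise_sd = 0.5,
                       zero_inflation = 0.7,
                       moderator_effect_map = default_moderator_map(),
                       exclusion_rates = c(physician = 0.005, driver = 0.005),
                       excluded_extra_hours = 40L,
                       multi_category_rate = 0.05,
                       city_tier_probs = c(0.15, 0.25, 0.30, 0.30),
                       consumption_probs = c(low = 0.4, medium = 0.4, high = 0.2),
                       app_count_meanlog = 3.31,
                       app_count_sdlog = 0.73,
                       run_length_mix = 2:6,
                       seed = 1L) {
  if (!all(adoption_window %in% months)) {
    stop("adoption_window must lie inside the month grid", call. = FALSE)
  }
  aw <- month_index(adoption_window, months)
  if (aw[2] < aw[1]) stop("adoption_window is reversed", call. = FALSE)
  probs <- c(p_used, zero_inflation, exclusion_rates, multi_category_rate,
             city_tier_probs, consumption_probs)
  if (any(probs < 0 | probs > 1)) {
    stop("all probability fields must lie in [0, 1]", call. = FALSE)
  }
  check_effects_map(true_dynamic_effects, "true_dynamic_effects")
  check_effects_map(pretrend_effects, "pretrend_effects")
  if (length(pretrend_effects) &&
      any(as.integer(names(pretrend_effects)) > 0L)) {
    stop("pretrend_effects keys must be negative event times", call. = FALSE)
  }
  if (length(month_fe) != length(months)) {
    stop("month_fe must have one entry per month", call. = FALSE)
  }
  mix <- as.integer(run_length_mix)
  if (length(mix) == 0L || any(mix < 1L) ||
      (any(mix == 1L) && any(mix >= 2L))) {
    stop("run_length_mix must be all >= 2 (qualifying) or all == 1 (singleton)",
         call. = FALSE)
  }
  structure(list(
    n_users = as.integer(n_users), months = months,
    adoption_window = adoption_window, p_used = p_used,
    true_dynamic_effects = true_dynamic_effects,
    pretrend_effects = pretrend_effects,
    baseline_log_hours = baseline_log_hours, user_fe_sd = user_fe_sd,
    month_fe = month_fe, noise_sd = noise_sd, zero_inflation = zero_inflation,
    moderator_effect_map = moderator_effect_map,
    exclusion_rates = exclusion_rates,
    excluded_extra_hours = as.integer(excluded_extra_hours),
    multi_category_rate = multi_category_rate,
    city_tier_probs = city_tier_probs, consumption_probs = consumption_probs,
    app_count_meanlog = app_count_meanlog, app_count_sdlog = app_count_sdlog,
    run_length_mix = mix, seed = as.integer(seed)
  ), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat("  users:          ", x$n_users, "\n")
  cat("  months:         ", x$months[1], "..", x$months[length(x$months)], "\n")
  cat("  adoption window:", x$adoption_window[1], "..", x$adoption_window[2], "\n")
  cat("  p_used:         ", x$p_used, "\n")
  cat("  dynamic effects:",
      paste0("r=", names(x$true_dynamic_effects), ":",
             signif(x$true_dynamic_effects, 3), collapse = " "), "\n")
  cat("  zero inflation: ", x$zero_inflation,
      " noise sd: ", x$noise_sd, " seed: ", x$seed, "\n", sep = "")
  invisible(x)
}

#' Generate user records
#'
#' Draws static attributes and treatment assignment for a cohort of adopters:
#' adoption month uniform over the adoption window, a Bernoulli used flag,
#' occupation tags, consumption level, city tier, installed-app count and a
#' multi-category-adopter flag. Deterministic given the config seed.
#'
#' @param cfg A [sim_config()].
#' @return A `data.table` with one row per user.
#' @export
generate_users <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(stage_seed(cfg$seed, "users"))
  n <- cfg$n_users
  window <- month_seq(cfg$adoption_window[1], cfg$adoption_window[2])
  occ_p <- c(none = 1 - sum(cfg$exclusion_rates),
             physician = unname(cfg$exclusion_rates["physician"]),
             driver = unname(cfg$exclusion_rates["driver"]))
  users <- data.table::data.table(
    user_id = seq_len(n),
    adoption_month = sample(window, n, replace = TRUE),
    used_flag = stats::runif(n) < cfg$p_used,
    occupation_tag = sample(names(occ_p), n, replace = TRUE, prob = occ_p),
    consumption_level = factor(
      sample(names(cfg$consumption_probs), n, replace = TRUE,
             prob = cfg$consumption_probs),
      levels = c("low", "medium", "high")),
    city_tier = sample(1:4, n, replace = TRUE, prob = cfg$city_tier_probs),
    installed_app_count = pmax(0L, as.integer(round(stats::rlnorm(
      n, cfg$app_count_meanlog, cfg$app_count_sdlog)))),
    multi_category_adopter = stats::runif(n) < cfg$multi_category_rate
  )
  users
}

# treatment-effect multiplier per user from the moderator map
moderator_multiplier <- function(users, map) {
  cm <- map$consumption_level[as.character(users$consumption_level)]
  tm <- map$city_tier[as.character(users$city_tier)]
  app <- users$installed_app_count
  s <- stats::sd(app)
  z <- if (is.na(s) || s == 0) rep(0, length(app)) else (app - mean(app)) / s
  unname(cm * tm * (1 + map$app_count_per_sd * z))
}

#' Generate latent monthly outcomes (panel truth)
#'
#' Builds the latent log-scale outcome eta = baseline + gamma_i + delta_t +
#' effect(r) + eps_it, where the dynamic effect applies only to the used
#' subgroup (scaled by the user's moderator multiplier) and any pre-trend
#' effect applies to all adopters. The latent value is mapped to nonnegative
#' integer hours via hours = round(exp(eta) - 1) clipped at 0, with
#' zero-inflation forcing a fraction of user-months to zero; a realized value
#' of a single hour is promoted to 2, since a measured visit spans at least
#' two consecutive epochs.
#'
#' @param users Output of [generate_users()].
#' @param cfg The same [sim_config()].
#' @return A `data.table` with one row per user x month: latent `eta`,
#'   realized `visit_hours`, `log_outcome = log(1 + visit_hours)`, event time,
#'   post flag and user attributes.
#' @export
generate_outcomes <- function(users, cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  check_effects_map(cfg$true_dynamic_effects, "true_dynamic_effects")
  set.seed(stage_seed(cfg$seed, "outcomes"))
  months <- cfg$months
  n <- nrow(users)
  gamma <- stats::rnorm(n, 0, cfg$user_fe_sd)
  mult <- moderator_multiplier(users, cfg$moderator_effect_map)

  grid <- data.table::CJ(user_id = users$user_id,
                         month_pos = seq_along(months), sorted = TRUE)
  ui <- match(grid$user_id, users$user_id)
  grid[, month := months[month_pos]]
  adopt_pos <- month_index(users$adoption_month, months)[ui]
  grid[, event_time := month_pos - adopt_pos]

  dyn <- cfg$true_dynamic_effects
  pre <- cfg$pretrend_effects
  eff <- rep(0, nrow(grid))
  if (length(dyn)) {
    d <- dyn[as.character(grid$event_time)]
    d[is.na(d)] <- 0
    eff <- eff + unname(d) * users$used_flag[ui] * mult[ui]
  }
  if (length(pre)) {
    p <- pre[as.character(grid$event_time)]
    p[is.na(p)] <- 0
    eff <- eff + unname(p)
  }
  eta <- cfg$baseline_log_hours + gamma[ui] + cfg$month_fe[grid$month_pos] +
    eff + stats::rnorm(nrow(grid), 0, cfg$noise_sd)

  hours <- pmax(0L, as.integer(round(expm1(eta))))
  hours[hours == 1L] <- 2L
  cap <- 24L * days_in_month(grid$month)
  hours <- pmin(hours, cap)
  if (cfg$zero_inflation > 0) {
    hours[stats::runif(nrow(grid)) < cfg$zero_inflation] <- 0L
  }

  out <- data.table::data.table(
    user_id = grid$user_id,
    month = grid$month,
    month_pos = grid$month_pos,
    event_time = grid$event_time,
    post_flag = as.integer(grid$event_time >= 1L),
    eta = eta,
    visit_hours = hours,
    log_outcome = log1p(hours),
    used_flag = users$used_flag[ui],
    adoption_month = users$adoption_month[ui],
    occupation_tag = users$occupation_tag[ui],
    consumption_level = users$consumption_level[ui],
    city_tier = users$city_tier[ui],
    installed_app_count = users$installed_app_count[ui],
    multi_category_adopter = users$multi_category_adopter[ui]
  )
  out[]
}

# Decompose H at-hospital hours into run lengths drawn from `mix`. Qualifying
# mode (all lengths >= 2) guarantees the remainder is never 1, so the total
# under the 2-epoch rule reconstructs H exactly; singleton mode emits H
# isolated hours, none of which qualify.
decompose_runs <- function(H, mix) {
  H <- as.integer(H)
  if (H <= 0L) return(integer())
  if (all(mix == 1L)) return(rep(1L, H))
  mix <- sort(unique(mix[mix >= 2L]))
  if (H == 1L) {
    stop("cannot realize a single at-hospital hour as a run of >= 2 epochs",
         call. = FALSE)
  }
  lens <- integer()
  while (H > 0L) {
    ok <- mix[mix <= H & (H - mix) != 1L]
    L <- if (length(ok)) ok[sample.int(length(ok), 1L)] else H
    lens <- c(lens, L)
    H <- H - L
  }
  lens
}

# Place runs at random non-overlapping positions in a month of n_h hours with
# at least one empty hour between runs (so each run is maximal). Merges runs
# when the month is too tight for the gaps; errors if the hours themselves do
# not fit. Returns 0-based start offsets aligned with (possibly merged) lens.
place_runs <- function(lens, n_h) {
  if (length(lens) == 0L) return(list(starts = integer(), lens = integer()))
  if (sum(lens) > n_h) {
    stop("target hours exceed hours in month", call. = FALSE)
  }
  lens <- lens[sample.int(length(lens))]
  while (sum(lens) + length(lens) - 1L > n_h && length(lens) > 1L) {
    lens <- c(lens[1L] + lens[2L], lens[-(1:2)])
  }
  k <- length(lens)
  slack <- n_h - sum(lens) - (k - 1L)
  gaps <- if (slack > 0L) tabulate(sample.int(k + 1L, slack, replace = TRUE),
                                   nbins = k + 1L) else integer(k + 1L)
  starts <- integer(k)
  pos <- 0L
  for (j in seq_len(k)) {
    pos <- pos + gaps[j]
    starts[j] <- pos
    pos <- pos + lens[j] + 1L  # +1 empty hour keeps runs maximal
  }
  list(starts = starts, lens = lens)
}

#' Realize monthly hours as hourly epoch streams
#'
#' Emits, for every user-month with positive target hours, at-hospital runs
#' whose qualifying total under the 2-epoch rule equals the target (when the
#' run mix uses lengths >= 2). Physician and driver users additionally get
#' extra at-hospital hours injected each month, so the occupation exclusion
#' rule has something to catch. The stream is sparse: one row per at-hospital
#' user-hour; absent hours mean not at hospital.
#'
#' @param panel_truth Output of [generate_outcomes()].
#' @param cfg The same [sim_config()].
#' @return A `data.table` with columns `user_id`, `hour_ts` (POSIXct, UTC,
#'   whole hours) and `at_hospital`.
#' @export
generate_epoch_streams <- function(panel_truth, cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(stage_seed(cfg$seed, "streams"))
  pt <- data.table::as.data.table(panel_truth)
  target <- pt$visit_hours +
    ifelse(pt$occupation_tag %in% c("physician", "driver"),
           cfg$excluded_extra_hours, 0L)
  idx <- which(target > 0L)
  if (length(idx) == 0L) {
    return(data.table::data.table(user_id = integer(),
                                  hour_ts = as.POSIXct(character(), tz = "UTC"),
                                  at_hospital = logical()))
  }
  m_start <- month_start(cfg$months)
  names(m_start) <- cfg$months
  uid <- vector("list", length(idx))
  ts <- vector("list", length(idx))
  for (j in seq_along(idx)) {
    i <- idx[j]
    n_h <- 24L * days_in_month(pt$month[i])
    lens <- decompose_runs(target[i], cfg$run_length_mix)
    pl <- place_runs(lens, n_h)
    offs <- unlist(Map(function(s, l) s + seq_len(l) - 1L, pl$starts, pl$lens),
                   use.names = FALSE)
    uid[[j]] <- rep(pt$user_id[i], length(offs))
    ts[[j]] <- unname(m_start[pt$month[i]]) + offs * 3600
  }
  out <- data.table::data.table(
    user_id = unlist(uid, use.names = FALSE),
    hour_ts = as.POSIXct(unlist(ts, use.names = FALSE), tz = "UTC",
                         origin = "1970-01-01"),
    at_hospital = TRUE
  )
  data.table::setkey(out, user_id, hour_ts)
  out[]
}

#' Simulate a full cohort
#'
#' Convenience wrapper: users, latent panel truth and (optionally) epoch
#' streams from one config.
#'
#' @param cfg A [sim_config()].
#' @param streams Emit epoch streams too? (The latent truth alone suffices for
#'   estimator studies and is much faster.)
#' @return A list with `users`, `truth` and (if requested) `streams`.
#' @export
simulate_cohort <- function(cfg, streams = TRUE) {
  users <- generate_users(cfg)
  truth <- generate_outcomes(users, cfg)
  out <- list(users = users, truth = truth)
  if (streams) out$streams <- generate_epoch_streams(truth, cfg)
  out
}

#' Write simulated tables to disk
#'
#' @param sim Output of [simulate_cohort()].
#' @param cfg The [sim_config()] used (serialized as YAML alongside).
#' @param dir Output directory (created if needed).
#' @param format `"csv"` (default) or `"parquet"` (needs the arrow package).
#' @return Invisibly, the paths written.
#' @export
write_synth <- function(sim, cfg, dir, format = c("csv", "parquet")) {
  format <- match.arg(format)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(users = file.path(dir, paste0("users.", format)),
             truth = file.path(dir, paste0("panel_truth.", format)),
             config = file.path(dir, "sim_config.yaml"))
  tabs <- list(users = sim$users, truth = sim$truth)
  if (!is.null(sim$streams)) {
    paths["streams"] <- file.path(dir, paste0("epoch_streams.", format))
    tabs$streams <- data.table::copy(sim$streams)
    tabs$streams[, hour_ts := format(hour_ts, "%Y-%m-%d %H:%M:%S", tz = "UTC")]
  }
  for (nm in names(tabs)) {
    if (format == "csv") {
      data.table::fwrite(tabs[[nm]], paths[[nm]])
    } else {
      if (!requireNamespace("arrow", quietly = TRUE)) {
        stop("parquet output needs the arrow package", call. = FALSE)
      }
      arrow::write_parquet(tabs[[nm]], paths[[nm]])
    }
  }
  cfg_l <- unclass(cfg)
  cfg_l$true_dynamic_effects <- as.list(cfg_l$true_dynamic_effects)
  cfg_l$pretrend_effects <- as.list(cfg_l$pretrend_effects)
  yaml::write_yaml(cfg_l, paths[["config"]])
  invisible(paths)
}
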