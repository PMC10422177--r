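# End-to-end orchestration: simulate -> visit construction -> panel ->
# DD/DDD fits across the sensitivity matrix (visit rules x adoption windows)
# -> moderation models -> pre-trend report, with JSON-lines logging, tidy
# coefficient CSVs and a reproducibility manifest.

#' Run configuration
#'
#' @param sim A [sim_config()] describing the synthetic cohort (or `NULL` if
#'   `input_dir` points at pre-built user/stream tables).
#' @param input_dir Optional directory with `users.csv` and
#'   `epoch_streams.csv` to use instead of simulating.
#' @param visit_rules Integer vector of consecutive-epoch thresholds to run
#'   (default `c(2, 3, 4)`).
#' @param measures Outcome measures to run (`"hours"`, `"days"`).
#' @param windows Named list of [cohort_window()]s (default: the main Apr-Sep
#'   window and the shortened May-Aug check).
#' @param models Which estimations to fit: subset of `"dd"`, `"ddd"`,
#'   `"moderation"`.
#' @param out_dir Output directory.
#' @param seed Root seed (overrides the sim config seed so one seed governs
#'   the whole run).
#' @return An object of class `run_config`.
#' @export
run_config <- function(sim = sim_config(n_users = 1000L),
                       input_dir = NULL,
                       visit_rules = c(2L, 3L, 4L),
                       measures = "hours",
                       windows = list(
                         main = cohort_window("2019-04", "2019-09"),
                         shortened = cohort_window("2019-05", "2019-08")),
                       models = c("dd", "ddd", "moderation"),
                       out_dir = tempfile("mhdid_run_"),
                       seed = 1L) {
  models <- match.arg(models, c("dd", "ddd", "moderation"),
                      several.ok = TRUE)
  if (length(models) == 0L) stop("at least one model must be requested",
                                 call. = FALSE)
  stopifnot(all(measures %in% c("hours", "days")))
  if (!is.null(sim)) {
    sim$seed <- as.integer(seed)
  }
  structure(list(sim = sim, input_dir = input_dir,
                 visit_rules = as.integer(visit_rules), measures = measures,
                 windows = windows, models = models, out_dir = out_dir,
                 seed = as.integer(seed)),
            class = "run_config")
}

# JSON-lines stage log
log_stage <- function(con, stage, ...) {
  rec <- c(list(stage = stage, time = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
           list(...))
  writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE), con)
}

#' Run the full pipeline
#'
#' Executes simulate -> visits -> panel -> fits over the requested matrix of
#' visit rules, outcome measures and cohort windows, plus the moderation
#' models and a pre-trend report on the main DD fit. Writes one tidy
#' coefficient CSV per fit, an event-study export, a JSON-lines log and a
#' manifest with the config, row counts and coefficient-table hashes.
#' Identical config and seed reproduce byte-identical coefficient tables.
#'
#' @param cfg A [run_config()].
#' @return Invisibly, the manifest list (also written to
#'   `manifest.json` in the output directory).
#' @export
run_all <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  logf <- file(file.path(cfg$out_dir, "run_log.jsonl"), open = "wt")
  on.exit(close(logf), add = TRUE)

  months <- if (!is.null(cfg$sim)) cfg$sim$months else
    month_seq("2019-01", "2019-12")

  if (!is.null(cfg$input_dir)) {
    users <- data.table::fread(file.path(cfg$input_dir, "users.csv"))
    users[, consumption_level := factor(consumption_level,
                                        levels = c("low", "medium", "high"))]
    streams <- data.table::fread(file.path(cfg$input_dir, "epoch_streams.csv"))
    streams[, hour_ts := as.POSIXct(hour_ts, tz = "UTC")]
    log_stage(logf, "load", users = nrow(users), stream_rows = nrow(streams))
  } else {
    sim <- simulate_cohort(cfg$sim, streams = TRUE)
    users <- sim$users
    streams <- sim$streams
    log_stage(logf, "simulate", users = nrow(users),
              stream_rows = nrow(streams), seed = cfg$seed)
  }

  n0 <- nrow(users)
  users <- exclude_multi_category(users)
  log_stage(logf, "filter_multi_category", removed = n0 - nrow(users),
            retained = nrow(users))

  fits <- list()
  tables <- character()
  for (k in cfg$visit_rules) {
    for (meas in cfg$measures) {
      mv <- monthly_visits(streams, users, visit_rule(k, meas), months)
      log_stage(logf, "visits", rule = k, measure = meas,
                excluded_users = length(attr(mv, "excluded_users")),
                rows = nrow(mv))
      for (wname in names(cfg$windows)) {
        window <- cfg$windows[[wname]]
        pan <- build_panel(mv, users, window, months, measure = meas)
        pan <- event_time_dummies(pan, window)
        has_both <- length(unique(pan$used_flag)) == 2L
        if (has_both) pan <- add_ddd_terms(pan)
        log_stage(logf, "panel", rule = k, measure = meas, window = wname,
                  rows = nrow(pan), users = data.table::uniqueN(pan$user_id))
        for (model in intersect(cfg$models, c("dd", "ddd"))) {
          if (model == "ddd" && !has_both) {
            log_stage(logf, "skip", model = "ddd", window = wname,
                      reason = "a used/never-used subgroup is empty")
            next
          }
          spec <- if (model == "dd") build_dd(window) else build_ddd(window)
          fit <- fe_fit(spec, pan)
          tag <- paste(model, wname, paste0("k", k), meas, sep = "_")
          fits[[tag]] <- fit
          path <- file.path(cfg$out_dir, paste0(tag, ".csv"))
          data.table::fwrite(coef_table(fit), path)
          tables <- c(tables, path)
          log_stage(logf, "fit", model = model, rule = k, measure = meas,
                    window = wname, n = fit$n_obs,
                    clusters = fit$n_clusters, r2 = round(fit$r_squared, 4))
        }
      }
    }
  }

  pretrend <- NULL
  main_dd <- paste0("dd_", names(cfg$windows)[1], "_k",
                    cfg$visit_rules[1], "_", cfg$measures[1])
  if (main_dd %in% names(fits)) {
    pretrend <- pretrend_report(fits[[main_dd]], cfg$windows[[1L]])
    utils::capture.output(print(pretrend),
                          file = file.path(cfg$out_dir, "pretrend.txt"))
    log_stage(logf, "pretrend", wald = pretrend$wald, p = pretrend$p_value)
  }

  if ("moderation" %in% cfg$models) {
    window <- cfg$windows[[1L]]
    mv <- monthly_visits(streams, users, visit_rule(cfg$visit_rules[1]),
                         months)
    pan <- build_panel(mv, users, window, months)
    for (mod in c("none", "consumption_level", "city_tier", "app_count")) {
      mspec <- moderation_spec(mod)
      mp <- moderation_panel(pan, mspec$horizon, months)
      fit <- fe_fit(build_moderation(mspec), mp)
      tag <- paste0("moderation_", mod)
      fits[[tag]] <- fit
      path <- file.path(cfg$out_dir, paste0(tag, ".csv"))
      data.table::fwrite(coef_table(fit), path)
      tables <- c(tables, path)
      log_stage(logf, "fit", model = "moderation", moderator = mod,
                n = fit$n_obs, clusters = fit$n_clusters)
    }
  }

  es <- eventstudy_export(fits[intersect(names(fits),
                                         grep("^dd|^ddd", names(fits),
                                              value = TRUE))])
  es_path <- file.path(cfg$out_dir, "eventstudy.csv")
  data.table::fwrite(es, es_path)
  tables <- c(tables, es_path)

  manifest <- list(
    package_version = as.character(utils::packageVersion("mhdid")),
    seed = cfg$seed,
    models = cfg$models,
    visit_rules = cfg$visit_rules,
    measures = cfg$measures,
    windows = lapply(cfg$windows, unclass),
    n_users = nrow(users),
    tables = stats::setNames(
      vapply(tables, function(p) unname(tools::md5sum(p)), ""),
      basename(tables))
  )
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  log_stage(logf, "done", tables = length(tables))
  invisible(list(manifest = manifest, fits = fits, pretrend = pretrend,
                 out_dir = cfg$out_dir))
}

#' Plot-ready event-study table
#'
#' Long-format table of dynamic coefficients with CIs, one block per fit,
#' including the reference period at event time 0 with estimate 0, suitable
#' for external plotting.
#'
#' @param fits A named list of [fe_fit()] objects (DD and/or DDD).
#' @return `data.table` with `model`, `event_time`, `estimate`, `ci_low`,
#'   `ci_high`.
#' @export
eventstudy_export <- function(fits) {
  if (inherits(fits, "fe_fit")) fits <- list(fit = fits)
  if (length(fits) == 0L) stop("need at least one dynamic fit", call. = FALSE)
  out <- lapply(names(fits), function(nm) {
    fit <- fits[[nm]]
    tab <- coef_table(fit)
    is_ddd <- any(startsWith(tab$term, "used_x_"))
    if (is_ddd) {
      tab <- tab[startsWith(tab$term, "used_x_"), , drop = FALSE]
      tab$term <- sub("^used_x_", "", tab$term)
    }
    tab <- tab[grepl("^ev_[mp][0-9]+$", tab$term), , drop = FALSE]
    neg <- startsWith(tab$term, "ev_m")
    r <- integer(nrow(tab))
    r[neg] <- -as.integer(sub("ev_m", "", tab$term[neg]))
    r[!neg] <- as.integer(sub("ev_p", "", tab$term[!neg]))
    dt <- data.table::data.table(model = nm, event_time = r,
                                 estimate = tab$estimate,
                                 ci_low = tab$ci_low, ci_high = tab$ci_high)
    ref <- data.table::data.table(model = nm, event_time = 0L,
                                  estimate = 0, ci_low = 0, ci_high = 0)
    data.table::setorder(rbind(dt, ref), event_time)[]
  })
  data.table::rbindlist(out)
}
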