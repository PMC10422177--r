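# Estimation-panel construction: event-time coding relative to the adoption
# month, cohort-window filtering, outcome transform, and event-time indicator
# columns with end-cap binning.

#' Cohort window
#'
#' Which adoption cohorts enter the panel and which event times are reported.
#' Event time 0 (the adoption month) is the omitted reference category; event
#' times beyond the reported leads/lags are binned into end caps.
#'
#' @param adoption_first,adoption_last First/last admissible adoption month.
#' @param report_leads Number of reported pre-adoption months (default 2).
#' @param report_lags Number of reported post-adoption months (default 3).
#' @param reference_period Event time omitted from estimation (default 0).
#' @return An object of class `cohort_window`.
#' @export
cohort_window <- function(adoption_first = "2019-04",
                          adoption_last = "2019-09",
                          report_leads = 2L, report_lags = 3L,
                          reference_period = 0L) {
  if (report_leads < 1L || report_lags < 1L) {
    stop("report_leads and report_lags must be >= 1", call. = FALSE)
  }
  structure(list(adoption_first = adoption_first,
                 adoption_last = adoption_last,
                 report_leads = as.integer(report_leads),
                 report_lags = as.integer(report_lags),
                 reference_period = as.integer(reference_period)),
            class = "cohort_window")
}

#' @export
print.cohort_window <- function(x, ...) {
  cat("<cohort_window> adoption", x$adoption_first, "..", x$adoption_last,
      "| leads", x$report_leads, "lags", x$report_lags,
      "| reference r =", x$reference_period, "\n")
  invisible(x)
}

#' Build the estimation panel
#'
#' One row per retained user and calendar month. Users adopting outside the
#' cohort window are dropped (counterfactuals come from adopters of the same
#' app in other months, so every retained user has an adoption month). The
#' outcome is log(1 + visit_hours) (or visit_days), event time is the signed
#' month difference from the adoption month, and the installed-app count is
#' mean-centred over the retained users.
#'
#' @param visits Monthly visit table from [monthly_visits()] (or the
#'   `visit_hours`/`visit_days` columns of the latent truth).
#' @param users User table (already filtered for occupation and
#'   multi-category adopters).
#' @param window A [cohort_window()].
#' @param months Month grid of the data window.
#' @param measure `"hours"` or `"days"`.
#' @return `data.table` of panel rows.
#' @export
build_panel <- function(visits, users, window = cohort_window(),
                        months = month_seq("2019-01", "2019-12"),
                        measure = c("hours", "days")) {
  stopifnot(inherits(window, "cohort_window"))
  measure <- match.arg(measure)
  users <- data.table::as.data.table(users)
  visits <- data.table::as.data.table(visits)
  if (!"adoption_month" %in% names(users) || anyNA(users$adoption_month)) {
    stop("every user needs an adoption month", call. = FALSE)
  }
  wmonths <- month_seq(window$adoption_first, window$adoption_last)
  users <- users[adoption_month %in% wmonths]
  if (!all(visits$month %in% months)) {
    stop("visits contain calendar months outside the data window", call. = FALSE)
  }
  pan <- visits[user_id %in% users$user_id]
  ucols <- intersect(c("user_id", "adoption_month", "used_flag",
                       "consumption_level", "city_tier",
                       "installed_app_count"), names(users))
  pan <- users[, ucols, with = FALSE][pan, on = "user_id"]
  pan[, month_pos := month_index(month, months)]
  pan[, event_time := month_pos - month_index(adoption_month, months)]
  pan[, post_flag := as.integer(event_time >= 1L)]
  yvar <- if (measure == "hours") "visit_hours" else "visit_days"
  pan[, log_outcome := log1p(as.numeric(.SD[[1L]])), .SDcols = yvar]
  if ("installed_app_count" %in% names(pan)) {
    pan[, app_count_centered := installed_app_count -
          mean(installed_app_count[!duplicated(user_id)])]
  }
  data.table::setorder(pan, user_id, month_pos)
  pan[]
}

# canonical indicator column name for an event time
event_term_name <- function(r) {
  ifelse(r < 0, paste0("ev_m", -r), paste0("ev_p", r))
}

#' Event-time indicator columns
#'
#' Adds one 0/1 column per event time r in `[-report_leads, report_lags]`
#' excluding the reference period, plus end caps `ev_pre` (r <= -(leads+1))
#' and `ev_post` (r >= lags+1) whenever observations fall beyond the reported
#' range. Every row activates exactly one indicator among {reported terms,
#' caps, implicit reference}.
#'
#' @param panel Panel from [build_panel()].
#' @param window The [cohort_window()].
#' @return The panel with indicator columns added; attribute `event_terms`
#'   holds the column names in display order (leads, caps, lags).
#' @export
event_time_dummies <- function(panel, window = cohort_window()) {
  stopifnot(inherits(window, "cohort_window"))
  pan <- data.table::as.data.table(panel)
  rs <- setdiff(seq(-window$report_leads, window$report_lags),
                window$reference_period)
  terms <- character()
  lo <- -(window$report_leads + 1L)
  hi <- window$report_lags + 1L
  if (any(pan$event_time <= lo)) {
    pan[, ev_pre := as.integer(event_time <= lo)]
    terms <- c(terms, "ev_pre")
  }
  for (r in sort(rs)) {
    nm <- event_term_name(r)
    pan[, (nm) := as.integer(event_time == r)]
    terms <- c(terms, nm)
  }
  if (any(pan$event_time >= hi)) {
    pan[, ev_post := as.integer(event_time >= hi)]
    terms <- c(terms, "ev_post")
  }
  data.table::setattr(pan, "event_terms", terms)
  pan[]
}

#' Add triple-difference interaction columns
#'
#' For each event-time indicator, adds its interaction with the used flag
#' (`used_x_*`). These are the coefficients of interest in the DDD
#' specification; the base indicators stay in the model as the shared
#' adoption-timed profile of both subgroups.
#'
#' @param panel Panel with event-time dummies (see [event_time_dummies()]).
#' @return The panel with `used_x_*` columns; attribute `ddd_terms` holds
#'   their names.
#' @export
add_ddd_terms <- function(panel) {
  pan <- data.table::as.data.table(panel)
  terms <- attr(panel, "event_terms")
  if (is.null(terms)) stop("run event_time_dummies() first", call. = FALSE)
  if (!"used_flag" %in% names(pan)) stop("used_flag missing", call. = FALSE)
  n_used <- sum(pan$used_flag)
  if (n_used == 0L || n_used == nrow(pan)) {
    stop("both the used and never-used subgroups must be nonempty",
         call. = FALSE)
  }
  dnames <- paste0("used_x_", terms)
  for (j in seq_along(terms)) {
    pan[, (dnames[j]) := as.integer(.SD[[1L]] * used_flag),
        .SDcols = terms[j]]
  }
  data.table::setattr(pan, "event_terms", terms)
  data.table::setattr(pan, "ddd_terms", dnames)
  pan[]
}
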