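# Dependent-variable construction: hourly epoch streams -> monthly hospital
# visit duration (hours) and day counts, under a minimum consecutive-epoch
# rule, with occupation-based exclusions.

#' Visit-counting rule
#'
#' A geolocation record counts toward hospital visits only as part of a run of
#' at least `min_consecutive_epochs` consecutive at-hospital hours ("more than
#' an hour" = at least 2 epochs; 3 and 4 are the sensitivity variants). The
#' measure is either total qualifying hours or the number of distinct days
#' touched by a qualifying run.
#'
#' @param min_consecutive_epochs Integer >= 1; 2 (default), 3 and 4 are the
#'   study rules, 1 yields the raw at-hospital hour count.
#' @param measure `"hours"` or `"days"`.
#' @return An object of class `visit_rule`.
#' @export
visit_rule <- function(min_consecutive_epochs = 2L,
                       measure = c("hours", "days")) {
  k <- as.integer(min_consecutive_epochs)
  if (is.na(k) || k < 1L) {
    stop("min_consecutive_epochs must be an integer >= 1", call. = FALSE)
  }
  structure(list(min_consecutive_epochs = k, measure = match.arg(measure)),
            class = "visit_rule")
}

#' @export
print.visit_rule <- function(x, ...) {
  cat("<visit_rule> k =", x$min_consecutive_epochs,
      "consecutive epochs, measure =", x$measure, "\n")
  invisible(x)
}

#' Maximal runs of consecutive at-hospital epochs
#'
#' Scans a sparse epoch stream (rows are at-hospital user-hours) and returns
#' maximal runs of consecutive hours per user. Runs spanning a calendar-month
#' boundary are split at the boundary so monthly aggregation is unambiguous.
#'
#' @param stream `data.table` with columns `user_id`, `hour_ts` (POSIXct on a
#'   whole-hour grid), `at_hospital`.
#' @return `data.table` with one row per run: `user_id`, `start_ts`, `len`
#'   (hours) and `month`.
#' @export
find_runs <- function(stream) {
  st <- data.table::as.data.table(stream)
  if (nrow(st) == 0L) {
    return(data.table::data.table(user_id = integer(),
                                  start_ts = as.POSIXct(character(), tz = "UTC"),
                                  len = integer(), month = character()))
  }
  if ("at_hospital" %in% names(st)) st <- st[at_hospital == TRUE]
  st[, hour_idx := as.numeric(hour_ts) %/% 3600]
  if (any(as.numeric(st$hour_ts) %% 3600 != 0)) {
    stop("timestamps must lie on a whole-hour grid", call. = FALSE)
  }
  data.table::setorder(st, user_id, hour_idx)
  if (anyDuplicated(st, by = c("user_id", "hour_idx"))) {
    stop("duplicate (user, hour) records in epoch stream", call. = FALSE)
  }
  st[, month := format(hour_ts, "%Y-%m", tz = "UTC")]
  st[, run_id := cumsum(
    c(1L, (diff(hour_idx) != 1L) | (month[-1L] != month[-.N]))
  ), by = user_id]
  runs <- st[, .(start_ts = hour_ts[1L], len = .N, month = month[1L]),
             by = .(user_id, run_id)]
  runs[, run_id := NULL]
  runs[]
}

#' Monthly hospital-visit durations
#'
#' Aggregates qualifying runs (length >= k) into one row per retained user and
#' calendar month: total qualifying hours and the number of distinct days
#' containing at least one qualifying-run hour. Users tagged physician or
#' web-based ride-hailing driver are excluded (they visit hospitals for
#' reasons outside the outcome of interest) and contribute no rows; the
#' excluded ids are attached as an attribute.
#'
#' @param stream Epoch stream (see [find_runs()]).
#' @param users User table with `user_id` and `occupation_tag`.
#' @param rule A [visit_rule()].
#' @param months Month grid; every retained user gets a row for every month
#'   (zero-filled).
#' @return `data.table` `user_id`, `month`, `visit_hours`, `visit_days`, with
#'   attribute `excluded_users`.
#' @export
monthly_visits <- function(stream, users, rule = visit_rule(),
                           months = month_seq("2019-01", "2019-12")) {
  stopifnot(inherits(rule, "visit_rule"))
  users <- data.table::as.data.table(users)
  excluded <- users[occupation_tag %in% c("physician", "driver"), user_id]
  keep <- setdiff(users$user_id, excluded)

  runs <- find_runs(stream)
  runs <- runs[user_id %in% keep & len >= rule$min_consecutive_epochs]

  hours <- runs[, .(visit_hours = sum(len)), by = .(user_id, month)]

  # expand qualifying runs to their hours to count distinct days touched
  if (nrow(runs)) {
    ex <- runs[rep(seq_len(.N), len)]
    ex[, day := format(start_ts + 3600 * (sequence(runs$len) - 1L),
                       "%Y-%m-%d", tz = "UTC")]
    days <- ex[, .(visit_days = data.table::uniqueN(day)),
               by = .(user_id, month)]
  } else {
    days <- data.table::data.table(user_id = integer(), month = character(),
                                   visit_days = integer())
  }

  grid <- data.table::CJ(user_id = keep, month = months, sorted = TRUE)
  out <- days[hours[grid, on = c("user_id", "month")],
              on = c("user_id", "month")]
  out[is.na(visit_hours), visit_hours := 0L]
  out[is.na(visit_days), visit_days := 0L]
  data.table::setcolorder(out, c("user_id", "month", "visit_hours", "visit_days"))
  data.table::setattr(out, "excluded_users", excluded)
  out[]
}

#' Drop multi-category app adopters
#'
#' Users who adopted more than one category of health and fitness app are
#' removed to rule out synergistic effects across app categories.
#'
#' @param users User table with a logical `multi_category_adopter` column.
#' @return The retained users; messages the number removed, warns if none
#'   remain.
#' @export
exclude_multi_category <- function(users) {
  users <- data.table::as.data.table(users)
  if (!"multi_category_adopter" %in% names(users)) {
    stop("users table lacks multi_category_adopter", call. = FALSE)
  }
  n0 <- nrow(users)
  out <- users[multi_category_adopter == FALSE]
  removed <- n0 - nrow(out)
  if (removed > 0L) message("excluded ", removed, " multi-category adopter(s)")
  if (nrow(out) == 0L) warning("all users were multi-category adopters")
  out[]
}
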