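# Declarative builders for the three estimations: dynamic DD (event study with
# user and month fixed effects), triple-difference DDD (used vs never-used
# adopters, with user and month-by-subgroup fixed effects), and moderation
# models (post indicator interacted with consumption level, city tier or
# installed-app count, outcome shifted three months ahead). Plus a pre-trend
# report with a joint Wald test on the lead coefficients.

# expected event-time indicator names for a window, in display order
# (lead cap, leads, lags, lag cap)
window_terms <- function(window, include_caps = TRUE) {
  rs <- setdiff(seq(-window$report_leads, window$report_lags),
                window$reference_period)
  terms <- event_term_name(sort(rs))
  if (include_caps) terms <- c("ev_pre", terms, "ev_post")
  terms
}

#' Dynamic difference-in-differences specification
#'
#' Event-time indicators (reported leads/lags plus end caps, adoption month
#' omitted), user and calendar-month fixed effects, user-clustered SEs.
#'
#' @param window A [cohort_window()].
#' @param include_caps Include the binned end-cap indicators (default TRUE;
#'   set FALSE when the panel was trimmed to the reported range).
#' @param outcome Outcome column (default `"log_outcome"`).
#' @return A [model_spec()].
#' @export
build_dd <- function(window = cohort_window(), include_caps = TRUE,
                     outcome = "log_outcome") {
  model_spec(outcome = outcome,
             regressors = window_terms(window, include_caps),
             fe = c("user_id", "month"),
             cluster = "user_id")
}

#' Triple-difference (DDD) specification
#'
#' Adds the used-subgroup interactions of every event-time indicator on top of
#' the base indicators, and replaces the calendar-month fixed effects with
#' month-by-subgroup effects. The user dimension already nests the subgroup,
#' so plain user fixed effects coincide with user-by-subgroup effects. The
#' coefficients of interest are the `used_x_*` terms; the base indicators
#' absorb any adoption-timed shock shared by both subgroups.
#'
#' @inheritParams build_dd
#' @return A [model_spec()].
#' @export
build_ddd <- function(window = cohort_window(), include_caps = TRUE,
                      outcome = "log_outcome") {
  terms <- window_terms(window, include_caps)
  model_spec(outcome = outcome,
             regressors = c(terms, paste0("used_x_", terms)),
             fe = c("user_id", "month:used_flag"),
             cluster = "user_id")
}

#' Moderation-analysis specification
#'
#' @param moderator `"none"` (post indicator only), `"consumption_level"`,
#'   `"city_tier"` or `"app_count"`.
#' @param horizon Months ahead for the outcome (default 3: the outcome is the
#'   visit duration three months after the observation month, the horizon at
#'   which a short exercise program can plausibly show health effects).
#' @param controls_mode `"observables"` (default): time-invariant user
#'   characteristics enter as controls, so their main effects are estimable;
#'   `"user_fe"`: user fixed effects absorb all time-invariant terms and only
#'   the interactions remain.
#' @return An object of class `moderation_spec`.
#' @export
moderation_spec <- function(moderator = c("none", "consumption_level",
                                          "city_tier", "app_count"),
                            horizon = 3L,
                            controls_mode = c("observables", "user_fe")) {
  horizon <- as.integer(horizon)
  if (horizon < 0L) stop("horizon must be >= 0", call. = FALSE)
  structure(list(moderator = match.arg(moderator), horizon = horizon,
                 controls_mode = match.arg(controls_mode)),
            class = "moderation_spec")
}

# moderator dummy/interaction column names (reference: low consumption,
# tier 4; app count mean-centred)
moderator_columns <- list(
  consumption_level = c("cons_medium", "cons_high"),
  city_tier = c("tier_1", "tier_2", "tier_3"),
  app_count = "app_count_centered"
)

#' Prepare a panel for the moderation models
#'
#' Shifts the outcome `horizon` months ahead within user (rows whose shifted
#' month leaves the data window are dropped) and expands the moderators:
#' consumption dummies (reference low), city-tier dummies (reference tier 4),
#' mean-centred app count, and their interactions with the post indicator.
#'
#' @param panel Panel from [build_panel()].
#' @param horizon Months ahead for the outcome.
#' @param months Month grid of the data window.
#' @return `data.table` with `y_lead`, moderator dummies and `post_x_*`
#'   interaction columns.
#' @export
moderation_panel <- function(panel, horizon = 3L,
                             months = month_seq("2019-01", "2019-12")) {
  horizon <- as.integer(horizon)
  if (horizon >= length(months)) {
    stop("horizon exceeds the data window length", call. = FALSE)
  }
  pan <- data.table::as.data.table(panel)
  data.table::setorder(pan, user_id, month_pos)
  pan[, y_lead := data.table::shift(log_outcome, horizon, type = "lead"),
      by = user_id]
  pan <- pan[!is.na(y_lead)]
  pan[, cons_medium := as.integer(consumption_level == "medium")]
  pan[, cons_high := as.integer(consumption_level == "high")]
  for (tr in 1:3) {
    pan[, (paste0("tier_", tr)) := as.integer(city_tier == tr)]
  }
  mods <- c("cons_medium", "cons_high", "tier_1", "tier_2", "tier_3",
            "app_count_centered")
  for (mcol in mods) {
    pan[, (paste0("post_x_", mcol)) := post_flag * .SD[[1L]], .SDcols = mcol]
  }
  pan[]
}

#' Build the model spec for one moderation model
#'
#' @param mspec A [moderation_spec()].
#' @return A [model_spec()] to be fit on a [moderation_panel()].
#' @export
build_moderation <- function(mspec = moderation_spec()) {
  stopifnot(inherits(mspec, "moderation_spec"))
  main <- unlist(moderator_columns, use.names = FALSE)
  inter <- if (mspec$moderator == "none") character() else
    paste0("post_x_", moderator_columns[[mspec$moderator]])
  if (mspec$controls_mode == "observables") {
    regressors <- c("post_flag", main, inter)
    fe <- "month"
  } else {
    regressors <- c("post_flag", inter)
    fe <- c("user_id", "month")
  }
  model_spec(outcome = "y_lead", regressors = regressors, fe = fe,
             cluster = "user_id")
}

#' Pre-trend assessment
#'
#' Tabulates the lead (pre-adoption) coefficients of a dynamic DD fit and
#' tests H0: all leads are zero with a joint Wald statistic using the
#' cluster-robust covariance. Significant leads signal a parallel-trends
#' violation and motivate the DDD contrast.
#'
#' @param fit An [fe_fit()] of a dynamic DD spec.
#' @param window The [cohort_window()].
#' @param alpha Significance level for the verdict (default 0.05).
#' @return Object of class `pretrend_report`: lead table, Wald statistic,
#'   df, p-value, verdict.
#' @export
pretrend_report <- function(fit, window = cohort_window(), alpha = 0.05) {
  stopifnot(inherits(fit, "fe_fit"))
  leads <- event_term_name(-seq_len(window$report_leads))
  leads <- intersect(leads, names(fit$coefficients))
  if (length(leads) == 0L) {
    stop("fit contains no lead (pre-adoption) terms", call. = FALSE)
  }
  b <- fit$coefficients[leads]
  V <- fit$vcov[leads, leads, drop = FALSE]
  W <- drop(t(b) %*% solve(V, b))
  df <- length(leads)
  p <- stats::pchisq(W, df = df, lower.tail = FALSE)
  verdict <- if (max(abs(b)) == 0) {
    "no pre-trend detected"
  } else if (p < alpha) {
    "pre-trend detected: parallel trends questionable; prefer the DDD contrast"
  } else {
    "no pre-trend detected"
  }
  tab <- coef_table(fit)
  structure(list(leads = tab[tab$term %in% leads, , drop = FALSE],
                 wald = W, df = df, p_value = p, alpha = alpha,
                 verdict = verdict),
            class = "pretrend_report")
}

#' @export
print.pretrend_report <- function(x, ...) {
  cat("Pre-trend assessment (joint Wald on lead terms)\n")
  print(x$leads, row.names = FALSE, digits = 4)
  cat(sprintf("Wald = %.3f on %d df, p = %.4g\n", x$wald, x$df, x$p_value))
  cat("Verdict:", x$verdict, "\n")
  invisible(x)
}

#' Serialize a model spec to YAML
#'
#' @param spec A [model_spec()].
#' @param path Optional file path; if omitted the YAML string is returned.
#' @return The YAML string (invisibly when written to a file).
#' @export
spec_to_yaml <- function(spec, path = NULL) {
  stopifnot(inherits(spec, "model_spec"))
  s <- yaml::as.yaml(unclass(spec))
  if (is.null(path)) return(s)
  writeLines(s, path)
  invisible(s)
}

#' Deserialize a model spec from YAML
#'
#' @param x A file path or a YAML string produced by [spec_to_yaml()].
#' @return A [model_spec()].
#' @export
spec_from_yaml <- function(x) {
  l <- if (file.exists(x)) yaml::read_yaml(x) else yaml::yaml.load(x)
  model_spec(outcome = l$outcome, regressors = unlist(l$regressors),
             fe = unlist(l$fe), cluster = l$cluster,
             demean_tol = l$demean_tol, max_sweeps = l$max_sweeps,
             dof = l$dof %||% "nested")
}
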