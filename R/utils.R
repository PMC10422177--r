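# Calendar-month helpers. Months are "YYYY-MM" strings throughout; event time
# is a plain integer difference of positions on the configured month grid.

#' Sequence of calendar months
#'
#' @param from,to Months as `"YYYY-MM"` strings, inclusive.
#' @return Character vector of consecutive months.
#' @examples
#' month_seq("2019-01", "2019-03")
#' @export
month_seq <- function(from, to) {
  f <- parse_month(from)
  t <- parse_month(to)
  if (t$idx < f$idx) stop("`to` precedes `from`", call. = FALSE)
  idx <- seq(f$idx, t$idx)
  sprintf("%d-%02d", idx %/% 12L, idx %% 12L + 1L)
}

# absolute month index (year*12 + month-1) plus components
parse_month <- function(m) {
  ok <- grepl("^\\d{4}-\\d{2}$", m)
  if (!all(ok)) {
    stop("malformed month(s): ", paste(m[!ok], collapse = ", "), call. = FALSE)
  }
  y <- as.integer(substr(m, 1L, 4L))
  mo <- as.integer(substr(m, 6L, 7L))
  if (any(mo < 1L | mo > 12L)) stop("month out of range in: ", paste(m[mo < 1L | mo > 12L], collapse = ", "), call. = FALSE)
  list(year = y, month = mo, idx = y * 12L + mo - 1L)
}

#' Position of months on a month grid
#'
#' @param m Character vector of `"YYYY-MM"` months.
#' @param grid Character vector of consecutive months (the data window).
#' @return Integer positions (1-based) of `m` on `grid`; months outside the
#'   grid are an error.
#' @export
month_index <- function(m, grid) {
  i <- match(m, grid)
  if (anyNA(i)) {
    stop("month(s) outside the data window: ",
         paste(unique(m[is.na(i)]), collapse = ", "), call. = FALSE)
  }
  i
}

# days in a "YYYY-MM" month (2019 has no leap concerns but keep it general)
days_in_month <- function(m) {
  p <- parse_month(m)
  dim <- c(31L, 28L, 31L, 30L, 31L, 30L, 31L, 31L, 30L, 31L, 30L, 31L)
  d <- dim[p$month]
  leap <- (p$year %% 4L == 0L & p$year %% 100L != 0L) | p$year %% 400L == 0L
  d[p$month == 2L & leap] <- 29L
  d
}

# first hour (POSIXct, UTC) of a month
month_start <- function(m) {
  as.POSIXct(paste0(m, "-01 00:00:00"), tz = "UTC")
}

# Derive a stage-specific seed from a root seed so each pipeline stage has an
# independent, reproducible stream. Kept below 2^31 - 1.
stage_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483629)
}

# named-numeric effects map validation: names are nonzero integers (r = 0 is
# the reference period and must not carry an injected effect)
check_effects_map <- function(x, what) {
  if (length(x) == 0L) return(invisible(x))
  if (is.null(names(x)) || any(names(x) == "")) {
    stop(what, " must be a named numeric vector (names = event times)", call. = FALSE)
  }
  r <- suppressWarnings(as.integer(names(x)))
  if (anyNA(r)) stop(what, " names must be integers", call. = FALSE)
  if (any(r == 0L)) {
    stop(what, " must not contain an entry for r = 0 (the reference period)",
         call. = FALSE)
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
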