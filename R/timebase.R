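# Discrete 1-minute simulation clock and calendar arithmetic.

#' Weekday names in simulation order
#'
#' Day indices cycle through this vector with period 7, starting at the
#' configured start weekday on day 0.
#'
#' @format Character vector of length 7, `"Sunday"` .. `"Saturday"`.
#' @export
WEEKDAY_NAMES <- c("Sunday", "Monday", "Tuesday", "Wednesday", "Thursday",
                   "Friday", "Saturday")

#' Create a simulation clock
#'
#' A simulation clock anchors tick 0 (minutes since simulation start) to a
#' weekday and a wall-clock time on day 0. Time then advances in whole
#' minutes; there are no time zones or daylight-saving transitions.
#'
#' @param start_weekday Weekday name of day 0 (one of [WEEKDAY_NAMES]).
#' @param start_clock_min Minutes past midnight on day 0 at tick 0
#'   (integer in 0..1439). The default 960 is 16:00.
#' @return An object of class `sim_clock`.
#' @examples
#' clk <- sim_clock("Sunday", 960)
#' to_clock(480, clk) # 8 h later: day 1, Monday, midnight
#' @export
sim_clock <- function(start_weekday = "Sunday", start_clock_min = 960L) {
  start_weekday <- match.arg(start_weekday, WEEKDAY_NAMES)
  start_clock_min <- as.integer(start_clock_min)
  if (length(start_clock_min) != 1L || is.na(start_clock_min) ||
      start_clock_min < 0L || start_clock_min > 1439L) {
    stop("`start_clock_min` must be a single integer in 0..1439",
         call. = FALSE)
  }
  structure(list(start_weekday = start_weekday,
                 start_clock_min = start_clock_min),
            class = "sim_clock")
}

#' @export
print.sim_clock <- function(x, ...) {
  cat("<sim_clock> day 0 starts ", x$start_weekday, " ",
      format_hhmm(x$start_clock_min), "\n", sep = "")
  invisible(x)
}

#' Map simulation minutes to calendar day, weekday and clock time
#'
#' @param t_min Non-negative integer minutes since simulation start
#'   (vectorized).
#' @param clock A [sim_clock()].
#' @return A list with components `day` (integer day index, day 0 is the
#'   start day), `weekday` (character) and `clock_min` (minutes past
#'   midnight, 0..1439).
#' @export
to_clock <- function(t_min, clock = sim_clock()) {
  t_min <- as.integer(t_min)
  if (any(is.na(t_min)) || any(t_min < 0L)) {
    stop("`t_min` must be non-negative", call. = FALSE)
  }
  abs_min <- clock$start_clock_min + t_min
  day <- abs_min %/% 1440L
  wd0 <- match(clock$start_weekday, WEEKDAY_NAMES) - 1L
  list(day = day,
       weekday = WEEKDAY_NAMES[(wd0 + day) %% 7L + 1L],
       clock_min = abs_min %% 1440L)
}

#' Format minutes as "HH:MM"
#'
#' Clock times use 0..1439; durations may exceed 1439 and format as total
#' elapsed hours:minutes (e.g. 1500 -> `"25:00"`).
#'
#' @param minutes Non-negative integer minutes (vectorized).
#' @return Character vector of zero-padded `"HH:MM"` strings.
#' @examples
#' format_hhmm(c(0, 495, 1439))
#' @export
format_hhmm <- function(minutes) {
  minutes <- as.integer(round(minutes))
  if (any(is.na(minutes)) || any(minutes < 0L)) {
    stop("`minutes` must be non-negative", call. = FALSE)
  }
  sprintf("%02d:%02d", minutes %/% 60L, minutes %% 60L)
}

#' Parse "HH:MM" strings into minutes
#'
#' Inverse of [format_hhmm()].
#'
#' @param x Character vector of `"HH:MM"` strings.
#' @return Integer minutes.
#' @export
parse_hhmm <- function(x) {
  ok <- grepl("^[0-9]{1,3}:[0-5][0-9]$", x)
  if (any(!ok)) {
    stop("malformed time string(s): ",
         paste(utils::head(x[!ok], 3L), collapse = ", "), call. = FALSE)
  }
  parts <- strsplit(x, ":", fixed = TRUE)
  vapply(parts, function(p) as.integer(p[1L]) * 60L + as.integer(p[2L]),
         integer(1))
}

#' Is a weekday a workday?
#'
#' Workdays are fixed to Monday through Friday.
#'
#' @param weekday Character vector of weekday names.
#' @return Logical vector.
#' @export
is_workday <- function(weekday) {
  weekday %in% WEEKDAY_NAMES[2:6]
}

# Round to nearest integer, ties away from zero upward (0.5 -> 1). Base
# round() uses banker's rounding, which would make tick-boundary alignment
# depend on parity.
round_half_up <- function(x) {
  as.integer(floor(x + 0.5))
}

#' Convert decimal hours to whole minutes
#'
#' Sampled activity parameters are expressed in decimal hours; the simulation
#' clock ticks in whole minutes, so every realization is rounded to the
#' nearest minute (ties up) before it enters the schedule.
#'
#' @param h Numeric hours.
#' @return Integer minutes.
#' @export
hours_to_min <- function(h) {
  round_half_up(h * 60)
}
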