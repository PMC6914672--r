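# The seven activity definitions, their parameterization, and
# truncated-normal sampling of activity parameters.

ACTIVITY_IDS <- c("sleep", "eat_breakfast", "commute_to_work", "work",
                  "eat_lunch", "commute_from_work", "eat_dinner")

ACTIVITY_LABELS <- c(sleep = "Sleep",
                     eat_breakfast = "Eat breakfast",
                     commute_to_work = "Commute to work",
                     work = "Work",
                     eat_lunch = "Eat lunch",
                     commute_from_work = "Commute from work",
                     eat_dinner = "Eat dinner",
                     idle = "Idle")

# Which need each activity serves.
ACTIVITY_NEED <- c(sleep = "Rest",
                   eat_breakfast = "Hunger",
                   commute_to_work = "Travel",
                   work = "Income",
                   eat_lunch = "Hunger",
                   commute_from_work = "Travel",
                   eat_dinner = "Hunger")

#' Activity definitions
#'
#' The seven modeled activities with the need each serves, the environments
#' in which it may run, interruptibility, which activities may interrupt it,
#' which of start/end/duration are directly parameterized, and linkage to
#' other activities. Work is the only interruptible activity and eating
#' lunch the only activity that may interrupt it; the morning commute ends
#' at the start of work and the evening commute starts at the end of work.
#'
#' @return A data frame with one row per activity and list-columns
#'   `environments`, `may_interrupt` and `parameterized`.
#' @examples
#' activity_specs()[, c("id", "need", "interruptible")]
#' @export
activity_specs <- function() {
  data.frame(
    id = ACTIVITY_IDS,
    label = unname(ACTIVITY_LABELS[ACTIVITY_IDS]),
    need = unname(ACTIVITY_NEED[ACTIVITY_IDS]),
    environments = I(list("Residence",
                          "Residence",
                          "Outdoors",
                          "Workplace",
                          c("Residence", "Workplace"),
                          "Outdoors",
                          "Residence")),
    interruptible = c(FALSE, FALSE, FALSE, TRUE, FALSE, FALSE, FALSE),
    may_interrupt = I(list(character(0), character(0), character(0),
                           character(0), "work", character(0),
                           character(0))),
    parameterized = I(list(c("start", "end"),
                           c("start", "duration"),
                           "duration",
                           c("start", "end"),
                           c("start", "duration"),
                           "duration",
                           c("start", "duration"))),
    link = c(NA, NA, "ends_at_start_of:work", NA, NA,
             "starts_at_end_of:work", NA),
    stringsAsFactors = FALSE
  )
}

#' Distribution of one activity parameter
#'
#' Each directly parameterized activity parameter (a start time, end time or
#' duration, in decimal hours) follows its own normal distribution with mean
#' `mu` (the agent's long-term average) and standard deviation `sigma` (its
#' day-to-day variation), truncated to one standard deviation on either side
#' of the mean.
#'
#' @param mu Mean in decimal hours (clock hours for times, elapsed hours for
#'   durations).
#' @param sigma Standard deviation in hours, `>= 0`; `sigma = 0` gives the
#'   constant `mu`.
#' @return An object of class `param_dist`.
#' @export
param_dist <- function(mu, sigma) {
  if (!is.numeric(mu) || length(mu) != 1L || is.na(mu)) {
    stop("`mu` must be a single number", call. = FALSE)
  }
  if (!is.numeric(sigma) || length(sigma) != 1L || is.na(sigma) ||
      sigma < 0) {
    stop("`sigma` must be a single number >= 0", call. = FALSE)
  }
  structure(list(mu = mu, sigma = sigma), class = "param_dist")
}

#' @export
print.param_dist <- function(x, ...) {
  cat(sprintf("<param_dist> mu = %g h, sigma = %g h\n", x$mu, x$sigma))
  invisible(x)
}

#' Sample activity parameters
#'
#' Draws from `Normal(mu, sigma)` truncated to `[mu - sigma, mu + sigma]`
#' by inverse-CDF sampling, so every draw lies within one standard deviation
#' of the mean. With `sigma = 0` the constant `mu` is returned without
#' consuming random numbers. Draws are in decimal hours; they are rounded to
#' whole minutes ([hours_to_min()]) only where they enter the integer-minute
#' simulation clock, so the truncation bounds hold exactly for the values
#' returned here.
#'
#' @param dist A [param_dist()].
#' @param n Number of draws.
#' @return Numeric vector of `n` draws in hours.
#' @examples
#' set.seed(1)
#' range(sample_param(param_dist(8, 2.5), 1000)) # within [5.5, 10.5]
#' @export
sample_param <- function(dist, n = 1L) {
  if (!inherits(dist, "param_dist")) {
    stop("`dist` must be a param_dist", call. = FALSE)
  }
  if (dist$sigma == 0) {
    return(rep(dist$mu, n))
  }
  u <- stats::runif(n, stats::pnorm(-1), stats::pnorm(1))
  dist$mu + dist$sigma * stats::qnorm(u)
}
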