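# Analytic event-schedule oracle for zero-variance configurations.

#' Analytic weekly schedule for a zero-variance configuration
#'
#' Computes the activity diary of a configuration with every `sigma = 0` by
#' plain event arithmetic, with no tick loop: triggers fall at the mean
#' parameter values, every activity starts exactly at its need's threshold
#' so realized durations equal the configured minimum recovery times, and
#' activity links hold by construction (the morning commute ends at the
#' work start; the evening commute starts at the work end). It serves as an
#' independent check of [run_simulation()], which must reproduce its output
#' minute for minute on such configurations.
#'
#' The construction assumes the mean schedule is well ordered within a day
#' (wake before breakfast, breakfast finished before the commute urge,
#' lunch inside the work block, home before dinner, dinner finished before
#' bedtime, and a day-0 start in the evening after any lunch/work block);
#' it refuses configurations with any `sigma > 0` or with means violating
#' those orderings.
#'
#' @param config A [sim_config()] with all `sigma = 0`.
#' @return An `activity_diary` data frame with the same columns and
#'   attributes as [run_simulation()] (minus the trace).
#' @examples
#' oracle <- oracle_schedule(zero_variance(sim_config()))
#' subset(oracle, day == 1)
#' @export
oracle_schedule <- function(config) {
  validate_config(config)
  sig <- unlist(lapply(config$params, function(pd) {
    vapply(pd, function(d) d$sigma, numeric(1))
  }))
  if (any(sig > 0)) {
    stop("oracle_schedule() requires every sigma = 0", call. = FALSE)
  }
  p <- config$params
  has_work <- !is.null(p$work)
  scm <- config$start_clock_min
  wd0 <- match(config$start_weekday, WEEKDAY_NAMES) - 1L
  horizon <- config$horizon_min
  mu_min <- function(id, par) hours_to_min(p[[id]][[par]]$mu)

  s_s <- mu_min("sleep", "start")
  s_e <- mu_min("sleep", "end")
  sleep_dur <- (s_e - s_s) %% 1440L
  if (sleep_dur == 0L) sleep_dur <- 1440L
  b_s <- mu_min("eat_breakfast", "start")
  b_d <- max(1L, mu_min("eat_breakfast", "duration"))
  l_s <- mu_min("eat_lunch", "start")
  l_d <- max(1L, mu_min("eat_lunch", "duration"))
  d_s <- mu_min("eat_dinner", "start")
  d_d <- max(1L, mu_min("eat_dinner", "duration"))
  if (has_work) {
    w_s <- mu_min("work", "start")
    w_e <- mu_min("work", "end")
    c1 <- max(1L, mu_min("commute_to_work", "duration"))
    c2 <- max(1L, mu_min("commute_from_work", "duration"))
    trig <- w_s - c1
  }

  wake <- s_e
  req <- function(ok, what) {
    if (!ok) stop("oracle_schedule() cannot order this schedule: ", what,
                  call. = FALSE)
  }
  req(wake <= b_s, "wake must precede breakfast")
  req(b_s + b_d <= l_s, "breakfast must finish before lunch")
  req(l_s + l_d <= d_s, "lunch must finish before dinner")
  req(d_s + d_d <= s_s, "dinner must finish before bedtime")
  if (has_work) {
    req(b_s + b_d <= trig, "breakfast must finish before the commute urge")
    req(w_s < l_s && l_s + l_d < w_e, "lunch must fall inside work")
    req(w_e + c2 <= d_s, "the agent must be home before dinner")
  }
  day0_workday <- ((wd0 + 0L) %% 7L) %in% 1:5
  req(scm < s_s, "day-0 start must precede bedtime")
  req(scm > l_s + l_d, "day-0 start must follow the lunch block")
  req(scm != d_s, "day-0 start must not coincide with dinner")
  if (has_work && day0_workday) {
    req(scm > w_e + c2, "day-0 start must follow the workday")
  }

  rows_start <- integer(0); rows_end <- integer(0)
  rows_act <- character(0); rows_env <- character(0)
  add <- function(a, b, id, ev) {
    if (b > a) {
      k <- length(rows_start) + 1L
      rows_start[k] <<- a; rows_end[k] <<- b
      rows_act[k] <<- id; rows_env[k] <<- ev
    }
  }
  at <- function(day, clock) day * 1440L + clock - scm

  # day 0: evening warm-up (dinner if still ahead, then the night's sleep)
  cur <- 0L
  if (d_s >= scm) {
    add(cur, at(0L, d_s), "idle", "Residence")
    add(at(0L, d_s), at(0L, d_s + d_d), "eat_dinner", "Residence")
    cur <- at(0L, d_s + d_d)
  }
  add(cur, at(0L, s_s), "idle", "Residence")
  sleep_at <- at(0L, s_s)

  day <- 0L
  while (sleep_at < horizon) {
    add(sleep_at, min(sleep_at + sleep_dur, horizon), "sleep", "Residence")
    cur <- sleep_at + sleep_dur
    if (cur >= horizon) break
    day <- day + 1L
    workday <- ((wd0 + day) %% 7L) %in% 1:5 && has_work
    add(cur, at(day, b_s), "idle", "Residence")
    add(at(day, b_s), at(day, b_s + b_d), "eat_breakfast", "Residence")
    cur <- at(day, b_s + b_d)
    if (workday) {
      add(cur, at(day, trig), "idle", "Residence")
      add(at(day, trig), at(day, w_s), "commute_to_work", "Outdoors")
      add(at(day, w_s), at(day, l_s), "work", "Workplace")
      add(at(day, l_s), at(day, l_s + l_d), "eat_lunch", "Workplace")
      add(at(day, l_s + l_d), at(day, w_e), "work", "Workplace")
      add(at(day, w_e), at(day, w_e + c2), "commute_from_work", "Outdoors")
      cur <- at(day, w_e + c2)
    } else {
      add(cur, at(day, l_s), "idle", "Residence")
      add(at(day, l_s), at(day, l_s + l_d), "eat_lunch", "Residence")
      cur <- at(day, l_s + l_d)
    }
    add(cur, at(day, d_s), "idle", "Residence")
    add(at(day, d_s), at(day, d_s + d_d), "eat_dinner", "Residence")
    add(at(day, d_s + d_d), at(day, s_s), "idle", "Residence")
    sleep_at <- at(day, s_s)
  }

  keep <- rows_start < horizon
  rows_start <- rows_start[keep]
  rows_end <- pmin(rows_end[keep], horizon)
  rows_act <- rows_act[keep]; rows_env <- rows_env[keep]

  dayv <- (scm + rows_start) %/% 1440L
  diary <- data.frame(
    day = dayv,
    start = (scm + rows_start) %% 1440L,
    end = (scm + rows_end) %% 1440L,
    duration = rows_end - rows_start,
    activity = unname(ACTIVITY_LABELS[rows_act]),
    weekday = WEEKDAY_NAMES[(wd0 + dayv) %% 7L + 1L],
    environment = rows_env,
    stringsAsFactors = FALSE
  )
  class(diary) <- c("activity_diary", "data.frame")
  attr(diary, "horizon_min") <- horizon
  attr(diary, "start_weekday") <- config$start_weekday
  attr(diary, "start_clock_min") <- scm
  diary
}
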