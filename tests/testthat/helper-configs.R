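# Shared fixtures: configurations used across tests, built in code.

# The default week-long case study with every sigma forced to zero.
det_config <- function(...) {
  zero_variance(sim_config(...))
}

# A battery of well-ordered zero-variance configurations exercising shifted
# meal times, changed durations, different work hours, a non-Sunday start,
# and a work-free (hence commute-free) schedule.
oracle_battery <- function() {
  shifted <- sim_config()
  shifted$params$eat_breakfast$start <- param_dist(8, 0)
  shifted$params$eat_breakfast$duration <- param_dist(1 / 3, 0)
  shifted$params$eat_lunch$start <- param_dist(13, 0)
  shifted$params$eat_dinner$start <- param_dist(18.5, 0)
  shifted$params$eat_dinner$duration <- param_dist(1, 0)

  hours <- sim_config()
  hours$params$work$start <- param_dist(8, 0)
  hours$params$work$end <- param_dist(16.5, 0)
  hours$params$commute_to_work$duration <- param_dist(0.25, 0)
  hours$params$commute_from_work$duration <- param_dist(0.5, 0)
  hours$params$eat_breakfast$start <- param_dist(7.25, 0)
  hours$params$sleep$start <- param_dist(21.5, 0)
  hours$params$sleep$end <- param_dist(6.5, 0)

  midweek <- sim_config(start_weekday = "Wednesday",
                        start_clock_min = parse_hhmm("18:30"), days = 9)

  no_work <- sim_config()
  no_work$params$work <- NULL
  no_work$params$commute_to_work <- NULL
  no_work$params$commute_from_work <- NULL

  lapply(list(default = sim_config(), shifted = shifted, hours = hours,
              midweek = midweek, no_work = no_work),
         zero_variance)
}

diary_cols <- function(d) {
  as.data.frame(d)[c("day", "start", "end", "duration", "activity",
                     "weekday", "environment")]
}

# wake events: (day the agent wakes on, wake clock minute) from sleep rows
wake_times <- function(diary) {
  sl <- diary[diary$activity == "Sleep", , drop = FALSE]
  spans_midnight <- sl$start > sl$end
  data.frame(day = sl$day + ifelse(spans_midnight, 1L, 0L),
             wake_min = sl$end)
}
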