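# Minute-stepped simulation driver and the needs-based decision loop.

#' Run a needs-based activity simulation
#'
#' Moves one agent through time a minute at a time. Each tick the engine
#' (1) completes any activity whose end time has arrived, applying its
#' end-of-activity effects (satiation reset to 1, next occurrence sampled,
#' decay re-aimed, environment relocation for commutes); (2) fires
#' step-function triggers for the scheduled needs (Income at the sampled
#' work start, Travel at the work start minus the commute duration in the
#' morning and at the work end in the evening); (3) when the agent is idle
#' or in an interruptible activity, collects advertisements from the objects
#' reachable from the current environment and starts the activity with the
#' highest strictly positive score (ties broken by the fixed need priority
#' Travel > Income > Rest > Hunger, then lexical activity id); and
#' (4) leaves linear satiations to evolve at their anchored constant rates.
#' Only work is interruptible, and only eating lunch may interrupt it; work
#' resumes afterwards until its sampled end time.
#'
#' Linear satiations are evaluated in closed form from their last anchor
#' point (value 1 at the end of the satisfying activity, constant rate per
#' hour), not by per-tick accumulation, so a decay aimed at a future
#' trigger lands on the threshold exactly at that minute.
#'
#' Initialization at tick 0 sets all satiations to 1 and samples the first
#' occurrence of every activity in a fixed order (sleep, breakfast, lunch,
#' dinner, work, commute to work, commute from work), so a given seed fixes
#' the full trace.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed (defaults to `config$seed`); `NULL` leaves the
#'   random number generator state untouched.
#' @param trace If `TRUE`, attach a data frame of every sampled activity
#'   parameter (attribute `"trace"`: columns `t`, `day`, `activity`,
#'   `parameter`, `value` in hours) to the returned diary.
#' @return An `activity_diary` data frame with columns `day`, `start`,
#'   `end` (minutes past midnight), `duration` (minutes), `activity`,
#'   `weekday`, `environment`. Entries are contiguous, non-overlapping, and
#'   span the full horizon, with idle time as first-class rows. Attributes:
#'   `horizon_min`, `start_weekday`, `start_clock_min`, `satiation_range`
#'   (the min and max satiation observed over every need and tick).
#' @examples
#' diary <- run_simulation(zero_variance(sim_config()), seed = 1)
#' head(diary)
#' @export
run_simulation <- function(config = sim_config(), seed = config$seed,
                           trace = FALSE) {
  validate_config(config)
  if (!is.null(seed)) set.seed(as.integer(seed))

  lam <- config$lambda
  eps <- config$epsilon
  tol <- 1e-9
  eta_t <- config$eta[["travel"]]
  eta_i <- config$eta[["income"]]
  p <- config$params
  scm <- config$start_clock_min
  wd0 <- match(config$start_weekday, WEEKDAY_NAMES) - 1L
  horizon <- config$horizon_min
  has_work <- !is.null(p$work)
  world <- build_world(config)
  meal_ids <- c("eat_breakfast", "eat_lunch", "eat_dinner")

  day_of <- function(t) (scm + t) %/% 1440L
  is_work_t <- function(t) {
    w <- (wd0 + day_of(t)) %% 7L
    w >= 1L && w <= 5L
  }
  # earliest absolute minute (>) t whose clock time is clock_min
  next_at_clock <- function(t, clock_min, strict = TRUE) {
    cand <- day_of(t) * 1440L + clock_min - scm
    if (if (strict) cand <= t else cand < t) cand <- cand + 1440L
    cand
  }
  next_day_at_clock <- function(t, clock_min) {
    (day_of(t) + 1L) * 1440L + clock_min - scm
  }
  next_workday_at <- function(t, clock_min) {
    a <- next_at_clock(t, clock_min)
    while (!is_work_t(a)) a <- a + 1440L
    a
  }

  # ---- sampled-parameter trace -------------------------------------------
  tr_t <- integer(0); tr_act <- character(0)
  tr_par <- character(0); tr_val <- numeric(0)
  samp <- function(act, par, t) {
    v <- sample_param(p[[act]][[par]])
    if (trace) {
      k <- length(tr_t) + 1L
      tr_t[k] <<- t; tr_act[k] <<- act; tr_par[k] <<- par; tr_val[k] <<- v
    }
    v
  }

  # ---- linear need state: closed-form evaluation from an anchor ----------
  # value(t) = clamp01(anchor_n + rate * (t - anchor_t) / 60); values within
  # numerical noise of the threshold snap to it so that a decay aimed at a
  # trigger minute scores identically to an exact threshold hit
  rest_a_t <- 0L; rest_a_n <- 1; rest_rate <- 0
  hun_a_t <- 0L; hun_a_n <- 1; hun_rate <- 0
  snap_lam <- function(n) if (abs(n - lam) <= tol) lam else n
  cur_rest <- function(t) {
    snap_lam(clamp01(rest_a_n + rest_rate * (t - rest_a_t) / 60))
  }
  cur_hun <- function(t) {
    snap_lam(clamp01(hun_a_n + hun_rate * (t - hun_a_t) / 60))
  }
  inc_n <- 1; trav_n <- 1
  inc_trig <- Inf; trav_trig <- Inf

  # ---- pending occurrences ------------------------------------------------
  sleep_start <- NA_integer_; sleep_dur <- NA_integer_
  meal_start <- rep(NA_integer_, 3L); meal_dur <- rep(NA_integer_, 3L)
  work_start <- Inf; work_end_pend <- Inf
  cto_dur <- NA_integer_; cfrom_dur <- NA_integer_

  sample_sleep <- function(t, strict = TRUE) {
    s <- samp("sleep", "start", t)
    e <- samp("sleep", "end", t)
    sm <- hours_to_min(s); em <- hours_to_min(e)
    sleep_start <<- next_at_clock(t, sm, strict)
    d <- (em - sm) %% 1440L
    sleep_dur <<- if (d == 0L) 1440L else d
    # anchor Rest at full satiation, aimed to reach lambda at the next start
    rest_a_t <<- t; rest_a_n <<- 1
    rest_rate <<- -(1 - lam) / (max(1L, sleep_start - t) / 60)
  }
  sample_meal <- function(i, t, same_day_ok = FALSE) {
    id <- meal_ids[i]
    s <- samp(id, "start", t)
    d <- samp(id, "duration", t)
    sm <- hours_to_min(s)
    meal_start[i] <<- if (same_day_ok) next_at_clock(t, sm, strict = FALSE)
                      else next_day_at_clock(t, sm)
    meal_dur[i] <<- max(1L, hours_to_min(d))
  }
  aim_hunger <- function(t) {
    # anchor Hunger at full satiation, aimed at whichever meal comes next
    hun_a_t <<- t; hun_a_n <<- 1
    hun_rate <<- -(1 - lam) / (max(1L, min(meal_start) - t) / 60)
  }
  sample_work <- function(t) {
    s <- samp("work", "start", t)
    e <- samp("work", "end", t)
    sm <- hours_to_min(s); em <- hours_to_min(e)
    ws <- next_workday_at(t, sm)
    work_start <<- ws
    work_end_pend <<- ws - sm + em
    inc_trig <<- ws
  }
  sample_cto <- function(t) {
    cto_dur <<- max(1L, hours_to_min(samp("commute_to_work", "duration", t)))
  }
  sample_cfrom <- function(t) {
    cfrom_dur <<- max(1L, hours_to_min(samp("commute_from_work", "duration",
                                            t)))
  }

  # ---- diary segments -----------------------------------------------------
  cap <- 256L; n_rows <- 0L
  r_start <- integer(cap); r_end <- integer(cap)
  r_act <- character(cap); r_env <- character(cap)
  seg_start <- 0L; seg_act <- "idle"; seg_env <- "Residence"
  push_seg <- function(t_now, new_act, new_env) {
    if (t_now > seg_start) {
      n_rows <<- n_rows + 1L
      if (n_rows > cap) {
        cap <<- cap * 2L
        length(r_start) <<- cap; length(r_end) <<- cap
        length(r_act) <<- cap; length(r_env) <<- cap
      }
      r_start[n_rows] <<- seg_start; r_end[n_rows] <<- t_now
      r_act[n_rows] <<- seg_act; r_env[n_rows] <<- seg_env
    }
    seg_start <<- t_now; seg_act <<- new_act; seg_env <<- new_env
  }

  # ---- agent state --------------------------------------------------------
  act <- "idle"; act_end <- NA_integer_; env <- "Residence"

  start_activity <- function(id, t) {
    if (id == "sleep") {
      n0 <- cur_rest(t)
      m <- (1 - lam) / (sleep_dur / 60)
      act_end <<- t + max(1L, round_half_up((1 - n0) / m * 60))
      rest_a_t <<- t; rest_a_n <<- n0; rest_rate <<- m
    } else if (id %in% meal_ids) {
      i <- match(id, meal_ids)
      n0 <- cur_hun(t)
      m <- (1 - lam) / (meal_dur[i] / 60)
      act_end <<- t + max(1L, round_half_up((1 - n0) / m * 60))
      hun_a_t <<- t; hun_a_n <<- n0; hun_rate <<- m
    } else if (id == "commute_to_work") {
      env <<- "Outdoors"
      act_end <<- t + cto_dur
    } else if (id == "commute_from_work") {
      env <<- "Outdoors"
      act_end <<- t + cfrom_dur
    } else if (id == "work") {
      act_end <<- work_end_pend    # end-anchored: oversleeping shortens work
    }
    act <<- id
    push_seg(t, id, env)
  }

  finish_activity <- function(t) {
    if (act == "sleep") {
      sample_sleep(t)              # re-anchors Rest at 1, aimed at next start
    } else if (act %in% meal_ids) {
      i <- match(act, meal_ids)
      sample_meal(i, t)
      # a meal whose scheduled start has passed unmet (e.g. skipped
      # breakfast) rolls forward to the next day
      for (j in seq_len(3L)[-i]) {
        if (meal_start[j] <= t) sample_meal(j, t)
      }
      aim_hunger(t)
    } else if (act == "commute_to_work") {
      trav_n <<- 1
      env <<- "Workplace"
      sample_cto(t)
    } else if (act == "commute_from_work") {
      trav_n <<- 1
      env <<- "Residence"
      sample_cfrom(t)
      trav_trig <<- work_start - cto_dur
    } else if (act == "work") {
      inc_n <<- 1
      sample_work(t)
      trav_n <<- eta_t             # the evening commute starts with work's end
    }
    act <<- "idle"; act_end <<- NA_integer_
    push_seg(t, "idle", env)
  }

  decide <- function(t, rest_n, hun_n) {
    ns <- c(Rest = rest_n, Hunger = hun_n, Income = inc_n, Travel = trav_n)
    avail <- list()
    if (env == "Residence") {
      if (rest_n <= lam) {
        avail$sleep <- list(available = TRUE, duration_min = sleep_dur)
      }
      for (i in seq_len(3L)) {
        if (t >= meal_start[i]) {
          avail[[meal_ids[i]]] <- list(available = TRUE,
                                       duration_min = meal_dur[i])
        }
      }
      if (has_work && trav_n <= lam) {
        avail$commute_to_work <- list(available = TRUE,
                                      duration_min = cto_dur)
      }
    } else if (env == "Workplace") {
      if (t >= meal_start[2L]) {
        avail$eat_lunch <- list(available = TRUE,
                                duration_min = meal_dur[2L])
      }
      if (has_work && inc_n <= lam && t < work_end_pend) {
        avail$work <- list(available = TRUE)
      }
      if (has_work && trav_n <= lam) {
        avail$commute_from_work <- list(available = TRUE,
                                        duration_min = cfrom_dur)
      }
    }
    if (length(avail) == 0L) return(NULL)
    # transport is reachable from the environments adjacent to outdoors:
    # performing a commute begins by stepping outside
    objs <- world[[env]]$objects
    if (env != "Outdoors") objs <- c(objs, world$Outdoors$objects)
    ads <- do.call(rbind, lapply(objs, advertise, needs_state = ns, t = t,
                                 availability = avail, lambda_thr = lam,
                                 epsilon = eps))
    ads <- ads[ads$score > 0, , drop = FALSE]
    if (nrow(ads) == 0L) return(NULL)
    pri <- c(Travel = 1L, Income = 2L, Rest = 3L, Hunger = 4L)
    ads <- ads[order(-ads$score, pri[ads$need], ads$activity), ,
               drop = FALSE]
    ads$activity[1L]
  }

  # ---- initialization -----------------------------------------------------
  sample_sleep(0L, strict = FALSE)
  for (i in seq_len(3L)) sample_meal(i, 0L, same_day_ok = TRUE)
  aim_hunger(0L)
  if (has_work) {
    sample_work(0L)
    sample_cto(0L)
    sample_cfrom(0L)
    trav_trig <- work_start - cto_dur
  }

  sat_min <- 1; sat_max <- 1

  # ---- main loop ----------------------------------------------------------
  for (t in 0:(horizon - 1L)) {
    if (!is.na(act_end) && t >= act_end) finish_activity(t)
    if (t >= inc_trig) { inc_n <- eta_i; inc_trig <- Inf }
    if (t >= trav_trig) { trav_n <- eta_t; trav_trig <- Inf }
    # a work occurrence that was never reached before its end time lapses
    if (has_work && act != "work" && inc_n <= lam &&
        t >= work_end_pend) {
      inc_n <- 1
      sample_work(t)
      trav_n <- eta_t
    }
    rest_n <- cur_rest(t)
    hun_n <- cur_hun(t)
    if (act == "idle") {
      consider <- if (env == "Residence") {
        rest_n <= lam ||
          (hun_n <= lam && t >= min(meal_start)) ||
          trav_n <= lam
      } else if (env == "Workplace") {
        (hun_n <= lam && t >= meal_start[2L]) ||
          inc_n <= lam || trav_n <= lam
      } else FALSE
      if (consider) {
        chosen <- decide(t, rest_n, hun_n)
        if (!is.null(chosen)) start_activity(chosen, t)
      }
    } else if (act == "work") {
      # work is interruptible, and only by eating lunch
      if (hun_n <= lam && t >= meal_start[2L] &&
          need_score(hun_n, 1, lam, eps) > 0) {
        start_activity("eat_lunch", t)
      }
    }
    lo <- min(rest_n, hun_n, inc_n, trav_n)
    hi <- max(rest_n, hun_n, inc_n, trav_n)
    if (lo < sat_min) sat_min <- lo
    if (hi > sat_max) sat_max <- hi
  }
  push_seg(horizon, "idle", env)

  # ---- assemble the diary -------------------------------------------------
  idx <- seq_len(n_rows)
  starts <- r_start[idx]; ends <- r_end[idx]
  day <- (scm + starts) %/% 1440L
  diary <- data.frame(
    day = day,
    start = (scm + starts) %% 1440L,
    end = (scm + ends) %% 1440L,
    duration = ends - starts,
    activity = unname(ACTIVITY_LABELS[r_act[idx]]),
    weekday = WEEKDAY_NAMES[(wd0 + day) %% 7L + 1L],
    environment = r_env[idx],
    stringsAsFactors = FALSE
  )
  class(diary) <- c("activity_diary", "data.frame")
  attr(diary, "horizon_min") <- horizon
  attr(diary, "start_weekday") <- config$start_weekday
  attr(diary, "start_clock_min") <- scm
  attr(diary, "satiation_range") <- c(min = sat_min, max = sat_max)
  if (trace) {
    attr(diary, "trace") <- data.frame(
      t = tr_t,
      day = (scm + tr_t) %/% 1440L,
      activity = tr_act,
      parameter = tr_par,
      value = tr_val,
      stringsAsFactors = FALSE
    )
  }
  diary
}
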