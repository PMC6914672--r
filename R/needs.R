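# Satiation dynamics and decision mathematics: decay, recovery, step
# satiation, activity duration, urgency weight, and advertisement score.

#' Linear satiation decay rate
#'
#' For a need whose satiation declines linearly with time since it was last
#' satisfied, the constant decay rate is `-(1 - lambda) / dt_decay`: starting
#' from full satiation (n = 1), the need reaches its threshold `lambda` after
#' exactly `dt_decay` hours.
#'
#' @param lambda_thr Threshold satiation in (0, 1) at which the agent starts
#'   seeking activities for the need.
#' @param dt_decay Hours (> 0) from full satiation to the threshold.
#' @return Decay rate per hour (strictly negative).
#' @examples
#' decay_rate(0.2, 16)   # -0.05 per hour
#' decay_rate(0.2, 3.5)  # about -0.2286 per hour
#' @export
decay_rate <- function(lambda_thr, dt_decay) {
  check_lambda(lambda_thr)
  if (any(dt_decay <= 0)) stop("`dt_decay` must be > 0", call. = FALSE)
  -(1 - lambda_thr) / dt_decay
}

#' Linear satiation recovery rate
#'
#' While an activity satisfies a linearly modeled need, satiation rises at the
#' constant rate `(1 - lambda) / dt_recover`: an agent starting exactly at the
#' threshold is fully satisfied after `dt_recover` hours.
#'
#' @inheritParams decay_rate
#' @param dt_recover Hours (> 0) needed to go from the threshold to full
#'   satiation.
#' @return Recovery rate per hour (strictly positive).
#' @examples
#' recovery_rate(0.2, 0.5) # 1.6 per hour
#' @export
recovery_rate <- function(lambda_thr, dt_recover) {
  check_lambda(lambda_thr)
  if (any(dt_recover <= 0)) stop("`dt_recover` must be > 0", call. = FALSE)
  (1 - lambda_thr) / dt_recover
}

#' Realized activity duration for full recovery
#'
#' The time an activity must run so that a linearly recovering need reaches
#' full satiation: `(1 - n) / m_recover`. An agent that starts an activity
#' below the threshold (n < lambda, e.g. going to sleep late) therefore runs
#' it longer than the minimum recovery time.
#'
#' @param n_now Current satiation in \[0, 1\].
#' @param m_recover Recovery rate per hour (> 0), see [recovery_rate()].
#' @return Required duration in hours (>= 0).
#' @examples
#' activity_duration(0.2, recovery_rate(0.2, 10)) # 10 h: on-time sleep
#' activity_duration(0, 1.6)                      # 0.625 h: very hungry meal
#' @export
activity_duration <- function(n_now, m_recover) {
  check_satiation(n_now)
  if (any(m_recover <= 0)) stop("`m_recover` must be > 0", call. = FALSE)
  (1 - n_now) / m_recover
}

#' Step-function satiation
#'
#' Needs that represent scheduled commitments (working, commuting) depend on
#' the clock rather than on time since last satisfaction: satiation is 1
#' before the trigger time `t0` and drops to `eta` (0 <= eta <= lambda) at
#' and after `t0`. Completing the corresponding activity returns satiation
#' to 1 and schedules the next trigger.
#'
#' @param t Current time in simulation minutes (vectorized).
#' @param t0 Trigger time in simulation minutes.
#' @param eta Post-trigger satiation, with `0 <= eta <= lambda_thr`.
#' @param lambda_thr Threshold; used only to validate `eta`.
#' @return Satiation value(s): 1 where `t < t0`, `eta` where `t >= t0`.
#' @export
step_satiation <- function(t, t0, eta, lambda_thr = 0.2) {
  check_lambda(lambda_thr)
  if (any(eta < 0) || any(eta > lambda_thr)) {
    stop("`eta` must satisfy 0 <= eta <= lambda_thr", call. = FALSE)
  }
  ifelse(t < t0, 1, eta)
}

#' Urgency weight of a need
#'
#' The weight is 0 while satiation exceeds the threshold (the need raises no
#' desire) and `1 / (n + epsilon)` at or below it, so lower satiation means
#' higher urgency. `epsilon` keeps the weight finite at n = 0.
#'
#' @param n Satiation in \[0, 1\] (vectorized).
#' @param lambda_thr Threshold in (0, 1).
#' @param epsilon Small positive constant preventing division by zero.
#' @return Non-negative weight(s).
#' @examples
#' need_weight(0.5, 0.2)        # 0: above threshold
#' need_weight(0.2, 0.2)        # about 5
#' @export
need_weight <- function(n, lambda_thr, epsilon = 1e-9) {
  check_satiation(n)
  check_lambda(lambda_thr)
  if (epsilon <= 0) stop("`epsilon` must be > 0", call. = FALSE)
  ifelse(n > lambda_thr, 0, 1 / (n + epsilon))
}

#' Advertisement score of an activity
#'
#' An advertised activity promises to move a need's satiation from `n_now` to
#' `n_future = n_now + delta`. Its score is 0 when the need is still above
#' threshold, and otherwise the urgency gained:
#' `1/(n_now + epsilon) - 1/(n_future + epsilon)`. The score is positive
#' exactly when the activity raises satiation, negative when it lowers it,
#' and zero for a no-op; the agent performs the highest-scoring positive
#' advertisement.
#'
#' @param n_now Current satiation in \[0, 1\].
#' @param n_future Satiation promised after the activity, in \[0, 1\].
#' @inheritParams need_weight
#' @return Score(s).
#' @examples
#' need_score(0.3, 1, 0.2)  # 0: not yet below threshold
#' need_score(0.2, 1, 0.2)  # about 4
#' @export
need_score <- function(n_now, n_future, lambda_thr, epsilon = 1e-9) {
  check_satiation(n_now)
  check_satiation(n_future)
  check_lambda(lambda_thr)
  if (epsilon <= 0) stop("`epsilon` must be > 0", call. = FALSE)
  ifelse(n_now > lambda_thr,
         0,
         1 / (n_now + epsilon) - 1 / (n_future + epsilon))
}

#' Construct a need
#'
#' A need is one of the agent's four motivations. `Rest` and `Hunger` are
#' `linear` needs (satiation decays at a constant negative rate since last
#' satisfaction); `Income` and `Travel` are `step` needs (satiation drops
#' from 1 to `eta` at a scheduled trigger time).
#'
#' @param name One of `"Rest"`, `"Hunger"`, `"Income"`, `"Travel"`.
#' @param kind `"linear"` or `"step"`.
#' @param n Initial satiation in \[0, 1\].
#' @param lambda_thr Threshold in (0, 1).
#' @param eta Post-trigger satiation (step needs), `0 <= eta <= lambda_thr`.
#' @param m_decay Decay rate per hour, `<= 0` (linear needs).
#' @param trigger_time Next unsatisfaction time in simulation minutes (step
#'   needs), or `Inf` when none is scheduled.
#' @return An object of class `need`.
#' @export
need <- function(name = c("Rest", "Hunger", "Income", "Travel"),
                 kind = c("linear", "step"),
                 n = 1, lambda_thr = 0.2, eta = 0,
                 m_decay = 0, trigger_time = Inf) {
  name <- match.arg(name)
  kind <- match.arg(kind)
  check_satiation(n)
  check_lambda(lambda_thr)
  if (kind == "step" && (eta < 0 || eta > lambda_thr)) {
    stop("`eta` must satisfy 0 <= eta <= lambda_thr", call. = FALSE)
  }
  if (m_decay > 0) stop("`m_decay` must be <= 0", call. = FALSE)
  structure(list(name = name, kind = kind, n = n, lambda_thr = lambda_thr,
                 eta = eta, m_decay = m_decay, trigger_time = trigger_time),
            class = "need")
}

#' @export
print.need <- function(x, ...) {
  cat(sprintf("<need> %s (%s): n = %.3f, lambda = %.2f\n",
              x$name, x$kind, x$n, x$lambda_thr))
  invisible(x)
}

#' Advance a linear need by a number of ticks
#'
#' Applies the constant decay rate for `dt_min` minutes and clamps the result
#' into \[0, 1\]. The clamp floor matters only when a need stays unsatisfied
#' past its trigger (e.g. Hunger after a skipped breakfast).
#'
#' @param nd A linear [need()].
#' @param dt_min Elapsed minutes (>= 0).
#' @return The updated need.
#' @export
advance_linear <- function(nd, dt_min) {
  if (!inherits(nd, "need") || nd$kind != "linear") {
    stop("`nd` must be a linear need", call. = FALSE)
  }
  if (dt_min < 0) stop("`dt_min` must be >= 0", call. = FALSE)
  nd$n <- clamp01(nd$n + nd$m_decay * dt_min / 60)
  nd
}

#' Recovery plan for a linearly satisfying activity
#'
#' Given the current satiation and the minimum recovery time of the episode
#' (the sampled duration for meals; sampled end minus sampled start for
#' sleep), computes the recovery rate and the realized duration needed to
#' reach full satiation.
#'
#' @param n_now Satiation at activity start, `n_now <= lambda_thr`.
#' @param lambda_thr Threshold in (0, 1).
#' @param dt_recover Minimum recovery time in hours (> 0).
#' @return A list of class `recovery_plan` with `m_recover` (per hour),
#'   `dt_recover` (hours), `dt_activity` (hours) and `dt_activity_min`
#'   (whole minutes, ties rounded up).
#' @examples
#' recovery_plan(0.2, 0.2, 10)    # on-time sleep: exactly 10 h
#' recovery_plan(0,   0.2, 0.25)  # famished breakfast: 0.3125 h
#' @export
recovery_plan <- function(n_now, lambda_thr, dt_recover) {
  m <- recovery_rate(lambda_thr, dt_recover)
  dt_act <- activity_duration(n_now, m)
  structure(list(m_recover = m,
                 dt_recover = dt_recover,
                 dt_activity = dt_act,
                 dt_activity_min = max(1L, round_half_up(dt_act * 60))),
            class = "recovery_plan")
}

clamp01 <- function(x) {
  pmin(1, pmax(0, x))
}

check_satiation <- function(n) {
  if (any(n < 0) || any(n > 1)) {
    stop("satiation must lie in [0, 1]", call. = FALSE)
  }
  invisible(n)
}

check_lambda <- function(lambda_thr) {
  if (any(lambda_thr <= 0) || any(lambda_thr >= 1)) {
    stop("`lambda_thr` must lie in (0, 1)", call. = FALSE)
  }
  invisible(lambda_thr)
}
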