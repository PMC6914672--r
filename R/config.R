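# Simulation configuration: global clock settings, need constants, and
# per-activity parameter distributions.

#' Default activity parameter distributions
#'
#' The case-study parameterization of a working adult: sleep around
#' 22:00-8:00 with a deliberately large wake-time spread, breakfast 8:15 for
#' 15 min, a 30-min morning commute ending at the 9:00 work start, work until
#' about 17:00 interrupted by a 30-min lunch around noon, a 60-min evening
#' commute, and dinner around 19:00 for about 45 min. All values are decimal
#' hours (clock hours for starts/ends, elapsed hours for durations).
#'
#' @return Named list of per-activity lists of [param_dist()] objects.
#' @export
default_params <- function() {
  list(
    sleep = list(start = param_dist(22, 0.5),
                 end = param_dist(8, 2.5)),
    eat_breakfast = list(start = param_dist(8.25, 0),
                         duration = param_dist(0.25, 0)),
    commute_to_work = list(duration = param_dist(0.5, 0)),
    work = list(start = param_dist(9, 0),
                end = param_dist(17, 0.08)),
    eat_lunch = list(start = param_dist(12, 0.25),
                     duration = param_dist(0.5, 0.17)),
    commute_from_work = list(duration = param_dist(1, 0)),
    eat_dinner = list(start = param_dist(19, 0.17),
                      duration = param_dist(0.75, 0.08))
  )
}

#' Create a simulation configuration
#'
#' @param days Number of full simulated days after the warm-up.
#' @param warmup_hours Hours simulated before the first full day; the
#'   default 8-hour evening warm-up lets the initial night's sleep be
#'   scheduled like every later one.
#' @param start_weekday Weekday of day 0.
#' @param start_clock_min Minutes past midnight at which the simulation
#'   starts on day 0 (default 960 = 16:00).
#' @param lambda Satiation threshold shared by all needs, in (0, 1).
#' @param epsilon Small positive constant of the urgency weight.
#' @param eta_travel,eta_income Post-trigger satiation of the two
#'   step-function needs, each in `[0, lambda]`. Travel's very low value
#'   makes leaving for work outrank eating breakfast on late mornings.
#' @param params Per-activity parameter distributions, as
#'   [default_params()]. Setting `params$work <- NULL` removes working and,
#'   because commutes are linked to work, both commutes.
#' @param seed Optional integer seed fixing the whole trace.
#' @return An object of class `sim_config`.
#' @examples
#' cfg <- sim_config(seed = 1)
#' cfg$horizon_min # 7 days + 8 h in minutes
#' @export
sim_config <- function(days = 7,
                       warmup_hours = 8,
                       start_weekday = "Sunday",
                       start_clock_min = 960L,
                       lambda = 0.2,
                       epsilon = 1e-9,
                       eta_travel = 0.0,
                       eta_income = 0.1,
                       params = default_params(),
                       seed = NULL) {
  cfg <- structure(list(days = days,
                        warmup_hours = warmup_hours,
                        start_weekday = start_weekday,
                        start_clock_min = as.integer(start_clock_min),
                        lambda = lambda,
                        epsilon = epsilon,
                        eta = c(travel = eta_travel, income = eta_income),
                        params = params,
                        seed = seed),
                   class = "sim_config")
  cfg$horizon_min <- as.integer(round(days * 1440 + warmup_hours * 60))
  validate_config(cfg)
  cfg
}

#' Validate a simulation configuration
#'
#' @param config A [sim_config()].
#' @return The config, invisibly; stops with a descriptive error when a
#'   field is out of range or a required parameter distribution is missing.
#' @export
validate_config <- function(config) {
  if (!inherits(config, "sim_config")) {
    stop("`config` must be a sim_config", call. = FALSE)
  }
  with(config, {
    if (!is.numeric(days) || days < 0) stop("`days` must be >= 0",
                                            call. = FALSE)
    if (!is.numeric(warmup_hours) || warmup_hours < 0) {
      stop("`warmup_hours` must be >= 0", call. = FALSE)
    }
    if (horizon_min < 1) stop("simulation horizon must be >= 1 minute",
                              call. = FALSE)
    if (!start_weekday %in% WEEKDAY_NAMES) {
      stop("`start_weekday` must be one of the weekday names",
           call. = FALSE)
    }
    if (start_clock_min < 0 || start_clock_min > 1439) {
      stop("`start_clock_min` must be in 0..1439", call. = FALSE)
    }
    check_lambda(lambda)
    if (epsilon <= 0) stop("`epsilon` must be > 0", call. = FALSE)
    if (any(eta < 0) || any(eta > lambda)) {
      stop("`eta` values must lie in [0, lambda]", call. = FALSE)
    }
  })
  specs <- activity_specs()
  has_work <- !is.null(config$params$work)
  for (i in seq_len(nrow(specs))) {
    id <- specs$id[i]
    # a config without work also drops the linked commutes
    if (!has_work && id %in% c("work", "commute_to_work",
                               "commute_from_work")) {
      next
    }
    pd <- config$params[[id]]
    if (is.null(pd)) stop("missing parameters for activity: ", id,
                          call. = FALSE)
    for (par in specs$parameterized[[i]]) {
      d <- pd[[par]]
      if (!inherits(d, "param_dist")) {
        stop("missing param_dist for ", id, "$", par, call. = FALSE)
      }
      if (par == "duration" && d$mu - d$sigma <= 0) {
        stop("duration of ", id, " must stay positive within mu +/- sigma",
             call. = FALSE)
      }
    }
  }
  if (has_work) {
    w <- config$params$work
    if (w$end$mu - w$end$sigma <= w$start$mu + w$start$sigma) {
      stop("work must end after it starts for every admissible draw",
           call. = FALSE)
    }
    if (is.null(config$params$commute_to_work) ||
        is.null(config$params$commute_from_work)) {
      stop("work requires both commute activities", call. = FALSE)
    }
  }
  invisible(config)
}

#' Set every parameter's day-to-day variation to zero
#'
#' Returns a copy of the configuration with all `sigma` set to 0, so every
#' day repeats the long-term mean schedule exactly. Used for the
#' deterministic schedule checks and the analytic oracle.
#'
#' @param config A [sim_config()].
#' @return The modified config.
#' @export
zero_variance <- function(config = sim_config()) {
  config$params <- lapply(config$params, function(pd) {
    lapply(pd, function(d) param_dist(d$mu, 0))
  })
  validate_config(config)
  config
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf("<sim_config> %g day(s) + %g h warm-up, day 0 %s %s\n",
              x$days, x$warmup_hours, x$start_weekday,
              format_hhmm(x$start_clock_min)))
  cat(sprintf("  lambda = %g, epsilon = %g, eta: travel = %g, income = %g\n",
              x$lambda, x$epsilon, x$eta[["travel"]], x$eta[["income"]]))
  for (id in names(x$params)) {
    pd <- x$params[[id]]
    cat("  ", id, ": ",
        paste(vapply(names(pd), function(p) {
          sprintf("%s mu=%g sigma=%g", p, pd[[p]]$mu, pd[[p]]$sigma)
        }, character(1)), collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' Read a simulation configuration from a YAML file
#'
#' The file mirrors [sim_config()]: a `simulation` section (days,
#' warmup_hours, start_weekday, start_time as `"HH:MM"`, optional seed), a
#' `needs` section (lambda, epsilon, eta_travel, eta_income) and an
#' `activities` section with `<parameter>_mu` / `<parameter>_sigma` entries
#' in decimal hours. Omitted fields fall back to the defaults. The shipped
#' default file is at
#' `system.file("extdata", "default_config.yaml", package = "needsim")`.
#'
#' @param path Path to a YAML file.
#' @return A [sim_config()].
#' @export
read_sim_config <- function(path) {
  raw <- yaml::read_yaml(path)
  sim <- raw$simulation
  nds <- raw$needs
  acts <- raw$activities
  pick <- function(x, nm, default) if (!is.null(x[[nm]])) x[[nm]] else default
  params <- default_params()
  if (!is.null(acts)) {
    params <- list()
    for (id in names(acts)) {
      if (!id %in% ACTIVITY_IDS) {
        stop("unknown activity in config: ", id, call. = FALSE)
      }
      a <- acts[[id]]
      pd <- list()
      for (par in c("start", "end", "duration")) {
        mu <- a[[paste0(par, "_mu")]]
        if (!is.null(mu)) {
          sg <- pick(a, paste0(par, "_sigma"), 0)
          pd[[par]] <- param_dist(mu, sg)
        }
      }
      params[[id]] <- pd
    }
  }
  sim_config(
    days = pick(sim, "days", 7),
    warmup_hours = pick(sim, "warmup_hours", 8),
    start_weekday = pick(sim, "start_weekday", "Sunday"),
    start_clock_min = if (!is.null(sim$start_time))
      parse_hhmm(sim$start_time) else 960L,
    lambda = pick(nds, "lambda", 0.2),
    epsilon = pick(nds, "epsilon", 1e-9),
    eta_travel = pick(nds, "eta_travel", 0.0),
    eta_income = pick(nds, "eta_income", 0.1),
    params = params,
    seed = pick(sim, "seed", NULL)
  )
}
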