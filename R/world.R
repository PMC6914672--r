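# Environments, objects, and the advertisement mechanism by which objects
# offer activities to a co-located agent.

ENVIRONMENT_NAMES <- c("Residence", "Workplace", "Outdoors")

# Allowed movement: residence <-> outdoors and workplace <-> outdoors only;
# never residence <-> workplace directly.
allowed_transition <- function(from, to) {
  (from == "Residence" & to == "Outdoors") |
    (from == "Outdoors" & to == "Residence") |
    (from == "Workplace" & to == "Outdoors") |
    (from == "Outdoors" & to == "Workplace")
}

world_object <- function(name, environment, activities) {
  structure(list(name = name, environment = environment,
                 activities = activities),
            class = "world_object")
}

#' Build the simulated world
#'
#' Three environments hold the objects an agent interacts with: the
#' residence contains a bed (sleeping) and food (all meals); the workplace
#' contains occupational objects (working) and food (lunch only); outdoors
#' contains transport (both commutes). An agent occupies exactly one
#' environment at a time and may move only between the residence and
#' outdoors or between the workplace and outdoors.
#'
#' @param config A [sim_config()]; currently only validated, the object
#'   layout itself is fixed.
#' @return An object of class `world`: a named list of environments, each
#'   with a named list of `world_object`s.
#' @examples
#' w <- build_world()
#' w$Residence$objects$Food$activities
#' @export
build_world <- function(config = sim_config()) {
  if (!inherits(config, "sim_config")) {
    stop("`config` must be a sim_config", call. = FALSE)
  }
  envs <- list(
    Residence = list(
      name = "Residence",
      objects = list(
        Bed = world_object("Bed", "Residence", "sleep"),
        Food = world_object("Food", "Residence",
                            c("eat_breakfast", "eat_lunch", "eat_dinner"))
      )
    ),
    Workplace = list(
      name = "Workplace",
      objects = list(
        Occupational = world_object("Occupational objects", "Workplace",
                                    "work"),
        Food = world_object("Food", "Workplace", "eat_lunch")
      )
    ),
    Outdoors = list(
      name = "Outdoors",
      objects = list(
        Transport = world_object("Transport", "Outdoors",
                                 c("commute_to_work", "commute_from_work"))
      )
    )
  )
  structure(envs, class = "world")
}

#' Activities supported in an environment
#'
#' @param world A [build_world()] result.
#' @param env_name Environment name.
#' @return Character vector of activity ids offered by the environment's
#'   objects.
#' @export
supported_activities <- function(world, env_name) {
  env <- world[[env_name]]
  if (is.null(env)) stop("unknown environment: ", env_name, call. = FALSE)
  sort(unique(unlist(lapply(env$objects, `[[`, "activities"))))
}

#' Advertisements from one object
#'
#' An object advertises each of its supported activities whose target need
#' is unsatisfied (satiation at or below the threshold) and whose activity
#' is currently available (scheduled occurrence reached, permitted in the
#' agent's situation). Each advertisement promises a satiation change
#' `delta` and carries the score of performing the activity now. Needs above
#' threshold and unavailable activities yield no advertisement, so no
#' advertisement ever has a positive score for a satisfied need.
#'
#' @param object A `world_object` (an element of a [build_world()]
#'   environment).
#' @param needs_state Named numeric vector or list of current satiations,
#'   names `"Rest"`, `"Hunger"`, `"Income"`, `"Travel"`.
#' @param t Current time in simulation minutes (carried into the result).
#' @param availability Named list keyed by activity id; each element a list
#'   with `available` (logical) and optionally `delta` (promised satiation
#'   change, default `1 - n`: full satisfaction) and `duration_min`
#'   (promised duration). Activities missing from the list are unavailable.
#' @param lambda_thr Threshold in (0, 1).
#' @param epsilon Constant of the urgency weight.
#' @return A data frame with columns `activity`, `need`, `delta`,
#'   `duration_min`, `score` (zero rows when nothing applies).
#' @export
advertise <- function(object, needs_state, t, availability,
                      lambda_thr = 0.2, epsilon = 1e-9) {
  if (!inherits(object, "world_object")) {
    stop("`object` must be a world_object", call. = FALSE)
  }
  rows <- lapply(object$activities, function(act) {
    av <- availability[[act]]
    if (is.null(av) || !isTRUE(av$available)) return(NULL)
    nm <- ACTIVITY_NEED[[act]]
    n <- as.numeric(needs_state[[nm]])
    if (n > lambda_thr + 1e-12) return(NULL)
    delta <- if (!is.null(av$delta)) av$delta else 1 - n
    n_future <- clamp01(n + delta)
    data.frame(activity = act,
               need = nm,
               delta = delta,
               duration_min = if (!is.null(av$duration_min))
                 av$duration_min else NA_integer_,
               score = need_score(n, n_future, lambda_thr, epsilon),
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L) {
    return(data.frame(activity = character(0), need = character(0),
                      delta = numeric(0), duration_min = integer(0),
                      score = numeric(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}
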