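# Activity-diary records, CSV serialization, and summary statistics.

DIARY_HEADER <- c("Day", "Start time", "End time", "Duration", "Activity",
                  "Weekday", "Environment")

#' Validate an activity diary
#'
#' Checks the column contract (day, start, end, duration, activity,
#' weekday, environment), that each entry's end clock is consistent with
#' its start and duration (entries spanning midnight belong to the day they
#' started), and that entries do not overlap in absolute time.
#'
#' @param diary An `activity_diary` data frame, as returned by
#'   [run_simulation()] or [read_diary()].
#' @return The diary, invisibly; stops on violation.
#' @export
validate_diary <- function(diary) {
  need_cols <- c("day", "start", "end", "duration", "activity", "weekday",
                 "environment")
  missing <- setdiff(need_cols, names(diary))
  if (length(missing) > 0L) {
    stop("diary is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(diary) == 0L) return(invisible(diary))
  if (any(diary$duration < 0)) {
    stop("diary durations must be non-negative", call. = FALSE)
  }
  abs_start <- diary$day * 1440L + diary$start
  abs_end <- abs_start + diary$duration
  if (any((abs_end %% 1440L) != diary$end)) {
    stop("diary end times inconsistent with start + duration",
         call. = FALSE)
  }
  o <- order(abs_start)
  if (any(abs_start[o][-1L] < abs_end[o][-length(o)])) {
    stop("diary entries overlap", call. = FALSE)
  }
  invisible(diary)
}

#' Write an activity diary to CSV
#'
#' Writes the Table-style diary schema: columns `Day`, `Start time`,
#' `End time`, `Duration`, `Activity`, `Weekday`, `Environment`, with all
#' times rendered as zero-padded `"HH:MM"` (durations as elapsed
#' hours:minutes, which may exceed `"23:59"`). Overlapping entries are
#' refused.
#'
#' @param diary An `activity_diary`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_diary <- function(diary, path) {
  validate_diary(diary)
  out <- data.frame(diary$day,
                    format_hhmm(diary$start),
                    format_hhmm(diary$end),
                    format_hhmm(diary$duration),
                    diary$activity,
                    diary$weekday,
                    diary$environment,
                    stringsAsFactors = FALSE,
                    check.names = FALSE)
  names(out) <- DIARY_HEADER
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an activity diary from CSV
#'
#' Inverse of [write_diary()]: `read_diary(write_diary(d))` reproduces `d`
#' entry for entry. Malformed time fields are reported with their row
#' number.
#'
#' @param path Path to a diary CSV.
#' @return An `activity_diary` data frame.
#' @export
read_diary <- function(path) {
  raw <- utils::read.csv(path, check.names = FALSE,
                         stringsAsFactors = FALSE, colClasses = "character")
  if (!identical(names(raw), DIARY_HEADER)) {
    stop("unexpected diary header: ", paste(names(raw), collapse = ", "),
         call. = FALSE)
  }
  parse_col <- function(x, what) {
    ok <- grepl("^[0-9]{1,3}:[0-5][0-9]$", x)
    if (any(!ok)) {
      stop("malformed ", what, " at row ", which(!ok)[1L], call. = FALSE)
    }
    parse_hhmm(x)
  }
  day <- suppressWarnings(as.integer(raw$Day))
  if (any(is.na(day))) {
    stop("malformed Day at row ", which(is.na(day))[1L], call. = FALSE)
  }
  diary <- data.frame(
    day = day,
    start = parse_col(raw[["Start time"]], "start time"),
    end = parse_col(raw[["End time"]], "end time"),
    duration = parse_col(raw[["Duration"]], "duration"),
    activity = raw$Activity,
    weekday = raw$Weekday,
    environment = raw$Environment,
    stringsAsFactors = FALSE
  )
  class(diary) <- c("activity_diary", "data.frame")
  validate_diary(diary)
  diary
}

#' Per-activity summary statistics of a diary
#'
#' For each activity present in the diary: episode count, number of
#' distinct days with at least one episode, mean/min/max start clock time
#' (decimal hours), mean/min/max duration (minutes), and the episode split
#' between workdays (Monday-Friday) and weekends.
#'
#' @param diary An `activity_diary`.
#' @return A data frame with one row per activity; zero rows for an empty
#'   diary.
#' @examples
#' d <- run_simulation(zero_variance(sim_config()), seed = 1)
#' summarize_diary(d)
#' @export
summarize_diary <- function(diary) {
  validate_diary(diary)
  if (nrow(diary) == 0L) {
    return(data.frame(activity = character(0), episodes = integer(0),
                      days = integer(0), start_mean_h = numeric(0),
                      start_min_h = numeric(0), start_max_h = numeric(0),
                      duration_mean_min = numeric(0),
                      duration_min_min = numeric(0),
                      duration_max_min = numeric(0),
                      workday_episodes = integer(0),
                      weekend_episodes = integer(0),
                      stringsAsFactors = FALSE))
  }
  canonical <- unname(ACTIVITY_LABELS)
  acts <- unique(diary$activity)
  acts <- c(intersect(canonical, acts), setdiff(acts, canonical))
  rows <- lapply(acts, function(a) {
    d <- diary[diary$activity == a, , drop = FALSE]
    wk <- is_workday(d$weekday)
    data.frame(activity = a,
               episodes = nrow(d),
               days = length(unique(d$day)),
               start_mean_h = mean(d$start) / 60,
               start_min_h = min(d$start) / 60,
               start_max_h = max(d$start) / 60,
               duration_mean_min = mean(d$duration),
               duration_min_min = min(d$duration),
               duration_max_min = max(d$duration),
               workday_episodes = sum(wk),
               weekend_episodes = sum(!wk),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' @export
print.activity_diary <- function(x, n = 10L, ...) {
  cat(sprintf("<activity_diary> %d entries, %s minutes\n", nrow(x),
              format(sum(x$duration))))
  shown <- utils::head(x, n)
  fmt <- data.frame(Day = shown$day,
                    `Start time` = format_hhmm(shown$start),
                    `End time` = format_hhmm(shown$end),
                    Duration = format_hhmm(shown$duration),
                    Activity = shown$activity,
                    Weekday = shown$weekday,
                    Environment = shown$environment,
                    check.names = FALSE)
  print.data.frame(fmt, row.names = FALSE)
  if (nrow(x) > n) cat("... and", nrow(x) - n, "more entries\n")
  invisible(x)
}
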