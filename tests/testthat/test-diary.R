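test_that("diary CSV serialization round-trips entry for entry", {
  d <- run_simulation(sim_config(), seed = 4)
  path <- withr::local_tempfile(fileext = ".csv")
  write_diary(d, path)

  header <- strsplit(readLines(path, n = 1L), ",")[[1]]
  expect_equal(header, c("Day", "Start time", "End time", "Duration",
                         "Activity", "Weekday", "Environment"))

  d2 <- read_diary(path)
  expect_identical(diary_cols(d2), diary_cols(d))
  expect_identical(summarize_diary(d2), summarize_diary(d))
})

test_that("a sleep entry spanning midnight keeps its start day and duration", {
  d <- run_simulation(det_config(), seed = 1)
  sl <- d[d$activity == "Sleep", ][1, ]
  expect_equal(sl$day, 0)
  expect_equal(format_hhmm(sl$start), "22:00")
  expect_equal(format_hhmm(sl$end), "08:00")
  expect_equal(format_hhmm(sl$duration), "10:00")
  expect_equal(sl$weekday, "Sunday")
})

test_that("the writer refuses overlapping entries", {
  d <- run_simulation(det_config(), seed = 1)
  bad <- d
  bad$start[2] <- bad$start[2] - 10L   # second entry now overlaps the first
  bad$duration[2] <- bad$duration[2] + 10L
  path <- withr::local_tempfile(fileext = ".csv")
  expect_error(write_diary(bad, path), "overlap")
})

test_that("malformed rows are reported with their row number", {
  d <- run_simulation(det_config(), seed = 1)
  path <- withr::local_tempfile(fileext = ".csv")
  write_diary(d, path)
  lines <- readLines(path)
  lines[4] <- sub("([0-9]{2}:[0-9]{2})", "nonsense", lines[4])
  writeLines(lines, path)
  expect_error(read_diary(path), "row 3")
})

test_that("summaries report counts, clock statistics and weekday splits", {
  d <- run_simulation(det_config(), seed = 1)
  s <- summarize_diary(d)
  rownames(s) <- s$activity

  # five workdays of work, split in two blocks by lunch
  expect_equal(s["Work", "days"], 5L)
  expect_equal(s["Work", "episodes"], 10L)
  expect_equal(s["Work", "weekend_episodes"], 0L)

  # breakfast: constant 15-minute episodes at 8:15
  expect_equal(s["Eat breakfast", "duration_mean_min"], 15)
  expect_equal(s["Eat breakfast", "duration_min_min"], 15)
  expect_equal(s["Eat breakfast", "duration_max_min"], 15)
  expect_equal(s["Eat breakfast", "start_mean_h"], 8.25)

  # single-entry summary equals the entry itself
  one <- d[d$activity == "Eat dinner", ][1, ]
  s1 <- summarize_diary(one)
  expect_equal(s1$episodes, 1L)
  expect_equal(s1$duration_mean_min, one$duration)
  expect_equal(s1$start_mean_h, one$start / 60)

  # durations in any summary always cover the whole horizon
  expect_equal(sum(s$episodes * s$duration_mean_min), sum(d$duration))
})
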