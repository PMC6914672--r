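test_that("the world places objects and activities per the component table", {
  w <- build_world(sim_config())
  expect_setequal(names(w), c("Residence", "Workplace", "Outdoors"))
  expect_setequal(supported_activities(w, "Residence"),
                  c("sleep", "eat_breakfast", "eat_lunch", "eat_dinner"))
  expect_setequal(supported_activities(w, "Workplace"),
                  c("work", "eat_lunch"))
  expect_setequal(supported_activities(w, "Outdoors"),
                  c("commute_to_work", "commute_from_work"))
  # residence food offers all meals; workplace food only lunch
  expect_setequal(w$Workplace$objects$Food$activities, "eat_lunch")
})

test_that("movement is only allowed through the outdoors", {
  trans <- needsim:::allowed_transition
  expect_true(trans("Residence", "Outdoors"))
  expect_true(trans("Outdoors", "Workplace"))
  expect_false(trans("Residence", "Workplace"))
  expect_false(trans("Workplace", "Residence"))
})

test_that("objects advertise only unsatisfied, available needs", {
  w <- build_world(sim_config())
  ns <- c(Rest = 0.2, Hunger = 0.9, Income = 1, Travel = 1)
  avail <- list(sleep = list(available = TRUE, duration_min = 600L),
                eat_dinner = list(available = TRUE, duration_min = 45L))

  # bed advertises sleep with a positive score at threshold Rest
  ads <- advertise(w$Residence$objects$Bed, ns, t = 0, availability = avail)
  expect_equal(nrow(ads), 1L)
  expect_equal(ads$activity, "sleep")
  expect_equal(ads$need, "Rest")
  expect_gt(ads$score, 0)
  expect_equal(ads$delta, 0.8)

  # food stays silent while hunger is satisfied, even though dinner is due
  ads_food <- advertise(w$Residence$objects$Food, ns, t = 0,
                        availability = avail)
  expect_equal(nrow(ads_food), 0L)

  # transport with no availability (weekend: no trigger) is silent even
  # for an unsatisfied Travel need
  ns2 <- c(Rest = 1, Hunger = 1, Income = 1, Travel = 0)
  ads_tr <- advertise(w$Outdoors$objects$Transport, ns2, t = 0,
                      availability = list())
  expect_equal(nrow(ads_tr), 0L)
})

test_that("no advertisement carries a positive score for a satisfied need", {
  w <- build_world(sim_config())
  all_avail <- setNames(
    lapply(activity_specs()$id, function(id) list(available = TRUE)),
    activity_specs()$id)
  set.seed(11)
  for (k in 1:50) {
    ns <- setNames(runif(4), c("Rest", "Hunger", "Income", "Travel"))
    for (env in names(w)) {
      for (obj in w[[env]]$objects) {
        ads <- advertise(obj, ns, t = 0, availability = all_avail)
        if (nrow(ads) > 0) {
          expect_true(all(ns[ads$need] <= 0.2 + 1e-9))
          expect_true(all(ads$score > 0))
        }
      }
    }
  }
})
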