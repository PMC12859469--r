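test_that("the simulator is deterministic given the seed", {
  win <- study_window("2018-01-01", "2018-03-31")
  cfg <- simulation_config(n_patients = 100, window = win, seed = 11)
  r1 <- simulate_registry(cfg)
  r2 <- simulate_registry(cfg)
  expect_identical(r1, r2)
  r3 <- simulate_registry(simulation_config(n_patients = 100, window = win,
                                            seed = 12))
  expect_false(identical(r1, r3))
})

test_that("every simulated patient has an index-class dispensing", {
  win <- study_window("2018-01-01", "2018-06-30")
  cfg <- simulation_config(n_patients = 300, window = win, seed = 3)
  reg <- simulate_registry(cfg)
  map <- atc_class_map()
  lab <- map_atc_to_class(reg$atc_code, map)
  idx <- unique(reg$patient_id[lab %in% c("Antidepressants", "Anxiolytics")])
  expect_setequal(unique(reg$patient_id), idx)
  # records are valid per the registry invariants
  expect_silent(validate_registry(reg, window = win))
  expect_true(all(reg$ddd_ratio > 0 & reg$ddd_ratio <= 3))
})

test_that("equal weekday multipliers give a uniform day-of-week cycle", {
  win <- study_window("2018-01-01", "2018-12-31")
  cfg <- simulation_config(n_patients = 2000, window = win, seed = 5,
                           weekday_multipliers = rep(1, 7),
                           seasonal_amplitude = 0,
                           class_trend_slopes = c(Antidepressants = 0,
                                                  Anxiolytics = 0))
  reg <- simulate_registry(cfg)
  dow <- factor(format(reg$dispense_date, "%u"), levels = as.character(1:7))
  # expected proportions follow the number of each weekday in the window
  days <- seq(win$start, win$end, by = "day")
  p_exp <- as.vector(table(factor(format(days, "%u"),
                                  levels = as.character(1:7))))
  p_exp <- p_exp / sum(p_exp)
  ct <- suppressWarnings(stats::chisq.test(table(dow), p = p_exp))
  expect_gt(ct$p.value, 0.01)
})

test_that("the configured Monday:Saturday ratio is recovered empirically", {
  win <- study_window("2018-01-01", "2018-12-31")
  mult <- c(2.5, 1, 1, 1, 1, 1, 1)  # Monday 2.5x Saturday
  cfg <- simulation_config(n_patients = 5000, window = win, seed = 8,
                           weekday_multipliers = mult,
                           seasonal_amplitude = 0,
                           class_trend_slopes = c(Antidepressants = 0,
                                                  Anxiolytics = 0))
  reg <- simulate_registry(cfg)
  dow <- format(reg$dispense_date, "%u")
  days <- format(seq(win$start, win$end, by = "day"), "%u")
  per_day_mon <- sum(dow == "1") / sum(days == "1")
  per_day_sat <- sum(dow == "6") / sum(days == "6")
  expect_lt(abs(per_day_mon / per_day_sat - 2.5) / 2.5, 0.1)
})

test_that("registry_summary reproduces cohort structure year by year", {
  win <- study_window("2018-01-01", "2019-12-31")
  reg <- make_registry("P1", "N06AB06", c("2018-03-01", "2019-07-01"),
                       birth_year = 1985L)
  s <- registry_summary(reg, win)
  expect_identical(s$year, 2018:2019)
  expect_identical(s$n_total, c(1L, 1L))
  expect_equal(s$mean_age_female, c(33, 34))

  # empty year inside the window still gets a (zero) row
  reg2 <- make_registry("P1", "N06AB06", "2018-03-01")
  s2 <- registry_summary(reg2, win)
  expect_identical(s2$n_total, c(1L, 0L))

  # female share close to the configured fraction at n = 10000
  cfg <- simulation_config(n_patients = 10000,
                           window = study_window("2018-01-01", "2018-12-31"),
                           seed = 21)
  s3 <- registry_summary(simulate_registry(cfg),
                         study_window("2018-01-01", "2018-12-31"))
  expect_lt(abs(s3$female_share[1] - 0.633), 0.02)
})

test_that("total dispensing volume scales linearly with cohort size", {
  win <- study_window("2018-01-01", "2018-06-30")
  sizes <- c(250L, 500L, 1000L)
  per_patient <- sapply(seq_along(sizes), function(i) {
    cfg <- simulation_config(n_patients = sizes[i], window = win,
                             seed = 30 + i)
    nrow(simulate_registry(cfg)) / sizes[i]
  })
  expect_lt(max(per_patient) / min(per_patient), 1.1)
})
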