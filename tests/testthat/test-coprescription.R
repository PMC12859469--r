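test_that("prescription-days count active medications per day", {
  win <- study_window("2018-01-01", "2018-03-31")
  codes <- c("N06AB06", "N05BA01", "C07AB02", "A10BA02", "R03AC02",
             "B01AC06", "M01AE01")
  # seven medications active on a single day -> 7 prescription-days
  reg <- make_registry("P1", codes, "2018-01-01", days_supplied = 1L)
  ex <- exposure_days(expand_records(reg, win), win)
  expect_identical(prescription_days(ex), 7L)
  # no active medication -> 0
  expect_identical(prescription_days(ex[0]), 0L)
  # 3 medications x 5 days -> 15
  reg3 <- make_registry("P1", codes[1:3], "2018-01-01", days_supplied = 5L)
  ex3 <- exposure_days(expand_records(reg3, win), win)
  expect_identical(prescription_days(ex3), 15L)
})

test_that("same-class days need >=2 distinct focal medications on the day", {
  win <- study_window("2018-01-01", "2018-03-31")
  # two distinct antidepressants for one day -> 2
  reg <- make_registry("P1", c("N06AB06", "N06AF01"), "2018-01-01",
                       days_supplied = 1L)
  ex <- exposure_days(expand_records(reg, win), win)
  expect_identical(same_class_days(ex, "Antidepressants"), 2L)
  # a single antidepressant for 10 days -> no co-prescription
  reg1 <- make_registry("P1", "N06AB06", "2018-01-01", days_supplied = 10L)
  ex1 <- exposure_days(expand_records(reg1, win), win)
  expect_identical(same_class_days(ex1, "Antidepressants"), 0L)
})

test_that("multi-class days count the non-focal medications on mixed days", {
  win <- study_window("2018-01-01", "2018-03-31")
  # one antidepressant + two cardiovascular drugs for one day -> 2
  reg <- make_registry("P1", c("N06AB06", "C07AB02", "C09AA05"),
                       "2018-01-01", days_supplied = 1L)
  ex <- exposure_days(expand_records(reg, win), win)
  expect_identical(multi_class_days(ex, "Antidepressants"), 2L)
  # focal class alone -> 0
  reg2 <- make_registry("P1", c("N06AB06", "N06AF01"), "2018-01-01",
                        days_supplied = 5L)
  ex2 <- exposure_days(expand_records(reg2, win), win)
  expect_identical(multi_class_days(ex2, "Antidepressants"), 0L)
})

test_that("co-prescription statistics match a brute-force day scan", {
  set.seed(31)
  win <- study_window("2018-01-01", "2018-03-01")
  iv <- random_intervals(n = 80L, n_pat = 8L, n_days = win$n_days)
  ex <- exposure_days(iv, win)
  grid <- as.data.frame(ex)

  # brute force over the patient x day grid
  bf_presc <- nrow(grid)
  bf_same <- 0L
  bf_multi <- 0L
  for (p in unique(grid$patient_id)) for (d in unique(grid$day)) {
    cls <- grid$class_label[grid$patient_id == p & grid$day == d]
    nf <- sum(cls == "Antidepressants")
    if (nf >= 2L) bf_same <- bf_same + nf
    if (nf >= 1L && sum(cls != "Antidepressants") >= 1L) {
      bf_multi <- bf_multi + sum(cls != "Antidepressants")
    }
  }
  expect_identical(prescription_days(ex), bf_presc)
  expect_identical(same_class_days(ex, "Antidepressants"), bf_same)
  expect_identical(multi_class_days(ex, "Antidepressants"), bf_multi)

  # same-class days can never exceed prescription-days
  expect_lte(same_class_days(ex, "Antidepressants"), prescription_days(ex))
})

test_that("yearly summary totals equal per-person means times cohort size", {
  win <- study_window("2018-01-01", "2018-12-31")
  cfg <- simulation_config(n_patients = 150, window = win, seed = 44)
  reg <- simulate_registry(cfg)
  ex <- exposure_days(expand_records(reg, win), win)
  cop <- coprescription_summary(ex, reg, window = win)
  expect_true(all(cop$year == 2018L))
  expect_equal(cop$same_class_mean * cop$n_persons, cop$same_class_total)
  expect_equal(cop$multi_class_mean * cop$n_persons, cop$multi_class_total)
  expect_equal(cop$total_mean * cop$n_persons, cop$total_n)
  expect_true(all(cop$multi_class_total >= 0))
  # the focal totals agree with the standalone operations restricted to
  # the yearly cohort
  map <- atc_class_map()
  lab <- map_atc_to_class(reg$atc_code, map)
  coh <- unique(reg$patient_id[lab == "Antidepressants"])
  expect_identical(cop[focal_class == "Antidepressants"]$same_class_total,
                   same_class_days(ex, "Antidepressants", patient_ids = coh))
})

test_that("polypharmacy needs >=5 medications for >=30 consecutive days", {
  win <- study_window("2018-01-01", "2018-12-31")
  codes <- c("N06AB06", "N05BA01", "C07AB02", "A10BA02", "R03AC02")
  reg30 <- make_registry("P1", codes, "2018-01-01", days_supplied = 30L)
  ex30 <- exposure_days(expand_records(reg30, win), win)
  expect_true(polypharmacy_flags(ex30)$polypharmacy)

  reg29 <- make_registry("P1", codes, "2018-01-01", days_supplied = 29L)
  ex29 <- exposure_days(expand_records(reg29, win), win)
  expect_false(polypharmacy_flags(ex29)$polypharmacy)

  # only 4 concurrent medications never qualifies
  reg4 <- make_registry("P1", codes[1:4], "2018-01-01", days_supplied = 60L)
  ex4 <- exposure_days(expand_records(reg4, win), win)
  expect_false(polypharmacy_flags(ex4)$polypharmacy)

  # monotone: adding exposure can only set the flag
  extra <- make_registry("P1", "B01AC06", "2018-01-01", days_supplied = 45L)
  ex5 <- exposure_days(expand_records(rbind(reg29, extra), win), win)
  expect_true(polypharmacy_flags(ex5)$polypharmacy ||
                !polypharmacy_flags(ex29)$polypharmacy)
})

test_that("polypharmacy runs match a brute-force run-length scan", {
  set.seed(17)
  win <- study_window("2018-01-01", "2018-06-30")
  iv <- random_intervals(n = 150L, n_pat = 6L, n_days = win$n_days,
                         codes = c("N06AB06", "N06AF01", "N05BA01",
                                   "C07AB02", "A10BA02", "B01AC06",
                                   "R03AC02"))
  ex <- exposure_days(iv, win)
  got <- polypharmacy_flags(ex, min_meds = 3L, min_days = 10L)
  grid <- as.data.frame(ex)
  for (p in unique(grid$patient_id)) {
    n_by_day <- integer(win$n_days)
    sub <- grid[grid$patient_id == p, ]
    for (d in unique(sub$day)) n_by_day[d + 1L] <- sum(sub$day == d)
    ok <- n_by_day >= 3L
    run <- 0L; best <- 0L
    for (v in ok) { run <- if (v) run + 1L else 0L; best <- max(best, run) }
    expect_identical(got[patient_id == p]$polypharmacy, best >= 10L,
                     label = paste("patient", p))
  }
})

test_that("subgroup labels age patients per calendar year", {
  win <- study_window("2018-01-01", "2019-12-31")
  reg <- make_registry("P1", "N06AB06", "2018-05-01", birth_year = 1954L)
  ex <- exposure_days(expand_records(reg, win), win)
  lab <- subgroup_labels(reg, ex, win)
  expect_identical(lab[year == 2018]$age_group, "<65")   # 64
  expect_identical(lab[year == 2019]$age_group, ">=65")  # 65
  expect_false(any(lab$polypharmacy))
})

test_that("a degenerate single-subgroup run equals the population run", {
  win <- study_window("2018-01-01", "2018-02-28")
  cfg <- simulation_config(n_patients = 80, window = win, seed = 50)
  reg <- simulate_registry(cfg)
  ex <- exposure_days(expand_records(reg, win), win)
  asg <- data.table(patient_id = unique(ex$patient_id), group = "all")
  runs <- subgroup_run(ex, asg, window = win)
  pop <- daily_centrality(build_daily_networks(ex))
  expect_equal(runs$all$centrality, pop)
})
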