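test_that("individual daily networks connect exactly the active class pairs", {
  map <- atc_class_map()
  labels <- atc_class_labels(map)
  act <- data.table(class_label = c("Antidepressants", "Anxiolytics"))
  A <- build_individual_daily(act, map)
  expect_identical(sum(A) / 2, 1)  # one undirected edge
  expect_identical(A["Antidepressants", "Anxiolytics"], 1L)
  expect_true(all(diag(A) == 0))

  # single class: no pair, zero matrix
  expect_identical(sum(build_individual_daily(
    data.table(class_label = "Antidepressants"), map)), 0L)

  # k distinct classes -> k(k-1)/2 edges
  act5 <- data.table(class_label = labels[c(1, 3, 7, 12, 20)])
  expect_identical(sum(build_individual_daily(act5, map)) / 2, 10)
})

test_that("population aggregation is the element-wise sum", {
  map <- atc_class_map()
  a1 <- build_individual_daily(
    data.table(class_label = c("Antidepressants", "Anxiolytics")), map)
  a2 <- build_individual_daily(
    data.table(class_label = c("Antidepressants", "Anxiolytics",
                               "Cardiovascular")), map)
  counts <- aggregate_population(list(a1, a2))
  expect_identical(counts["Antidepressants", "Anxiolytics"], 2L)
  expect_identical(counts["Anxiolytics", "Cardiovascular"], 1L)
  expect_error(aggregate_population(list(a1, a1[1:3, 1:3])), "mixed")
})

test_that("the Gaussian DDD kernel matches its closed form", {
  p <- weight_params()  # sigma = 1/3
  expect_equal(gaussian_weight(1, p), 3 / sqrt(2 * pi), tolerance = 1e-12)
  expect_equal(gaussian_weight(1e-12, p),
               3 / sqrt(2 * pi) * exp(-4.5), tolerance = 1e-6)
  # symmetry about 1
  d <- c(0.05, 0.3, 0.77)
  expect_equal(gaussian_weight(1 + d, p), gaussian_weight(1 - d, p))
  # maximum at 1, strictly decreasing in |ddd - 1| on a grid
  grid <- seq(0.05, 2.95, by = 0.05)
  w <- gaussian_weight(grid, p)
  expect_identical(grid[which.max(w)], 1)
  above <- w[grid > 1]
  expect_true(all(diff(above) < 0))
  below <- w[grid < 1]
  expect_true(all(diff(below) > 0))
  # peak normalisation puts the maximum at exactly 1
  expect_equal(gaussian_weight(1, weight_params(peak_normalized = TRUE)), 1)
  expect_error(gaussian_weight(0), "positive")
  expect_error(gaussian_weight(-1), "positive")
})

test_that("edge weights average the endpoint weights", {
  expect_identical(edge_weight(0.7, 0.7), 0.7)
  expect_identical(edge_weight(0.4, 0.6), 0.5)
  w <- runif(24, 0.1, 1.2)
  pair <- outer(w, w, edge_weight)
  for (i in c(1, 7, 24)) for (j in c(2, 13)) {
    expect_identical(pair[i, j], (w[i] + w[j]) / 2)
  }
  expect_identical(pair, t(pair))
})

test_that("matrix-level weighting honours combine modes and kills the diagonal", {
  counts <- matrix(0L, 3, 3, dimnames = rep(list(c("a", "b", "c")), 2))
  counts[1, 2] <- counts[2, 1] <- 3L
  counts[1, 1] <- 5L
  om <- c(a = 0.4, b = 0.6, c = 0.9)
  W <- apply_weighting(counts, om, weight_params())
  expect_identical(W[1, 2], 1.5)       # 3 * (0.4+0.6)/2
  expect_identical(diag(W), c(a = 0, b = 0, c = 0))
  Wl <- apply_weighting(counts, om,
                        weight_params(combine = "literal_eq4"))
  expect_identical(Wl[1, 2], 0.5)
  expect_identical(Wl[1, 3], 0)        # no co-prescription, no weight
  # neutral weights reduce multiply mode to counts with zeroed diagonal
  W1 <- apply_weighting(counts, c(a = 1, b = 1, c = 1), weight_params())
  expect_identical(W1[1, 2], 3)
  expect_identical(W1[1, 1], 0)
})

test_that("daily population networks match brute-force pair counting", {
  set.seed(12)
  win <- study_window("2018-01-01", "2018-02-28")
  cfg <- simulation_config(n_patients = 100, window = win, seed = 12)
  reg <- simulate_registry(cfg)
  ex <- exposure_days(expand_records(reg, win), win)
  nets <- build_daily_networks(ex)
  for (d in c(10L, 30L, 55L)) {
    got <- network_matrix(nets, d, type = "counts")
    want <- brute_pair_counts(ex, d, nets$labels)
    expect_identical(got, matrix(as.numeric(want), 24, 24,
                                 dimnames = dimnames(want)))
  }
  # symmetry and zero weighted diagonal on every sampled day
  for (d in c(0L, 20L, 47L)) {
    W <- network_matrix(nets, d, type = "weighted")
    expect_identical(W, t(W))
    expect_true(all(diag(W) == 0))
  }
})

test_that("per-record weighting with constant class DDD equals class_mean mode", {
  win <- study_window("2018-01-01", "2018-01-31")
  reg <- make_registry(
    patient_id = c("P1", "P1", "P2", "P2", "P2"),
    atc_code = c("N06AB06", "N05BA01", "N06AB06", "C07AB02", "A10BA02"),
    dispense_date = "2018-01-01", days_supplied = 10L,
    ddd_ratio = c(0.8, 0.5, 0.8, 1.2, 0.6))
  ex <- exposure_days(expand_records(reg, win), win)
  per <- build_daily_networks(ex, params = weight_params(mode = "per_record"))
  byc <- build_daily_networks(ex, params = weight_params(mode = "class_mean"))
  expect_equal(per$edges, byc$edges, tolerance = 1e-12)
})

test_that("subgroup count matrices sum exactly to the population counts", {
  win <- study_window("2018-01-01", "2018-03-31")
  cfg <- simulation_config(n_patients = 120, window = win, seed = 77)
  reg <- simulate_registry(cfg)
  ex <- exposure_days(expand_records(reg, win), win)
  pats <- unique(ex$patient_id)
  asg <- data.table(patient_id = pats,
                    group = rep(c("g1", "g2", "g3"), length.out = length(pats)))
  runs <- subgroup_run(ex, asg, window = win)
  pop <- build_daily_networks(ex)
  for (d in c(5L, 40L, 80L)) {
    tot <- Reduce(`+`, lapply(runs, function(r)
      network_matrix(r$networks, d, type = "counts")))
    expect_identical(tot, network_matrix(pop, d, type = "counts"))
  }
})

test_that("doubling every patient doubles weighted entries exactly", {
  win <- study_window("2018-01-01", "2018-01-31")
  reg <- make_registry(
    patient_id = c("P1", "P1", "P2", "P2"),
    atc_code = c("N06AB06", "N05BA01", "N06AB06", "C07AB02"),
    dispense_date = "2018-01-01", days_supplied = 10L,
    ddd_ratio = c(0.8, 0.5, 1.1, 1.2))
  reg2 <- data.table::copy(reg)[, patient_id := paste0(patient_id, "bis")]
  ex1 <- exposure_days(expand_records(reg, win), win)
  ex2 <- exposure_days(expand_records(rbind(reg, reg2), win), win)
  n1 <- build_daily_networks(ex1)
  n2 <- build_daily_networks(ex2)
  W1 <- network_matrix(n1, 5L)
  W2 <- network_matrix(n2, 5L)
  expect_equal(W2, 2 * W1, tolerance = 1e-12)
})
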