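#' Simulation configuration for the synthetic dispensing registry
#'
#' The simulator draws, for each patient and therapeutic class, dispensing
#' events from an inhomogeneous Poisson process whose daily intensity is
#'
#' `base_rate[class] * weekday * seasonal * trend * exp(loading[class] * z_p)`
#'
#' where `z_p` is a patient-level latent multimorbidity factor (standard
#' normal plus an age shift). This is the simplest generative process that
#' reproduces the features population dispensing data shows: a weekday
#' cycle peaking on Monday and dipping on Saturday, mild yearly
#' seasonality, slow class-specific volume trends (antidepressants rising,
#' anxiolytics declining), and dense multimorbidity-driven co-prescription
#' across chronic-disease classes.
#'
#' @param n_patients Number of patients in the static cohort.
#' @param window A [study_window()].
#' @param female_fraction Probability a patient is female (default 0.633,
#'   the stable share such cohorts show).
#' @param weekday_multipliers Length-7 positive vector, Monday first. The
#'   default is proportional to observed mean daily dispensing volumes
#'   (Monday peak, Saturday trough), normalised to mean 1.
#' @param class_base_rates Named per-class dispensing intensity
#'   (events/patient/day). Default: per-class shares of observed dispensing
#'   volumes scaled to `total_rate` events per patient-day overall.
#' @param total_rate Overall expected dispensings per patient per day used
#'   to scale the default `class_base_rates` (default 20 per patient-year).
#' @param class_trend_slopes Named relative yearly slopes; default +2%/year
#'   for antidepressants, -2%/year for anxiolytics, flat elsewhere.
#' @param seasonal_amplitude Relative amplitude of the yearly sinusoid
#'   (default 0.08, peaking mid-January).
#' @param comorbidity_loadings Named non-negative loadings linking the
#'   latent factor to class intensities; defaults are larger for
#'   chronic-disease classes (cardiovascular, alimentary, blood, ...).
#' @param age_comorbidity_slope Shift of the latent factor per
#'   (age - 40)/25; makes older patients accumulate more co-medication.
#' @param ddd_meanlog,ddd_sdlog Named lognormal parameters for the
#'   per-record DDD ratio; defaults match per-class DDD means < 1 with
#'   realistic within-class spread, truncated to (0, 3].
#' @param days_supplied_values,days_supplied_probs Categorical distribution
#'   of the days-supplied field (default over 7/14/30/90 days).
#' @param planted_hub_class Optional class label to plant as a
#'   co-prescription hub: its intensity is set to `hub_boost` times the
#'   largest class base rate and its loading to the maximum loading, so it
#'   co-occurs with everything (used for parameter-recovery checks).
#' @param hub_boost Multiplier for the planted hub (default 3).
#' @param seed Integer seed; the simulator is deterministic given the seed.
#' @param map An [atc_class_map()].
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(n_patients = 2000,
                              window = study_window(),
                              female_fraction = 0.633,
                              weekday_multipliers = NULL,
                              class_base_rates = NULL,
                              total_rate = 20 / 365.25,
                              class_trend_slopes = NULL,
                              seasonal_amplitude = 0.08,
                              comorbidity_loadings = NULL,
                              age_comorbidity_slope = 0.5,
                              ddd_meanlog = NULL,
                              ddd_sdlog = NULL,
                              days_supplied_values = c(7L, 14L, 30L, 90L),
                              days_supplied_probs = c(0.15, 0.2, 0.5, 0.15),
                              planted_hub_class = NULL,
                              hub_boost = 3,
                              seed = 1L,
                              map = atc_class_map()) {
  defs <- atc_class_defaults()
  labels <- atc_class_labels(map)
  defs <- defs[match(labels, class_label)]
  if (anyNA(defs$class_label)) {
    stop("class map labels must match the packaged default taxonomy ",
         "when relying on default rates; pass explicit rates otherwise")
  }

  if (is.null(weekday_multipliers)) {
    vol <- c(7222, 6793, 6865, 7109, 6726, 2808, 2991)  # Mon..Sun means
    weekday_multipliers <- vol / mean(vol)
  }
  if (length(weekday_multipliers) != 7L || any(weekday_multipliers <= 0)) {
    stop("weekday_multipliers must be 7 positive values (Monday first)")
  }

  if (is.null(class_base_rates)) {
    class_base_rates <- defs$dispensing_share * total_rate
    names(class_base_rates) <- labels
  }
  class_base_rates <- class_base_rates[labels]
  if (anyNA(class_base_rates) || any(class_base_rates <= 0)) {
    stop("class_base_rates must be positive for all 24 classes")
  }

  slopes <- setNames(rep(0, 24L), labels)
  slopes["Antidepressants"] <- 0.02
  slopes["Anxiolytics"] <- -0.02
  if (!is.null(class_trend_slopes)) {
    slopes[names(class_trend_slopes)] <- class_trend_slopes
  }

  loadings <- setNames(defs$comorbidity_loading, labels)
  if (!is.null(comorbidity_loadings)) {
    loadings[names(comorbidity_loadings)] <- comorbidity_loadings
  }
  if (any(loadings < 0)) stop("comorbidity_loadings must be non-negative")

  if (is.null(ddd_meanlog)) {
    m <- defs$ddd_mean; s <- defs$ddd_sd
    ddd_meanlog <- setNames(log(m^2 / sqrt(m^2 + s^2)), labels)
    ddd_sdlog <- setNames(sqrt(log(1 + s^2 / m^2)), labels)
  }

  if (!is.null(planted_hub_class)) {
    if (!planted_hub_class %in% labels) {
      stop("planted_hub_class must be one of the 24 class labels")
    }
    class_base_rates[planted_hub_class] <- hub_boost * max(class_base_rates)
    loadings[planted_hub_class] <- max(loadings)
  }

  if (female_fraction <= 0 || female_fraction >= 1) {
    stop("female_fraction must lie strictly between 0 and 1")
  }
  if (abs(sum(days_supplied_probs) - 1) > 1e-8 ||
      any(days_supplied_probs < 0)) {
    stop("days_supplied_probs must be a probability vector")
  }

  structure(list(
    n_patients = as.integer(n_patients), window = window,
    female_fraction = female_fraction,
    weekday_multipliers = weekday_multipliers,
    class_base_rates = class_base_rates,
    class_trend_slopes = slopes,
    seasonal_amplitude = seasonal_amplitude,
    comorbidity_loadings = loadings,
    age_comorbidity_slope = age_comorbidity_slope,
    ddd_meanlog = ddd_meanlog, ddd_sdlog = ddd_sdlog,
    days_supplied_values = as.integer(days_supplied_values),
    days_supplied_probs = days_supplied_probs,
    planted_hub_class = planted_hub_class,
    seed = as.integer(seed), map = map
  ), class = "simulation_config")
}

# day-level intensity factors for one class: weekday * seasonal * trend
day_intensity <- function(config, slope) {
  win <- config$window
  dates <- seq(win$start, win$end, by = "day")
  dow <- as.integer(format(dates, "%u"))  # 1 = Monday
  doy <- as.integer(format(dates, "%j"))
  years <- as.numeric(dates - win$start) / 365.25
  config$weekday_multipliers[dow] *
    (1 + config$seasonal_amplitude * cos(2 * pi * (doy - 15) / 365.25)) *
    pmax(1 + slope * years, 0.05)
}

#' Simulate a synthetic dispensing registry
#'
#' Draws the cohort (sex, birth year, latent multimorbidity factor) and
#' per-patient, per-class dispensing events from the configured
#' inhomogeneous Poisson process; every record gets a level-5 ATC code from
#' a small deterministic pool under the class prefix (so same-class
#' co-prescription can occur), a days-supplied draw, and a DDD ratio from
#' the class lognormal truncated to (0, 3]. Patients who end up with no
#' index-class dispensing receive one (the cohort is defined by at least
#' one antidepressant or anxiolytic dispensing), so the output always
#' passes [filter_cohort()]-style index filtering.
#'
#' @param config A [simulation_config()].
#' @return A registry `data.table` (see [read_registry()] for the schema),
#'   sorted by patient, date and ATC code; deterministic given
#'   `config$seed`.
#' @export
#' @examples
#' reg <- simulate_registry(simulation_config(
#'   n_patients = 50, window = study_window("2018-01-01", "2018-06-30")))
#' head(reg)
simulate_registry <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  win <- config$window
  labels <- names(config$class_base_rates)
  n <- config$n_patients
  map <- config$map

  patients <- data.table(
    patient_id = sprintf("P%06d", seq_len(n)),
    sex = ifelse(runif(n) < config$female_fraction, "female", "male"),
    # ages 20..64 at window start, uniform; later years age the cohort
    birth_year = as.integer(format(win$start, "%Y")) -
      sample(20:64, n, replace = TRUE)
  )
  age0 <- as.integer(format(win$start, "%Y")) - patients$birth_year
  latent <- rnorm(n) + config$age_comorbidity_slope * (age0 - 40) / 25

  rules <- as.data.table(map)
  prefix_of <- setNames(rules$atc_prefix[!duplicated(rules$class_label)],
                        rules$class_label[!duplicated(rules$class_label)])

  recs <- vector("list", length(labels))
  for (ci in seq_along(labels)) {
    lab <- labels[ci]
    m <- day_intensity(config, config$class_trend_slopes[lab])
    load <- config$comorbidity_loadings[lab]
    # exp(load * z - load^2/2) has unit mean, so base_rate is the
    # population-average daily intensity for the class
    rate <- config$class_base_rates[lab] *
      exp(load * latent - load^2 / 2)
    # expected events = rate_p * sum(m_d / mean(m)) = rate_p * n_days
    n_ev <- rpois(n, rate * sum(m) / mean(m))
    total <- sum(n_ev)
    if (!total) next
    pool <- atc_code_pool(prefix_of[[lab]], 4L)
    recs[[ci]] <- data.table(
      patient_id = rep(patients$patient_id, n_ev),
      atc_code = sample(pool, total, replace = TRUE),
      day = sample.int(length(m), total, replace = TRUE, prob = m) - 1L,
      days_supplied = sample(config$days_supplied_values, total,
                             replace = TRUE,
                             prob = config$days_supplied_probs),
      ddd_ratio = rlnorm_trunc(total, config$ddd_meanlog[lab],
                               config$ddd_sdlog[lab]),
      class_label = lab
    )
  }
  reg <- rbindlist(recs)

  # guarantee the index-dispensing cohort property
  index_classes <- c("Antidepressants", "Anxiolytics")
  if (!any(index_classes %in% labels)) {
    stop("infeasible config: no index class present in the taxonomy")
  }
  has_index <- unique(reg[class_label %in% index_classes, patient_id])
  missing <- setdiff(patients$patient_id, has_index)
  if (length(missing)) {
    idx_rates <- config$class_base_rates[index_classes]
    idx_rates <- idx_rates[!is.na(idx_rates)]
    lab <- sample(names(idx_rates), length(missing), replace = TRUE,
                  prob = idx_rates)
    m <- day_intensity(config, 0)
    extra <- data.table(
      patient_id = missing,
      atc_code = vapply(lab, function(l) sample(atc_code_pool(
        prefix_of[[l]], 4L), 1L), character(1)),
      day = sample.int(length(m), length(missing), replace = TRUE,
                       prob = m) - 1L,
      days_supplied = sample(config$days_supplied_values, length(missing),
                             replace = TRUE,
                             prob = config$days_supplied_probs),
      ddd_ratio = rlnorm_trunc(length(missing),
                               config$ddd_meanlog[lab],
                               config$ddd_sdlog[lab]),
      class_label = lab
    )
    reg <- rbindlist(list(reg, extra))
  }

  reg[, dispense_date := win$start + day]
  reg[, c("day", "class_label") := NULL]
  reg <- patients[reg, on = "patient_id"]
  setcolorder(reg, registry_columns)
  setorder(reg, patient_id, dispense_date, atc_code)
  reg[]
}

rlnorm_trunc <- function(n, meanlog, sdlog, upper = 3) {
  meanlog <- rep_len(meanlog, n)
  sdlog <- rep_len(sdlog, n)
  x <- rlnorm(n, meanlog, sdlog)
  bad <- which(x > upper)
  for (i in seq_len(50)) {
    if (!length(bad)) break
    x[bad] <- rlnorm(length(bad), meanlog[bad], sdlog[bad])
    bad <- which(x > upper)
  }
  x[x > upper] <- upper
  x
}

#' Yearly cohort summary
#'
#' One row per calendar year in the window: number of patients with at
#' least one dispensing that year (by sex and total), the female share, and
#' mean age by sex (age = year - birth year). Years inside the window with
#' no dispensing at all still get a (zero) row.
#'
#' @param registry A dispensing registry.
#' @param window A [study_window()].
#' @return A `data.table` with columns `year`, `n_male`, `n_female`,
#'   `n_total`, `female_share`, `mean_age_male`, `mean_age_female`.
#' @export
registry_summary <- function(registry, window = study_window()) {
  dt <- as.data.table(registry)
  if (!nrow(dt)) stop("registry is empty")
  years <- seq(as.integer(format(window$start, "%Y")),
               as.integer(format(window$end, "%Y")))
  dt[, year := as.integer(format(dispense_date, "%Y"))]
  per <- dt[year %in% years,
            .(sex = sex[1L], birth_year = birth_year[1L]),
            by = .(patient_id, year)]
  out <- per[, .(
    n_male = sum(sex == "male"),
    n_female = sum(sex == "female"),
    n_total = .N,
    mean_age_male = mean((year - birth_year)[sex == "male"]),
    mean_age_female = mean((year - birth_year)[sex == "female"])
  ), by = year]
  out <- out[data.table(year = years), on = "year"]
  for (col in c("n_male", "n_female", "n_total")) {
    set(out, which(is.na(out[[col]])), col, 0L)
  }
  out[, female_share := ifelse(n_total > 0, n_female / n_total, NA_real_)]
  setcolorder(out, c("year", "n_male", "n_female", "n_total",
                     "female_share", "mean_age_male", "mean_age_female"))
  setorder(out, year)
  out[]
}
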