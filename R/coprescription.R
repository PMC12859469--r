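#' Prescription-days
#'
#' A prescription-day is one medication active on one day: seven
#' medications active on a single day account for 7 prescription-days.
#' The total over a set of patient-days is the sum of the active-set sizes
#' (distinct ATC codes).
#'
#' @param exposure Day-level exposure from [exposure_days()].
#' @param patient_ids Optional patient filter.
#' @param days Optional day-index filter.
#' @param by_patient Return a per-patient table instead of the total.
#' @return Integer total, or a `data.table` (`patient_id`, `prescription_days`).
#' @export
prescription_days <- function(exposure, patient_ids = NULL, days = NULL,
                              by_patient = FALSE) {
  ex <- as.data.table(exposure)
  if (!is.null(patient_ids)) ex <- ex[patient_id %in% patient_ids]
  if (!is.null(days)) ex <- ex[day %in% days]
  if (by_patient) {
    return(ex[, .(prescription_days = .N), by = patient_id])
  }
  nrow(ex)
}

#' Same-class and multi-class co-prescription days
#'
#' For a focal therapeutic class, `same_class_days()` counts, over
#' patient-days on which at least two distinct focal-class medications are
#' active, the number of focal-class medications active that day.
#' `multi_class_days()` counts, over patient-days on which at least one
#' focal-class and at least one other-class medication are active, the
#' number of non-focal medications active that day.
#'
#' @inheritParams prescription_days
#' @param focal_class One of the 24 class labels.
#' @return Integer total, or per-patient `data.table` when `by_patient`.
#' @export
same_class_days <- function(exposure, focal_class, patient_ids = NULL,
                            days = NULL, by_patient = FALSE) {
  ex <- as.data.table(exposure)
  if (!is.null(patient_ids)) ex <- ex[patient_id %in% patient_ids]
  if (!is.null(days)) ex <- ex[day %in% days]
  per <- ex[class_label == focal_class, .(n_focal = .N),
            by = .(patient_id, day)][n_focal >= 2L]
  if (by_patient) {
    return(per[, .(same_class_days = sum(n_focal)), by = patient_id])
  }
  sum(per$n_focal)
}

#' @rdname same_class_days
#' @export
multi_class_days <- function(exposure, focal_class, patient_ids = NULL,
                             days = NULL, by_patient = FALSE) {
  ex <- as.data.table(exposure)
  if (!is.null(patient_ids)) ex <- ex[patient_id %in% patient_ids]
  if (!is.null(days)) ex <- ex[day %in% days]
  per <- ex[, .(n_focal = sum(class_label == focal_class),
                n_other = sum(class_label != focal_class)),
            by = .(patient_id, day)][n_focal >= 1L & n_other >= 1L]
  if (by_patient) {
    return(per[, .(multi_class_days = sum(n_other)), by = patient_id])
  }
  sum(per$n_other)
}

#' Yearly co-prescription summary for focal classes
#'
#' One row per calendar year and focal class, with population totals and
#' per-person means/SDs of same-class, multi-class and total
#' prescription-days. Per-person statistics divide over the year's focal
#' cohort: patients with at least one dispensing of the focal class in
#' that calendar year (patients without co-prescription contribute zeros).
#'
#' @param exposure Day-level exposure from [exposure_days()].
#' @param registry The dispensing registry (defines yearly cohorts).
#' @param map An [atc_class_map()].
#' @param focal_classes Class labels to summarise (default antidepressants
#'   and anxiolytics).
#' @param window A [study_window()].
#' @return `data.table` with columns `year, focal_class, n_persons,
#'   same_class_total, same_class_mean, same_class_sd, multi_class_total,
#'   multi_class_mean, multi_class_sd, total_n, total_mean, total_sd`.
#' @export
coprescription_summary <- function(exposure, registry,
                                   map = atc_class_map(),
                                   focal_classes = c("Antidepressants",
                                                     "Anxiolytics"),
                                   window = study_window()) {
  ex <- copy(as.data.table(exposure))
  reg <- as.data.table(registry)
  ex[, year := as.integer(format(window$start + day, "%Y"))]
  reg_year <- reg[, .(patient_id, atc_code,
                      year = as.integer(format(dispense_date, "%Y")))]
  reg_year[, class_label := map_atc_to_class(atc_code, map)]

  per_day <- ex[, .(n_active = .N), by = .(patient_id, year, day)]
  total_py <- per_day[, .(total = sum(n_active)), by = .(patient_id, year)]

  out <- list()
  for (fc in focal_classes) {
    cohort <- unique(reg_year[class_label == fc, .(patient_id, year)])
    focal_day <- ex[, .(n_focal = sum(class_label == fc),
                        n_other = sum(class_label != fc)),
                    by = .(patient_id, year, day)]
    same_py <- focal_day[n_focal >= 2L,
                         .(same = sum(n_focal)), by = .(patient_id, year)]
    multi_py <- focal_day[n_focal >= 1L & n_other >= 1L,
                          .(multi = sum(n_other)), by = .(patient_id, year)]
    stats <- same_py[cohort, on = c("patient_id", "year")]
    stats <- multi_py[stats, on = c("patient_id", "year")]
    stats <- total_py[stats, on = c("patient_id", "year")]
    for (col in c("same", "multi", "total")) {
      set(stats, which(is.na(stats[[col]])), col, 0L)
    }
    out[[fc]] <- stats[, .(
      focal_class = fc, n_persons = .N,
      same_class_total = sum(same),
      same_class_mean = mean(same), same_class_sd = sd_pop0(same),
      multi_class_total = sum(multi),
      multi_class_mean = mean(multi), multi_class_sd = sd_pop0(multi),
      total_n = sum(total),
      total_mean = mean(total), total_sd = sd_pop0(total)
    ), by = year]
  }
  res <- rbindlist(out)
  setorder(res, focal_class, year)
  setcolorder(res, c("year", "focal_class"))
  res[]
}

# sample SD that degrades to 0 (not NA) for a single observation
sd_pop0 <- function(x) if (length(x) < 2L) 0 else sd(x)

#' General polypharmacy flag
#'
#' A patient is flagged for general polypharmacy when there is a run of at
#' least `min_days` consecutive days on each of which at least `min_meds`
#' distinct medications (ATC level-5 codes) are active. Runs may span
#' calendar-year boundaries. The flag is monotone in exposure: adding
#' medication days can never clear it.
#'
#' @param exposure Day-level exposure from [exposure_days()].
#' @param min_meds Minimum concurrent medications (default 5).
#' @param min_days Minimum consecutive days (default 30).
#' @return `data.table`: `patient_id, polypharmacy` (every patient in the
#'   exposure table appears).
#' @export
polypharmacy_flags <- function(exposure, min_meds = 5L, min_days = 30L) {
  ex <- as.data.table(exposure)
  per_day <- ex[, .(n_active = .N), by = .(patient_id, day)]
  hit <- per_day[n_active >= min_meds]
  runs <- hit[order(day), .(max_run = {
    d <- day
    if (!length(d)) 0L else max(tabulate(cumsum(c(1L, diff(d) != 1L))))
  }), by = patient_id]
  all_p <- unique(ex[, .(patient_id)])
  out <- runs[all_p, on = "patient_id"]
  out[, polypharmacy := !is.na(max_run) & max_run >= min_days]
  out[, max_run := NULL]
  setorder(out, patient_id)
  out[]
}

#' Subgroup labels per patient-year
#'
#' Labels each patient for each calendar year of the window with an age
#' group (`"<65"` / `">=65"`, age = year - birth year) and the static
#' general polypharmacy flag. A cohort capped at 65 at entry can still
#' contain a `">=65"` subgroup in later years because age is evaluated per
#' calendar year.
#'
#' @param registry The dispensing registry (supplies birth years).
#' @param exposure Day-level exposure (supplies the polypharmacy flag).
#' @param window A [study_window()].
#' @param age_cut Age threshold (default 65).
#' @return `data.table`: `patient_id, year, age_group, polypharmacy`.
#' @export
subgroup_labels <- function(registry, exposure, window = study_window(),
                            age_cut = 65L) {
  reg <- as.data.table(registry)
  births <- unique(reg[, .(patient_id, birth_year)])
  years <- seq(as.integer(format(window$start, "%Y")),
               as.integer(format(window$end, "%Y")))
  grid <- births[, .(year = years), by = .(patient_id, birth_year)]
  grid[, age_group := ifelse(year - birth_year >= age_cut, ">=65", "<65")]
  poly <- polypharmacy_flags(exposure)
  out <- poly[grid, on = "patient_id"]
  out[is.na(polypharmacy), polypharmacy := FALSE]
  out[, birth_year := NULL]
  setcolorder(out, c("patient_id", "year", "age_group", "polypharmacy"))
  setorder(out, patient_id, year)
  out[]
}

#' Run the network/centrality pipeline per subgroup
#'
#' Splits the exposure grid into disjoint subgroups and rebuilds the
#' population networks and daily centrality for each with identical
#' parameters. The assignment may be static (`patient_id, group`) or
#' yearly (`patient_id, year, group`), in which case each patient-day is
#' assigned by its calendar year; either way each patient-day lands in at
#' most one subgroup, so subgroup count matrices sum to the population
#' matrix wherever the assignment is a partition.
#'
#' @param exposure Day-level exposure from [exposure_days()].
#' @param assignment `data.table` with `patient_id`, `group` and
#'   optionally `year`. Rows with `NA` group are dropped.
#' @param map An [atc_class_map()].
#' @param params A [weight_params()].
#' @param window A [study_window()].
#' @return Named list (one element per group): `networks`
#'   (`dpn_networks`), `centrality` (daily table) and `mean_centrality`
#'   (per class over converged days, with high/low level). Empty subgroups
#'   produce a warning and are omitted.
#' @export
subgroup_run <- function(exposure, assignment, map = atc_class_map(),
                         params = weight_params(),
                         window = study_window()) {
  ex <- as.data.table(exposure)
  asg <- as.data.table(assignment)
  if ("year" %in% names(asg)) {
    ex <- copy(ex)[, year := as.integer(format(window$start + day, "%Y"))]
    ex <- asg[ex, on = c("patient_id", "year")]
  } else {
    ex <- asg[ex, on = "patient_id"]
  }
  ex <- ex[!is.na(group)]
  groups <- sort(unique(asg$group))
  out <- list()
  for (g in groups) {
    sub <- ex[group == g]
    if (!nrow(sub)) {
      warning("subgroup '", g, "' has no exposure; skipped")
      next
    }
    nets <- build_daily_networks(sub, map = map, params = params)
    cen <- daily_centrality(nets)
    mc <- cen[converged == TRUE & !is.na(centrality),
              .(mean_centrality = mean(centrality)), by = class_label]
    mc[, level := classify_centrality(mean_centrality, length(nets$labels))]
    out[[g]] <- list(networks = nets, centrality = cen,
                     mean_centrality = mc[])
  }
  out
}
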