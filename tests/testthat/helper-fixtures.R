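library(data.table)

# convenience constructor for small in-code registries
make_registry <- function(patient_id, atc_code, dispense_date,
                          days_supplied = 7L, ddd_ratio = 1,
                          sex = "female", birth_year = 1980L) {
  data.table(patient_id = patient_id, sex = sex, birth_year = birth_year,
             atc_code = atc_code,
             dispense_date = as.Date(dispense_date),
             days_supplied = as.integer(days_supplied),
             ddd_ratio = ddd_ratio)
}

# brute-force day-grid membership scan: which (patient, atc) pairs are
# active on each day, with the most recent dispensing's ddd winning
brute_active_grid <- function(intervals, n_days) {
  out <- list()
  iv <- as.data.frame(intervals)
  for (d in 0:(n_days - 1L)) {
    hit <- iv[iv$start_day <= d & d < iv$end_day, , drop = FALSE]
    if (!nrow(hit)) next
    hit <- hit[order(hit$patient_id, hit$atc_code, hit$dispense_date), ]
    keep <- !duplicated(hit[, c("patient_id", "atc_code")], fromLast = TRUE)
    hit <- hit[keep, ]
    out[[length(out) + 1L]] <- data.table(
      patient_id = hit$patient_id, day = d, atc_code = hit$atc_code,
      class_label = hit$class_label, ddd_ratio = hit$ddd_ratio)
  }
  res <- rbindlist(out)
  setkey(res, patient_id, day, atc_code)
  res[]
}

# brute-force per-pair patient counting for one day's population network
brute_pair_counts <- function(exposure, day_index, labels) {
  n <- length(labels)
  M <- matrix(0L, n, n, dimnames = list(labels, labels))
  ex <- as.data.frame(exposure[exposure$day == day_index, ])
  for (p in unique(ex$patient_id)) {
    cls <- unique(ex$class_label[ex$patient_id == p])
    idx <- match(cls, labels)
    for (i in idx) M[i, i] <- M[i, i] + 1L
    if (length(idx) >= 2L) {
      for (a in seq_along(idx)) for (b in seq_along(idx)) {
        if (a < b) {
          M[idx[a], idx[b]] <- M[idx[a], idx[b]] + 1L
          M[idx[b], idx[a]] <- M[idx[b], idx[a]] + 1L
        }
      }
    }
  }
  M
}

# internal pairing-to-assignment helper, reused by the acceptance checks
subgroup_assignment_for_tests <- function(labels_tab, pairing) {
  dpnflow:::subgroup_assignment(labels_tab, pairing)
}

# brute-force Mann-Kendall S
brute_mk_S <- function(x) {
  S <- 0L
  n <- length(x)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    S <- S + sign(x[j] - x[i])
  }
  S
}

# random small exposure fixture: k intervals over n_days for n_pat patients
random_intervals <- function(n = 50L, n_pat = 5L, n_days = 60L,
                             codes = c("N06AB06", "N06AF01", "N05BA01",
                                       "C07AB02", "A10BA02")) {
  map <- atc_class_map()
  start <- sample.int(n_days, n, replace = TRUE) - 1L
  len <- sample(1:20, n, replace = TRUE)
  dd <- as.Date("2018-01-01") + start
  data.table(
    patient_id = sprintf("P%02d", sample.int(n_pat, n, replace = TRUE)),
    atc_code = sample(codes, n, replace = TRUE),
    dispense_date = dd,
    start_day = start,
    end_day = pmin(start + len, n_days),
    ddd_ratio = round(runif(n, 0.2, 2), 2)
  )[, class_label := map_atc_to_class(atc_code, map)][]
}
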