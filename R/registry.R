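#' Study window
#'
#' The study window is the closed date range over which exposure and
#' networks are computed. All day indices in the package are 0-based
#' offsets from `start`, so `start` itself is day 0 and the window covers
#' days `0 .. n_days - 1`.
#'
#' @param start,end Window bounds, coercible to `Date`; `start < end`.
#' @return A list with `start`, `end` (Dates) and `n_days`.
#' @export
#' @examples
#' study_window("2018-01-01", "2022-12-31")$n_days  # 1826 (2020 is a leap year)
study_window <- function(start = "2018-01-01", end = "2022-12-31") {
  start <- as.Date(start)
  end <- as.Date(end)
  if (is.na(start) || is.na(end)) stop("window bounds must be valid dates")
  if (!(start < end)) stop("window start must precede window end")
  list(start = start, end = end,
       n_days = as.integer(end - start) + 1L)
}

registry_columns <- c("patient_id", "sex", "birth_year", "atc_code",
                      "dispense_date", "days_supplied", "ddd_ratio")

#' Read and write dispensing registries
#'
#' A registry is a delimited text file with one row per dispensing event and
#' header `patient_id,sex,birth_year,atc_code,dispense_date,days_supplied,
#' ddd_ratio` (dates ISO-8601). `read_registry()` parses every row,
#' rejecting rows that violate the record invariants (unknown sex,
#' non-positive `days_supplied` or `ddd_ratio`, malformed date or ATC code,
#' optionally a date outside the study window) rather than failing or
#' silently dropping them; rejected rows are reported with line numbers in
#' the `rejections` attribute and a warning.
#'
#' @param path File path.
#' @param window Optional [study_window()]; when given, records outside it
#'   are rejected.
#' @return `read_registry()`: a `data.table` of valid dispensing records,
#'   with attribute `rejections` (a `data.table` of `line`, `reason`).
#' @export
read_registry <- function(path, window = NULL) {
  if (!file.exists(path)) stop("registry file not found: ", path)
  raw <- fread(path, colClasses = "character")
  missing <- setdiff(registry_columns, names(raw))
  if (length(missing)) {
    stop("registry is missing column(s): ", paste(missing, collapse = ", "))
  }
  raw <- raw[, registry_columns, with = FALSE]
  # parse permissively, then validate row by row
  raw[, dispense_date := as.Date(dispense_date, format = "%Y-%m-%d")]
  raw[, birth_year := suppressWarnings(as.integer(birth_year))]
  raw[, days_supplied := suppressWarnings(as.integer(days_supplied))]
  raw[, ddd_ratio := suppressWarnings(as.numeric(ddd_ratio))]
  validate_registry(raw, window = window)
}

#' @rdname read_registry
#' @param registry A registry `data.table` (e.g. from [simulate_registry()]).
#' @export
write_registry <- function(registry, path) {
  out <- as.data.table(registry)[, registry_columns, with = FALSE]
  fwrite(out, path, dateTimeAs = "ISO")
  invisible(path)
}

#' @rdname read_registry
#' @details `validate_registry()` applies the same row-level checks to an
#'   in-memory table; it underlies `read_registry()`.
#' @export
validate_registry <- function(registry, window = NULL) {
  dt <- as.data.table(registry)
  reasons <- rep(NA_character_, nrow(dt))
  flag <- function(bad, why) {
    bad[is.na(bad)] <- TRUE
    reasons[is.na(reasons) & bad] <<- why
  }
  flag(!dt$sex %in% c("male", "female"), "sex must be 'male' or 'female'")
  flag(is.na(dt$birth_year), "malformed birth_year")
  flag(is.na(dt$dispense_date), "malformed dispense_date")
  flag(is.na(dt$days_supplied) | dt$days_supplied < 1L,
       "days_supplied must be a positive integer")
  flag(is.na(dt$ddd_ratio) | dt$ddd_ratio <= 0, "ddd_ratio must be positive")
  flag(!is_valid_atc(dt$atc_code) | nchar(dt$atc_code) < 3L,
       "malformed ATC code")
  if (!is.null(window)) {
    flag(dt$dispense_date < window$start | dt$dispense_date > window$end,
         "dispense_date outside study window")
  }
  keep <- is.na(reasons)
  rejections <- data.table(line = which(!keep) + 1L,  # +1 for the header
                           reason = reasons[!keep])
  if (nrow(rejections)) {
    warning(nrow(rejections), " registry row(s) rejected; see attr(x, 'rejections')")
  }
  out <- dt[keep]
  setattr(out, "rejections", rejections)
  out[]
}

#' Cohort specification
#'
#' The analysis cohort is static: a patient belongs to it if they have at
#' least one dispensing of an index class (by default antidepressants or
#' anxiolytics) inside the study window, with age at the first such
#' dispensing within `[min_age, max_age]`. Age is computed as dispensing
#' year minus birth year, since the registry carries no birth day.
#'
#' @param min_age,max_age Inclusive age bounds at first qualifying
#'   dispensing (defaults 18 and 65).
#' @param index_classes Class labels that qualify a patient for the cohort.
#' @param window A [study_window()].
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(min_age = 18, max_age = 65,
                        index_classes = c("Antidepressants", "Anxiolytics"),
                        window = study_window()) {
  if (!(min_age < max_age)) stop("min_age must be below max_age")
  if (!length(index_classes)) stop("index_classes must be non-empty")
  structure(list(min_age = min_age, max_age = max_age,
                 index_classes = index_classes, window = window),
            class = "cohort_spec")
}

#' Filter a registry to the eligible cohort
#'
#' Keeps *all* records (every therapeutic class) of patients who have at
#' least one index-class dispensing within the window and whose age at the
#' first qualifying dispensing lies in the spec's bounds. Idempotent.
#'
#' @param registry A dispensing registry `data.table`.
#' @param spec A [cohort_spec()].
#' @param map An [atc_class_map()].
#' @return The records of eligible patients.
#' @export
filter_cohort <- function(registry, spec = cohort_spec(),
                          map = atc_class_map()) {
  dt <- as.data.table(registry)
  if (!nrow(dt)) stop("registry is empty")
  lab <- map_atc_to_class(dt$atc_code, map)
  qual <- dt[lab %in% spec$index_classes &
               dispense_date >= spec$window$start &
               dispense_date <= spec$window$end]
  if (!nrow(qual)) {
    warning("no patient has an index-class dispensing in the window")
    return(dt[0])
  }
  first <- qual[order(dispense_date), .SD[1L], by = patient_id]
  first[, age := as.integer(format(dispense_date, "%Y")) - birth_year]
  eligible <- first[age >= spec$min_age & age <= spec$max_age, patient_id]
  if (!length(eligible)) warning("cohort is empty after the age filter")
  dt[patient_id %in% eligible]
}
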