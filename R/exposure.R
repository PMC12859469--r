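#' Expand dispensing records into exposure intervals
#'
#' Each dispensing covers the half-open day interval
#' `[dispense_date, dispense_date + days_supplied)`, clipped to the study
#' window and expressed as 0-based day indices from the window start.
#' Records whose interval falls entirely outside the window produce no
#' interval.
#'
#' @param registry A dispensing registry `data.table`.
#' @param window A [study_window()].
#' @param map An [atc_class_map()] used to attach class labels.
#' @return A `data.table` with columns `patient_id`, `atc_code`,
#'   `class_label`, `ddd_ratio`, `dispense_date`, `start_day`, `end_day`
#'   (half-open, `end_day > start_day`).
#' @export
#' @examples
#' win <- study_window("2018-01-01", "2018-12-31")
#' reg <- data.table::data.table(
#'   patient_id = "P1", sex = "female", birth_year = 1980,
#'   atc_code = "N06AB06", dispense_date = as.Date("2018-01-01"),
#'   days_supplied = 7L, ddd_ratio = 1)
#' expand_records(reg, win)[, .(start_day, end_day)]  # [0, 7)
expand_records <- function(registry, window = study_window(),
                           map = atc_class_map()) {
  dt <- as.data.table(registry)
  iv <- dt[, .(patient_id, atc_code,
               class_label = map_atc_to_class(atc_code, map),
               ddd_ratio, dispense_date,
               start_day = as.integer(dispense_date - window$start),
               end_day = as.integer(dispense_date - window$start) +
                 as.integer(days_supplied))]
  iv[, start_day := pmax(start_day, 0L)]
  iv[, end_day := pmin(end_day, window$n_days)]
  iv <- iv[end_day > start_day]
  setorder(iv, patient_id, atc_code, dispense_date)
  iv[]
}

# 'shift' refill policy: within patient x ATC code, a refill that overlaps
# the previous supply starts when that supply runs out, so no days are
# lost. Closed form: with intervals sorted by start, the shifted end is
# e_i = max_{j<=i}(s_j + sum_{k=j..i} len_k) = cummax(s - lag(cumsum(len)))
# + cumsum(len).
shift_refills <- function(iv, n_days) {
  iv <- copy(iv)
  setorder(iv, patient_id, atc_code, start_day, dispense_date)
  iv[, len := end_day - start_day]
  iv[, end_day := {
    cs <- cumsum(len)
    as.integer(cummax(start_day - c(0L, head(cs, -1L))) + cs)
  }, by = .(patient_id, atc_code)]
  iv[, start_day := end_day - len]
  iv[, len := NULL]
  iv[, start_day := pmin(start_day, n_days)]
  iv[, end_day := pmin(end_day, n_days)]
  iv[end_day > start_day]
}

#' Daily active-medication exposure
#'
#' Expands exposure intervals to a day-level grid: one row per patient,
#' day and distinct ATC code active on that day. Overlapping dispensings
#' of the same code are handled by the refill policy: `"union"` (default)
#' takes the day-level union, so overlapping days are not extended;
#' `"shift"` postpones a refill that overlaps the previous supply until
#' that supply runs out. When several dispensings of a code cover the same
#' day, the most recent dispensing's DDD ratio wins (the latest
#' prescription reflects the current regimen).
#'
#' @param intervals Output of [expand_records()].
#' @param window A [study_window()].
#' @param refill_policy `"union"` or `"shift"`.
#' @return A `data.table` keyed by `patient_id`, `day`, `atc_code` with
#'   `class_label` and `ddd_ratio`; set semantics (no duplicated code per
#'   patient-day).
#' @export
exposure_days <- function(intervals, window = study_window(),
                          refill_policy = c("union", "shift")) {
  refill_policy <- match.arg(refill_policy)
  iv <- as.data.table(intervals)
  if (refill_policy == "shift") iv <- shift_refills(iv, window$n_days)
  if (!nrow(iv)) {
    return(data.table(patient_id = character(), day = integer(),
                      atc_code = character(), class_label = character(),
                      ddd_ratio = numeric()))
  }
  n <- iv$end_day - iv$start_day
  out <- iv[rep.int(seq_len(.N), n)]
  out[, day := rep.int(iv$start_day, n) + (sequence(n) - 1L)]
  # most recent dispensing wins on overlapping days
  setorder(out, patient_id, atc_code, day, dispense_date)
  out <- unique(out, by = c("patient_id", "atc_code", "day"), fromLast = TRUE)
  out <- out[, .(patient_id, day, atc_code, class_label, ddd_ratio)]
  setkey(out, patient_id, day, atc_code)
  out[]
}

#' @rdname exposure_days
#' @param exposure A day-level exposure table from `exposure_days()`.
#' @param day_index A single 0-based day index.
#' @return `daily_active_set()`: the rows active on `day_index`.
#' @export
daily_active_set <- function(exposure, day_index) {
  exposure[day == day_index]
}
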