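#' Detrend a daily or weekly series
#'
#' Removes a slowly varying trend before seasonal inspection. The default
#' estimator is a centred moving average (window shrinks symmetrically at
#' the edges); `"ssa_trend"` instead subtracts the leading-eigentriple
#' trend of a singular spectrum decomposition (see [two_stage_ssa()]),
#' which is the pipeline-consistent alternative.
#'
#' @param values Numeric series.
#' @param method `"moving_average"` or `"ssa_trend"`.
#' @param window Moving-average window (odd; default 29 for daily data,
#'   use 13 for weekly) or the SSA lag.
#' @return Numeric residual series (`values` minus trend), same length.
#' @export
detrend <- function(values, method = c("moving_average", "ssa_trend"),
                    window = 29L) {
  method <- match.arg(method)
  n <- length(values)
  if (n <= window) stop("series must be longer than the window")
  if (any(!is.finite(values))) stop("series must be finite")
  trend <- if (method == "moving_average") {
    h <- (as.integer(window) - 1L) %/% 2L
    vapply(seq_len(n), function(i) {
      r <- min(h, i - 1L, n - i)  # shrink at the edges, keep centring
      mean(values[(i - r):(i + r)])
    }, numeric(1))
  } else {
    model <- ssa_embed(values, L = min(window, n - 1L))
    ssa_reconstruct(model, 1L)
  }
  values - trend
}

#' Deconstruct a series by its seasonal period
#'
#' Reshapes a series into (period instance, position within period, value)
#' long format for overlap inspection: daily data by ISO week (positions
#' Mon..Sun), weekly data by year (positions = ISO week numbers). Every
#' input point appears exactly once.
#'
#' @param index For `weekday_by_week`: a `Date` vector; for
#'   `week_by_year`: character ISO week labels `"YYYY-Www"`.
#' @param values Numeric series aligned with `index`.
#' @param period `"weekday_by_week"` or `"week_by_year"`.
#' @return `data.table`: `period_instance, position, value`; positions are
#'   ordered factors (`Mon..Sun`, or week numbers).
#' @export
seasonal_deconstruct <- function(index, values,
                                 period = c("weekday_by_week",
                                            "week_by_year")) {
  period <- match.arg(period)
  if (length(index) != length(values)) stop("index/values length mismatch")
  if (period == "weekday_by_week") {
    dates <- as.Date(index)
    out <- data.table(
      period_instance = iso_week_label(dates),
      position = factor(c("Mon", "Tue", "Wed", "Thu", "Fri", "Sat",
                          "Sun")[as.integer(format(dates, "%u"))],
                        levels = c("Mon", "Tue", "Wed", "Thu", "Fri",
                                   "Sat", "Sun"), ordered = TRUE),
      value = values)
  } else {
    lab <- as.character(index)
    ok <- grepl("^[0-9]{4}-W[0-9]{2}$", lab)
    if (!all(ok)) stop("week labels must look like 'YYYY-Www'")
    out <- data.table(
      period_instance = substr(lab, 1L, 4L),
      position = factor(as.integer(substr(lab, 7L, 8L)), levels = 1:53,
                        ordered = TRUE),
      value = values)
  }
  out[]
}

#' Autocorrelation and partial autocorrelation with significance band
#'
#' ACF uses the standard biased (1/N) autocovariance estimator (which
#' keeps the sequence positive semi-definite); PACF comes from the
#' Durbin-Levinson recursion on those autocorrelations. The white-noise
#' significance band is `+/- 1.96 / sqrt(N)`.
#'
#' @param values Numeric series (finite, non-constant).
#' @param max_lag Largest lag (default `10 * log10(N)` as usual).
#' @return `data.table`: `lag` (0..max_lag), `acf` (1 at lag 0), `pacf`
#'   (`NA` at lag 0), `band`.
#' @export
acf_pacf <- function(values, max_lag = NULL) {
  n <- length(values)
  if (any(!is.finite(values))) stop("series must be finite")
  if (var(values) == 0) stop("series has zero variance")
  if (is.null(max_lag)) max_lag <- floor(10 * log10(n))
  max_lag <- as.integer(max_lag)
  if (n <= max_lag + 1L) stop("series too short for max_lag = ", max_lag)
  a <- as.numeric(acf(values, lag.max = max_lag, plot = FALSE,
                      demean = TRUE)$acf)
  p <- as.numeric(pacf(values, lag.max = max_lag, plot = FALSE)$acf)
  data.table(lag = 0:max_lag, acf = a, pacf = c(NA_real_, p),
             band = 1.96 / sqrt(n))
}
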