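#' Eigenvector centrality of a weighted symmetric network
#'
#' Computes the dominant eigenvector of a symmetric non-negative adjacency
#' matrix by power iteration from the uniform vector, normalised so the
#' centralities sum to 1 (L1). With that normalisation the uniformly
#' connected unweighted network has centrality exactly `1/n` per node,
#' which is the package's baseline for classifying classes as high or low.
#'
#' A zero matrix has no meaningful centrality: the result is all-`NA` and
#' flagged not converged. For disconnected graphs the iteration converges
#' to the dominant component's eigenvector (the rest get ~0).
#'
#' @param W Symmetric non-negative matrix with zero diagonal.
#' @param tol L1 convergence tolerance on successive iterates
#'   (default 1e-10).
#' @param max_iter Iteration cap (default 10000).
#' @return A list of class `centrality_vector`: `c` (non-negative, sums to
#'   1), `lambda` (leading eigenvalue), `converged`, `iterations`.
#' @export
#' @examples
#' A <- matrix(1, 24, 24); diag(A) <- 0
#' eigenvector_centrality(A)$c[1]  # 1/24
eigenvector_centrality <- function(W, tol = 1e-10, max_iter = 10000L) {
  if (!is.matrix(W) || nrow(W) != ncol(W)) stop("W must be square")
  if (any(!is.finite(W))) stop("W contains non-finite entries")
  if (any(W < 0)) stop("W contains negative entries")
  if (max(abs(W - t(W))) > 1e-12 * max(1, max(abs(W)))) {
    stop("W must be symmetric")
  }
  n <- nrow(W)
  if (all(W == 0)) {
    return(structure(list(c = setNames(rep(NA_real_, n), rownames(W)),
                          lambda = 0, converged = FALSE, iterations = 0L),
                     class = "centrality_vector"))
  }
  # diagonal shift: W + aI has the same eigenvectors but strictly
  # dominant leading eigenvalue even for bipartite graphs, whose +/-
  # lambda pair would otherwise make plain power iteration oscillate
  shift <- 0.1 * max(rowSums(W))
  Ws <- W + diag(shift, n)
  v <- rep(1 / n, n)
  lambda <- 0
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    u <- as.vector(Ws %*% v)
    s <- sum(u)
    if (s == 0) break  # uniform start in the null space (cannot happen for
                       # non-negative nonzero symmetric W)
    u <- u / s
    if (sum(abs(u - v)) < tol) {
      v <- u
      converged <- TRUE
      break
    }
    v <- u
  }
  lambda <- sum(v * as.vector(W %*% v)) / sum(v * v)  # Rayleigh quotient
  structure(list(c = setNames(v, rownames(W)), lambda = lambda,
                 converged = converged, iterations = iter),
            class = "centrality_vector")
}

#' Classify centrality against the uniform baseline
#'
#' In a uniformly connected unweighted network every node has centrality
#' `1/n`; a class is "high" iff its (mean) centrality strictly exceeds
#' that baseline. Ties at exactly `1/n` are classified low.
#'
#' @param mean_c Centrality value(s) in `[0, 1]`.
#' @param n Number of network nodes (default 24).
#' @return `"high"`/`"low"` character vector (`NA` in, `NA` out).
#' @export
#' @examples
#' classify_centrality(0.09)  # "high": above 1/24
classify_centrality <- function(mean_c, n = 24L) {
  ifelse(is.na(mean_c), NA_character_,
         ifelse(mean_c > 1 / n, "high", "low"))
}

#' Daily centrality series for a stack of population networks
#'
#' Runs [eigenvector_centrality()] on every day's weighted matrix.
#'
#' @param networks A `dpn_networks` object from [build_daily_networks()].
#' @param days Optional integer vector of day indices (default: all days
#'   present in the edge table).
#' @return A `data.table`: `day, class_label, centrality, lambda,
#'   converged`; days whose weighted matrix is all zero carry `NA`
#'   centrality.
#' @export
daily_centrality <- function(networks, days = NULL) {
  if (is.null(days)) days <- sort(unique(networks$edges$day))
  res <- vector("list", length(days))
  for (k in seq_along(days)) {
    W <- network_matrix(networks, days[k], type = "weighted")
    ev <- eigenvector_centrality(W)
    res[[k]] <- data.table(day = days[k], class_label = networks$labels,
                           centrality = as.numeric(ev$c),
                           lambda = ev$lambda, converged = ev$converged)
  }
  rbindlist(res)
}

#' ISO-8601 week labels
#'
#' @param dates A `Date` vector.
#' @return Labels `"YYYY-Www"` (ISO week-based year and week number).
#' @export
#' @examples
#' iso_week_label(as.Date("2018-01-01"))  # "2018-W01"
iso_week_label <- function(dates) {
  format(dates, "%G-W%V")
}

#' Daily dispensing metrics
#'
#' The three count metrics tracked alongside centrality: number of
#' dispensings per day, number of distinct patients dispensed per day and
#' their ratio; one row per calendar day of the window (zero rows for
#' days without dispensing).
#'
#' @param registry A dispensing registry.
#' @param window A [study_window()].
#' @return `data.table`: `day, date, n_dispensings, n_patients, ratio`.
#' @export
daily_metrics <- function(registry, window = study_window()) {
  dt <- as.data.table(registry)
  dt <- dt[dispense_date >= window$start & dispense_date <= window$end]
  per <- dt[, .(n_dispensings = .N,
                n_patients = uniqueN(patient_id)),
            by = .(date = dispense_date)]
  grid <- data.table(date = seq(window$start, window$end, by = "day"))
  out <- per[grid, on = "date"]
  for (col in c("n_dispensings", "n_patients")) {
    set(out, which(is.na(out[[col]])), col, 0L)
  }
  out[, day := as.integer(date - window$start)]
  out[, ratio := ifelse(n_patients > 0, n_dispensings / n_patients, NA_real_)]
  setcolorder(out, c("day", "date", "n_dispensings", "n_patients", "ratio"))
  setorder(out, day)
  out[]
}

#' Aggregate daily metrics and centrality to ISO weeks
#'
#' Counts are summed within the ISO week and the dispensing-to-patient
#' ratio recomputed from the weekly sums; centrality is averaged over the
#' week's converged days (weeks with no converged day get `NA`), then
#' classified against the `1/n` baseline.
#'
#' @param daily A [daily_metrics()] table.
#' @param centrality A [daily_centrality()] table.
#' @param window A [study_window()] (maps day indices to dates).
#' @return `data.table`: `week, n_dispensings, n_patients, ratio,
#'   class_label, mean_centrality, level`.
#' @export
weekly_aggregate <- function(daily, centrality, window = study_window()) {
  d <- as.data.table(daily)
  d[, week := iso_week_label(date)]
  wk <- d[, .(n_dispensings = sum(n_dispensings),
              n_patients = sum(n_patients)), by = week]
  wk[, ratio := ifelse(n_patients > 0, n_dispensings / n_patients, NA_real_)]

  ce <- as.data.table(centrality)
  ce[, week := iso_week_label(window$start + day)]
  cw <- ce[, .(mean_centrality = {
    ok <- converged & !is.na(centrality)
    if (any(ok)) mean(centrality[ok]) else NA_real_
  }), by = .(week, class_label)]
  n <- uniqueN(ce$class_label)
  cw[, level := classify_centrality(mean_centrality, n)]

  out <- cw[wk, on = "week"]
  setorder(out, week, class_label)
  setcolorder(out, c("week", "n_dispensings", "n_patients", "ratio",
                     "class_label", "mean_centrality", "level"))
  out[]
}
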