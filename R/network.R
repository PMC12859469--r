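#' Gaussian DDD edge-weighting parameters
#'
#' Edge weights down-weight co-prescriptions whose prescribed daily dose
#' deviates from the expected one DDD. Each medication (or class) gets a
#' weight from a Gaussian kernel centred at the baseline DDD ratio of 1:
#'
#' `omega(d) = 1 / (sigma * sqrt(2*pi)) * exp(-(d - 1)^2 / (2 * sigma^2))`
#'
#' and an edge averages the two endpoint weights. With the default
#' `sigma = 1/3` the kernel value at `d = 1` is `3/sqrt(2*pi) ~= 1.197`;
#' `peak_normalized = TRUE` rescales so the peak is exactly 1.
#'
#' @param sigma Kernel standard deviation on the DDD-ratio scale
#'   (default 1/3, giving a gradual reduction as the dose leaves 1).
#' @param mode How endpoint weights are obtained: `"per_record"` computes
#'   a weight from each active medication's own DDD ratio (averaged within
#'   patient-day-class), `"class_mean"` uses one weight per class from the
#'   class's mean DDD ratio.
#' @param combine `"multiply_counts"` (default) multiplies the averaged
#'   pair weight into the co-prescription count so edge strength keeps
#'   frequency information; `"literal_eq4"` stores the bare averaged pair
#'   weight wherever the count is positive (frequency-free variant).
#' @param peak_normalized Rescale the kernel so its maximum is 1.
#' @return A list of class `weight_params`.
#' @export
weight_params <- function(sigma = 1 / 3,
                          mode = c("per_record", "class_mean"),
                          combine = c("multiply_counts", "literal_eq4"),
                          peak_normalized = FALSE) {
  if (!is.numeric(sigma) || sigma <= 0) stop("sigma must be positive")
  structure(list(sigma = sigma, mode = match.arg(mode),
                 combine = match.arg(combine),
                 peak_normalized = isTRUE(peak_normalized)),
            class = "weight_params")
}

#' Gaussian kernel weight of a DDD ratio
#'
#' @param ddd Positive DDD ratio(s) (prescribed daily dose / WHO DDD).
#' @param params A [weight_params()].
#' @return Numeric weights.
#' @export
#' @examples
#' gaussian_weight(1)            # 3/sqrt(2*pi) ~= 1.19683
#' gaussian_weight(1, weight_params(peak_normalized = TRUE))  # 1
gaussian_weight <- function(ddd, params = weight_params()) {
  if (any(!is.finite(ddd)) || any(ddd <= 0)) {
    stop("ddd must be positive and finite")
  }
  s <- params$sigma
  w <- exp(-(ddd - 1)^2 / (2 * s^2)) / (s * sqrt(2 * pi))
  if (params$peak_normalized) w <- w * s * sqrt(2 * pi)
  w
}

#' Average two endpoint weights into an edge weight
#'
#' @param omega_i,omega_j Positive endpoint weights.
#' @return `(omega_i + omega_j) / 2`, vectorised.
#' @export
edge_weight <- function(omega_i, omega_j) {
  (omega_i + omega_j) / 2
}

#' Individual daily co-prescription network
#'
#' Binary symmetric 24 x 24 adjacency for one patient-day: entry (i, j),
#' i != j, is 1 iff classes i and j both have at least one active
#' medication that day; the diagonal is zero. With k distinct active
#' classes the network has k(k-1)/2 edges.
#'
#' @param active A [daily_active_set()] table for one patient-day (columns
#'   `class_label`, at minimum).
#' @param map An [atc_class_map()] fixing node order.
#' @return An n x n 0/1 matrix with dimnames the class labels.
#' @export
build_individual_daily <- function(active, map = atc_class_map()) {
  labels <- atc_class_labels(map)
  n <- length(labels)
  A <- matrix(0L, n, n, dimnames = list(labels, labels))
  cls <- unique(active$class_label)
  idx <- match(cls, labels)
  if (anyNA(idx)) stop("active set contains unknown class label(s)")
  if (length(idx) >= 2L) {
    pairs <- utils::combn(idx, 2L)
    A[cbind(pairs[1L, ], pairs[2L, ])] <- 1L
    A[cbind(pairs[2L, ], pairs[1L, ])] <- 1L
  }
  A
}

#' Aggregate individual daily networks into a population network
#'
#' Element-wise sum of the individual binary adjacencies of one day; the
#' off-diagonal entry (i, j) counts patients with classes i and j
#' concurrently active that day. The diagonal is filled with the number of
#' patients having class i active (single-class dispensing counts); it is
#' excluded from network analyses downstream.
#'
#' @param networks List of matrices from [build_individual_daily()], plus
#'   optionally per-patient active class index lists for the diagonal.
#' @param active_classes Optional list (one element per patient) of active
#'   class indices/labels used to fill the diagonal; when `NULL` the
#'   diagonal counts patients that appear in any edge only.
#' @return Integer count matrix.
#' @export
aggregate_population <- function(networks, active_classes = NULL) {
  if (!length(networks)) stop("no networks to aggregate")
  dims <- vapply(networks, function(m) nrow(m), integer(1))
  if (length(unique(dims)) != 1L) stop("networks have mixed dimensions")
  counts <- Reduce(`+`, networks)
  if (!is.null(active_classes)) {
    labels <- rownames(networks[[1L]])
    for (cls in active_classes) {
      idx <- if (is.character(cls)) match(cls, labels) else cls
      counts[cbind(idx, idx)] <- counts[cbind(idx, idx)] + 1L
    }
  }
  counts
}

#' Build daily population networks from the exposure grid
#'
#' Computes, for every day of the window, the population count matrix
#' (off-diagonal: number of patients with the class pair concurrently
#' active; diagonal: number of patients with the class active) and its
#' DDD-weighted counterpart, in a sparse long format.
#'
#' In `per_record` mode every active medication contributes the Gaussian
#' weight of its own DDD ratio, averaged within patient-day-class, and an
#' edge accumulates `(omega_i + omega_j)/2` over patients; in
#' `class_mean` mode one weight per class (from `class_ddd`, the mean DDD
#' ratio per class) multiplies the count. `literal_eq4` stores the bare
#' pair weight wherever the count is positive. The weighted diagonal is
#' always zero (no self-loops).
#'
#' @param exposure Day-level exposure from [exposure_days()].
#' @param map An [atc_class_map()].
#' @param params A [weight_params()].
#' @param class_ddd Optional named per-class mean DDD ratio (required for
#'   `class_mean` and `literal_eq4`; defaults to the exposure-table means).
#' @return An object of class `dpn_networks`: list with `edges`
#'   (`data.table`: `day, class_i, class_j, count, weight`, `class_i <
#'   class_j` by node index), `diag` (`day, class_label, count`), `labels`,
#'   `n`, `params`.
#' @export
build_daily_networks <- function(exposure, map = atc_class_map(),
                                 params = weight_params(),
                                 class_ddd = NULL) {
  labels <- atc_class_labels(map)
  ex <- as.data.table(exposure)
  if (!nrow(ex)) stop("exposure grid is empty")
  ex[, class_id := match(class_label, labels)]
  if (anyNA(ex$class_id)) stop("exposure contains unknown class label(s)")

  # per patient-day-class: number of active meds and mean per-record weight
  pdc <- ex[, .(n_meds = .N,
                omega = mean(gaussian_weight(ddd_ratio, params))),
            by = .(patient_id, day, class_id)]

  if (params$mode == "class_mean" || params$combine == "literal_eq4") {
    if (is.null(class_ddd)) {
      cm <- ex[, .(m = mean(ddd_ratio)), by = class_id]
      class_omega <- rep(NA_real_, length(labels))
      class_omega[cm$class_id] <- gaussian_weight(cm$m, params)
    } else {
      if (!all(labels %in% names(class_ddd))) {
        stop("class_ddd must name every class label")
      }
      class_omega <- gaussian_weight(class_ddd[labels], params)
    }
  }
  if (params$mode == "class_mean") {
    pdc[, omega := class_omega[class_id]]
  }

  # all ordered pairs (i <= j) of classes active within a patient-day
  pairs <- pdc[pdc, on = .(patient_id, day), allow.cartesian = TRUE]
  pairs <- pairs[class_id <= i.class_id]
  edges <- pairs[class_id < i.class_id,
                 .(count = .N, weight = sum(edge_weight(omega, i.omega))),
                 by = .(day, class_i = class_id, class_j = i.class_id)]
  diag_dt <- pdc[, .(count = .N), by = .(day, class_id)]

  if (params$combine == "literal_eq4") {
    edges[, weight := edge_weight(class_omega[class_i],
                                  class_omega[class_j]) * (count > 0)]
  } else if (params$mode == "class_mean") {
    # count x averaged class-pair weight (the per-patient sum already
    # equals this, but recompute exactly to avoid float accumulation)
    edges[, weight := count * edge_weight(class_omega[class_i],
                                          class_omega[class_j])]
  }

  setorder(edges, day, class_i, class_j)
  diag_out <- diag_dt[, .(day, class_label = labels[class_id], count)]
  setorder(diag_out, day, class_label)
  structure(list(edges = edges[], diag = diag_out[], labels = labels,
                 n = length(labels), params = params),
            class = "dpn_networks")
}

#' Apply DDD weighting to a population count matrix
#'
#' Matrix-level counterpart of the weighting built into
#' [build_daily_networks()], for class-level weights: given the count
#' matrix and one weight per class, fills the weighted matrix either as
#' `counts_ij * (omega_i + omega_j)/2` (`multiply_counts`) or as the bare
#' pair average wherever the count is positive (`literal_eq4`). The
#' diagonal is forced to zero in both modes.
#'
#' @param counts Symmetric non-negative count matrix.
#' @param omega Per-class weights, one per row of `counts` (named vectors
#'   are matched against the dimnames).
#' @param params A [weight_params()]; only `combine` is used.
#' @return The weighted matrix.
#' @export
apply_weighting <- function(counts, omega, params = weight_params()) {
  n <- nrow(counts)
  if (!is.null(names(omega)) && !is.null(rownames(counts))) {
    omega <- omega[rownames(counts)]
  }
  if (length(omega) != n || anyNA(omega)) {
    stop("omega must supply one weight per class")
  }
  pair <- outer(omega, omega, edge_weight)
  W <- if (params$combine == "literal_eq4") {
    pair * (counts > 0)
  } else {
    counts * pair
  }
  diag(W) <- 0
  W
}

#' Extract one day's adjacency matrix
#'
#' @param networks A `dpn_networks` object.
#' @param day_index 0-based day index.
#' @param type `"weighted"` (zero diagonal) or `"counts"` (diagonal holds
#'   single-class active-patient counts).
#' @return A symmetric n x n matrix with class-label dimnames.
#' @export
network_matrix <- function(networks, day_index,
                           type = c("weighted", "counts")) {
  type <- match.arg(type)
  n <- networks$n
  A <- matrix(0, n, n, dimnames = list(networks$labels, networks$labels))
  e <- networks$edges[day == day_index]
  val <- if (type == "weighted") e$weight else e$count
  A[cbind(e$class_i, e$class_j)] <- val
  A[cbind(e$class_j, e$class_i)] <- val
  if (type == "counts") {
    d <- networks$diag[day == day_index]
    A[cbind(match(d$class_label, networks$labels),
            match(d$class_label, networks$labels))] <- d$count
  }
  A
}
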