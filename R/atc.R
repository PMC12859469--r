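#' The 24-class ATC therapeutic taxonomy
#'
#' Drug prescription networks in this package use 24 nodes: one per
#' therapeutic class obtained by grouping ATC codes with longest-prefix
#' rules. The whole-root classes (A, B, C, ...) cover one anatomical main
#' group each, while the nervous system root N is split at the second or
#' third level so that antidepressants (N06A), anxiolytics (N05B),
#' antipsychotics (N05A), hypnotics/sedatives (N05C), analgesics (N02) and
#' the remaining N subgroups are separate nodes.
#'
#' `atc_class_map()` returns the rule table, either the packaged default or
#' one read from a two-column `atc_prefix,class_label` CSV, validated to
#' contain exactly 24 distinct labels covering every ATC root.
#'
#' @param path Optional path to a CSV with columns `atc_prefix,class_label`.
#'   When `NULL` the packaged default table is used.
#' @return A `data.table` with columns `atc_prefix`, `class_label` and
#'   `class_id` (the canonical node index 1..24), ordered by prefix;
#'   attribute `class_labels` carries the node order used by all network
#'   matrices.
#' @export
#' @examples
#' map <- atc_class_map()
#' nrow(map)                       # 24 rules
#' map_atc_to_class("N06AB06", map)
atc_class_map <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "atc_class_map.csv", package = "dpnflow")
  }
  if (!file.exists(path)) stop("ATC class map file not found: ", path)
  map <- fread(path, colClasses = "character")
  if (!all(c("atc_prefix", "class_label") %in% names(map))) {
    stop("ATC class map must have columns 'atc_prefix' and 'class_label'")
  }
  validate_atc_class_map(map)
}

validate_atc_class_map <- function(map) {
  map <- as.data.table(map)[, .(atc_prefix, class_label)]
  labels <- unique(map$class_label)
  if (length(labels) != 24L) {
    stop("ATC class map must define exactly 24 distinct class labels, got ",
         length(labels))
  }
  roots <- c("A", "B", "C", "D", "G", "H", "J", "L", "M", "N", "P", "R",
             "S", "V")
  covered <- vapply(roots, function(r) any(startsWith(map$atc_prefix, r)),
                    logical(1))
  if (!all(covered)) {
    stop("ATC class map must cover every ATC root; missing: ",
         paste(roots[!covered], collapse = ", "))
  }
  n_prefixes <- c("N01", "N02", "N03", "N04", "N05A", "N05B", "N05C",
                  "N06A", "N06B", "N06D", "N07")
  if (!all(n_prefixes %in% map$atc_prefix)) {
    stop("ATC class map must split the N root at prefixes: ",
         paste(setdiff(n_prefixes, map$atc_prefix), collapse = ", "))
  }
  setorder(map, atc_prefix)
  # node order: first occurrence order after prefix sort (stable, documented)
  class_labels <- unique(map$class_label)
  map[, class_id := match(class_label, class_labels)]
  setattr(map, "class_labels", class_labels)
  setattr(map, "class", c("atc_class_map", class(map)))
  map
}

#' @rdname atc_class_map
#' @param map An `atc_class_map` object.
#' @return `atc_class_labels()`: character vector of the 24 node labels in
#'   canonical order.
#' @export
atc_class_labels <- function(map) attr(map, "class_labels", exact = TRUE)

#' Syntactic validity of ATC codes
#'
#' A valid (possibly truncated) ATC code is a letter, two digits, then
#' optionally one letter, one more letter, and two final digits: lengths
#' 1, 3, 4, 5 or 7. Codes shorter than 3 characters are rejected for
#' registry use.
#'
#' @param atc_code Character vector of candidate codes.
#' @return Logical vector.
#' @export
is_valid_atc <- function(atc_code) {
  grepl("^[A-Z][0-9]{2}([A-Z]([A-Z]([0-9]{2})?)?)?$", atc_code)
}

#' Map ATC codes to therapeutic classes
#'
#' Longest-prefix match against the rule table: among all rules whose
#' `atc_prefix` is a prefix of the code, the longest wins. Every valid code
#' maps to exactly one of the 24 labels; codes matching no rule raise an
#' error naming the offending code (silent drops would bias network counts)
#' unless `ignore_unmapped = TRUE`, in which case they yield `NA`.
#'
#' @param atc_code Character vector of ATC codes (>= 3 characters).
#' @param map An [atc_class_map()] rule table.
#' @param ignore_unmapped Return `NA` for unmapped codes instead of erroring.
#' @return Character vector of class labels.
#' @export
#' @examples
#' map <- atc_class_map()
#' map_atc_to_class(c("N06AB06", "N05BA01", "A10BA02"), map)
map_atc_to_class <- function(atc_code, map, ignore_unmapped = FALSE) {
  bad <- !is_valid_atc(atc_code) | nchar(atc_code) < 3L
  if (any(bad)) {
    stop("invalid ATC code(s): ",
         paste(unique(atc_code[bad])[1:min(5, sum(bad))], collapse = ", "))
  }
  out <- rep(NA_character_, length(atc_code))
  rules <- as.data.table(map)[order(-nchar(atc_prefix))]
  for (k in seq_len(nrow(rules))) {
    hit <- is.na(out) & startsWith(atc_code, rules$atc_prefix[k])
    out[hit] <- rules$class_label[k]
  }
  if (anyNA(out) && !ignore_unmapped) {
    stop("unmapped ATC code(s): ",
         paste(unique(atc_code[is.na(out)])[1:min(5, sum(is.na(out)))],
               collapse = ", "),
         " (pass ignore_unmapped = TRUE to drop them)")
  }
  out
}

# Per-class reference metadata used for simulator defaults: relative
# dispensing share, lognormal DDD-ratio location/spread (class means < 1,
# within-class spread), and a multimorbidity loading linking the latent
# patient factor to chronic-disease classes.
atc_class_defaults <- function() {
  dt <- data.table(
    atc_prefix = c("A", "B", "C", "D", "G", "H", "J", "L", "M",
                   "N01", "N02", "N03", "N04", "N05A", "N05B", "N05C",
                   "N06A", "N06B", "N06D", "N07", "P", "R", "S", "V"),
    class_label = c("Alimentary and metabolism", "Blood", "Cardiovascular",
                    "Dermatologicals", "Genitourinary", "Systemic hormonal",
                    "Systemic anti-infectives", "Antineoplastics",
                    "Musculoskeletal", "Anesthetic", "Analgesics",
                    "Antiepileptics", "Antiparkinson", "Antipsychotics",
                    "Anxiolytics", "Hypnotics and sedatives",
                    "Antidepressants", "Psychostimulants", "Antidementia",
                    "Other nervous system drugs", "Antiparasitics",
                    "Respiratory", "Sensory", "Others"),
    dispensing_share = c(11512424, 2908944, 9778030, 2086095, 2099833,
                         1602716, 734706, 449030, 1449535, 39455, 2557528,
                         1078266, 306541, 2473609, 2644309, 1467752,
                         6108776, 459207, 9937, 362624, 88760, 5492900,
                         196513, 18157),
    ddd_mean = c(0.597, 0.693, 0.538, 0.808, 0.746, 0.497, 0.634, 0.613,
                 0.559, 0.645, 0.423, 0.429, 0.353, 0.404, 0.463, 0.631,
                 0.536, 0.520, 0.680, 0.523, 0.524, 0.655, 0.466, 0.455),
    ddd_sd = c(0.326, 0.391, 0.305, 0.339, 0.369, 0.276, 0.323, 0.301,
               0.326, 0.447, 0.260, 0.252, 0.221, 0.265, 0.288, 0.316,
               0.309, 0.313, 0.285, 0.316, 0.253, 0.325, 0.287, 0.273),
    comorbidity_loading = c(0.7, 0.7, 0.8, 0.3, 0.5, 0.5, 0.3, 0.4, 0.5,
                            0.2, 0.6, 0.3, 0.3, 0.2, 0.2, 0.3, 0.2, 0.2,
                            0.3, 0.3, 0.2, 0.5, 0.3, 0.2)
  )
  dt[, dispensing_share := dispensing_share / sum(dispensing_share)]
  dt[]
}

# deterministic pool of syntactically valid level-5 codes under a prefix;
# used by the simulator so same-class co-prescription is possible
atc_code_pool <- function(prefix, k = 4L) {
  stopifnot(k >= 1L, k <= 26L)
  n <- nchar(prefix)
  letters5 <- LETTERS[seq_len(k)]
  if (n == 1L) {
    paste0(prefix, "02", "A", letters5, "01")
  } else if (n == 3L) {
    paste0(prefix, "A", letters5, "01")
  } else if (n == 4L) {
    paste0(prefix, letters5, "01")
  } else if (n == 5L) {
    paste0(prefix, sprintf("%02d", seq_len(k)))
  } else {
    rep(prefix, k)
  }
}
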