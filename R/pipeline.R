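#' Pipeline configuration
#'
#' Bundles every knob of the end-to-end analysis: where the registry comes
#' from (a CSV path, or the simulator when `registry_path` is `NULL`), the
#' study window, cohort rule, refill policy, edge-weighting parameters,
#' subgroup pairings and SSA settings. All method parameters default to
#' the analysis' canonical values (`sigma = 1/3`, `L1 = 52`, `k = 25`,
#' polypharmacy = 5 medications for 30 consecutive days, age cut 65), so
#' any deviation is explicit in the config.
#'
#' @param registry_path Optional path to a registry CSV; `NULL` simulates.
#' @param sim A [simulation_config()] used when simulating (its window and
#'   seed are overridden by `window`/`seed` here).
#' @param window A [study_window()].
#' @param cohort A [cohort_spec()] or `NULL` to skip cohort filtering
#'   (simulated registries are already cohorts by construction).
#' @param weights A [weight_params()].
#' @param refill_policy `"union"` or `"shift"` (see [exposure_days()]).
#' @param subgroup_pairings Character subset of
#'   `c("age", "polypharmacy", "combined")`.
#' @param ssa_L1,ssa_k,ssa_trend_components Stage-1 window, number of
#'   stage-2 components and trend eigentriple group for [two_stage_ssa()].
#' @param focal_classes Classes whose weekly series are decomposed and
#'   summarised.
#' @param seed Integer seed for the simulator.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(registry_path = NULL,
                            sim = NULL,
                            window = study_window(),
                            cohort = NULL,
                            weights = weight_params(),
                            refill_policy = "union",
                            subgroup_pairings = c("age", "polypharmacy",
                                                  "combined"),
                            ssa_L1 = 52L, ssa_k = 25L,
                            ssa_trend_components = 1L,
                            focal_classes = c("Antidepressants",
                                              "Anxiolytics"),
                            seed = 1L) {
  if (!is.null(registry_path) && !file.exists(registry_path)) {
    stop("registry file not found: ", registry_path)
  }
  subgroup_pairings <- match.arg(subgroup_pairings,
                                 c("age", "polypharmacy", "combined"),
                                 several.ok = TRUE)
  structure(list(registry_path = registry_path, sim = sim, window = window,
                 cohort = cohort, weights = weights,
                 refill_policy = refill_policy,
                 subgroup_pairings = subgroup_pairings,
                 ssa_L1 = as.integer(ssa_L1), ssa_k = as.integer(ssa_k),
                 ssa_trend_components = as.integer(ssa_trend_components),
                 focal_classes = focal_classes, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full co-prescription network pipeline
#'
#' simulate/read -> cohort filter -> exposure -> daily networks ->
#' centrality -> weekly metrics -> co-prescription summary -> subgroups ->
#' seasonality tables -> two-stage SSA + Mann-Kendall, writing one CSV per
#' stage plus a YAML run manifest into `out_dir`. Re-running with an
#' identical config and seed reproduces the outputs.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @param quiet Suppress per-stage messages.
#' @return Invisibly, a list with every stage's table and the manifest.
#' @export
run_pipeline <- function(config, out_dir, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(...)
  win <- config$window
  map <- atc_class_map()
  stage_rows <- list()

  # --- registry ----------------------------------------------------------
  if (is.null(config$registry_path)) {
    sim <- config$sim
    if (is.null(sim)) sim <- simulation_config(window = win,
                                               seed = config$seed)
    sim$window <- win
    sim$seed <- config$seed
    registry <- simulate_registry(sim)
    write_registry(registry, file.path(out_dir, "registry.csv"))
  } else {
    registry <- read_registry(config$registry_path, window = win)
  }
  if (!nrow(registry)) stop("stage registry: no valid records")
  if (!is.null(config$cohort)) {
    registry <- filter_cohort(registry, config$cohort, map)
    if (!nrow(registry)) stop("stage cohort: empty cohort")
  }
  stage_rows$registry <- nrow(registry)
  say("registry: ", nrow(registry), " records, ",
      uniqueN(registry$patient_id), " patients")

  summary_tab <- registry_summary(registry, win)
  fwrite(summary_tab, file.path(out_dir, "registry_summary.csv"))

  # --- exposure ----------------------------------------------------------
  intervals <- expand_records(registry, win, map)
  exposure <- exposure_days(intervals, win, config$refill_policy)
  stage_rows$exposure <- nrow(exposure)
  say("exposure: ", nrow(exposure), " patient-day-medication rows")

  # --- networks + centrality --------------------------------------------
  networks <- build_daily_networks(exposure, map, config$weights)
  fwrite(cbind(networks$edges[, .(day)],
               date = win$start + networks$edges$day,
               networks$edges[, .(class_i = networks$labels[class_i],
                                  class_j = networks$labels[class_j],
                                  count, weight)]),
         file.path(out_dir, "networks_edges.csv"))
  fwrite(networks$diag[, .(day, date = win$start + day, class_label,
                           count)],
         file.path(out_dir, "networks_diag.csv"))
  stage_rows$network_edges <- nrow(networks$edges)

  centrality <- daily_centrality(networks)
  fwrite(centrality[, .(day, date = win$start + day, class_label,
                        centrality, lambda, converged)],
         file.path(out_dir, "centrality_daily.csv"))
  stage_rows$centrality_days <- uniqueN(centrality$day)

  daily <- daily_metrics(registry, win)
  fwrite(daily, file.path(out_dir, "metrics_daily.csv"))
  weekly <- weekly_aggregate(daily, centrality, win)
  fwrite(weekly, file.path(out_dir, "metrics_weekly.csv"))
  stage_rows$weeks <- uniqueN(weekly$week)
  say("centrality: ", stage_rows$centrality_days, " days, ",
      stage_rows$weeks, " weeks")

  # --- co-prescription + subgroups --------------------------------------
  cop <- coprescription_summary(exposure, registry, map,
                                config$focal_classes, win)
  fwrite(cop, file.path(out_dir, "coprescription_yearly.csv"))

  labels_tab <- subgroup_labels(registry, exposure, win)
  fwrite(labels_tab, file.path(out_dir, "subgroups.csv"))

  sub_cent <- list()
  for (pairing in config$subgroup_pairings) {
    asg <- subgroup_assignment(labels_tab, pairing)
    runs <- subgroup_run(exposure, asg, map, config$weights, win)
    for (g in names(runs)) {
      sub_cent[[paste(pairing, g)]] <-
        cbind(pairing = pairing, group = g, runs[[g]]$mean_centrality)
    }
  }
  if (length(sub_cent)) {
    fwrite(rbindlist(sub_cent),
           file.path(out_dir, "subgroup_centrality.csv"))
  }

  # --- seasonality -------------------------------------------------------
  season <- seasonality_tables(daily, weekly, win)
  fwrite(season$correlogram, file.path(out_dir, "correlogram.csv"))
  fwrite(season$seasonal, file.path(out_dir, "seasonal_long.csv"))

  # --- SSA + trend tests -------------------------------------------------
  weekly_series <- weekly_class_series(registry, map, win,
                                       config$focal_classes, weekly)
  ssa_out <- decompose_weekly(weekly_series, config)
  if (!is.null(ssa_out)) {
    fwrite(ssa_out$components, file.path(out_dir, "ssa_components.csv"))
    fwrite(ssa_out$shares, file.path(out_dir, "ssa_shares.csv"))
    fwrite(ssa_out$trend_tests, file.path(out_dir, "trend_tests.csv"))
  } else {
    say("ssa: window too short for two-stage SSA; skipped")
  }

  # --- manifest ----------------------------------------------------------
  manifest <- list(
    package_version = as.character(packageVersion("dpnflow")),
    seed = config$seed,
    config_hash = rlang::hash(config[setdiff(names(config), "sim")]),
    window = list(start = as.character(win$start),
                  end = as.character(win$end)),
    weights = config$weights[c("sigma", "mode", "combine",
                               "peak_normalized")],
    refill_policy = config$refill_policy,
    stage_rows = stage_rows,
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  invisible(list(registry = registry, summary = summary_tab,
                 exposure = exposure, networks = networks,
                 centrality = centrality, daily = daily, weekly = weekly,
                 coprescription = cop, subgroups = labels_tab,
                 ssa = ssa_out, manifest = manifest))
}

# turn patient-year labels into a pairing-specific group assignment
subgroup_assignment <- function(labels_tab, pairing) {
  lt <- as.data.table(labels_tab)
  if (pairing == "age") {
    lt[, .(patient_id, year, group = age_group)]
  } else if (pairing == "polypharmacy") {
    unique(lt[, .(patient_id,
                  group = ifelse(polypharmacy, "polypharmacy",
                                 "non-polypharmacy"))])
  } else {  # combined: <65 non-poly vs >=65 poly (others unassigned)
    out <- lt[, .(patient_id, year,
                  group = fifelse(age_group == "<65" & !polypharmacy,
                                  "<65 non-polypharmacy",
                                  fifelse(age_group == ">=65" & polypharmacy,
                                          ">=65 polypharmacy",
                                          NA_character_)))]
    out[!is.na(group)]
  }
}

# correlogram + seasonal-deconstruction tables for daily and weekly counts
seasonality_tables <- function(daily, weekly, window) {
  d <- as.data.table(daily)
  wk <- unique(as.data.table(weekly)[, .(week, n_dispensings)])
  setorder(wk, week)
  cg <- list()
  sl <- list()
  if (nrow(d) > 29L && var(d$n_dispensings) > 0) {
    det_d <- detrend(as.numeric(d$n_dispensings), "moving_average", 29L)
    cg$daily <- cbind(series = "daily_dispensings_detrended",
                      acf_pacf(det_d, max_lag = min(60L, nrow(d) %/% 3L)))
    sl$daily <- cbind(series = "daily_dispensings_detrended",
                      seasonal_deconstruct(d$date, det_d,
                                           "weekday_by_week"))
  }
  if (nrow(wk) > 13L && var(wk$n_dispensings) > 0) {
    det_w <- detrend(as.numeric(wk$n_dispensings), "moving_average", 13L)
    cg$weekly <- cbind(series = "weekly_dispensings_detrended",
                       acf_pacf(det_w, max_lag = min(60L, nrow(wk) %/% 3L)))
    sl$weekly <- cbind(series = "weekly_dispensings_detrended",
                       seasonal_deconstruct(wk$week, det_w, "week_by_year"))
  }
  sl <- lapply(sl, function(d) {
    d <- as.data.table(d)
    d[, position := as.character(position)]
    d
  })
  list(correlogram = rbindlist(cg), seasonal = rbindlist(sl))
}

# weekly dispensing counts: population total, per focal class, plus the
# weekly mean centrality of focal classes
weekly_class_series <- function(registry, map, window, focal_classes,
                                weekly) {
  reg <- as.data.table(registry)
  reg <- reg[dispense_date >= window$start & dispense_date <= window$end]
  lab <- map_atc_to_class(reg$atc_code, map)
  weeks <- sort(unique(iso_week_label(seq(window$start, window$end,
                                          by = "day"))))
  series <- list()
  tot <- reg[, .(value = .N), by = .(week = iso_week_label(dispense_date))]
  series[["all_dispensings"]] <- tot[data.table(week = weeks),
                                     on = "week"][is.na(value),
                                                  value := 0][order(week)]
  for (fc in focal_classes) {
    s <- reg[lab == fc, .(value = .N),
             by = .(week = iso_week_label(dispense_date))]
    series[[paste0("dispensings_", fc)]] <-
      s[data.table(week = weeks), on = "week"][is.na(value),
                                               value := 0][order(week)]
    cw <- as.data.table(weekly)[class_label == fc,
                                .(week, value = mean_centrality)]
    series[[paste0("centrality_", fc)]] <-
      cw[data.table(week = weeks), on = "week"][order(week)]
  }
  series
}

decompose_weekly <- function(weekly_series, config) {
  comp <- list(); shares <- list(); tests <- list()
  any_done <- FALSE
  for (nm in names(weekly_series)) {
    s <- weekly_series[[nm]]
    x <- as.numeric(s$value)
    if (anyNA(x) || length(x) < 2L * config$ssa_L1) next
    dec <- two_stage_ssa(x, config$ssa_L1, config$ssa_k,
                         config$ssa_trend_components)
    any_done <- TRUE
    wide <- data.table(series = nm, week = s$week, original = x,
                       trend = dec$trend, remainder = dec$remainder,
                       reconstruction = dec$reconstruction)
    wide <- cbind(wide, as.data.table(dec$components))
    long <- melt(wide, id.vars = c("series", "week"),
                 variable.name = "component", value.name = "value")
    comp[[nm]] <- long
    shares[[nm]] <- cbind(series = nm, dec$variance_shares)
    mk_raw <- mann_kendall(x)
    mk_trend <- mann_kendall(dec$trend)
    tests[[nm]] <- data.table(
      series = c(paste0(nm, "_raw"), paste0(nm, "_ssa_trend")),
      S = c(mk_raw$S, mk_trend$S), var_S = c(mk_raw$var_S, mk_trend$var_S),
      z = c(mk_raw$z, mk_trend$z), p = c(mk_raw$p, mk_trend$p),
      direction = c(mk_raw$direction, mk_trend$direction))
  }
  if (!any_done) return(NULL)
  list(components = rbindlist(comp), shares = rbindlist(shares),
       trend_tests = rbindlist(tests))
}

#' Verify the cross-file invariants of a pipeline run
#'
#' Re-reads a completed output directory and asserts the invariants that
#' hold by construction: converged daily centralities sum to 1, the weekly
#' dispensing-to-patient ratio equals its recomputed value, per-person
#' co-prescription means times person counts reproduce the totals, and
#' the SSA components satisfy trend + sum(F) + remainder = original.
#'
#' @param out_dir A directory written by [run_pipeline()].
#' @return A `data.table` of `check`, `pass`, `detail`; one row per check.
#' @export
verify_outputs <- function(out_dir) {
  checks <- list()
  add <- function(name, pass, detail = "") {
    checks[[length(checks) + 1L]] <<- data.table(check = name,
                                                 pass = pass,
                                                 detail = detail)
  }

  f <- file.path(out_dir, "centrality_daily.csv")
  if (file.exists(f)) {
    ce <- fread(f)
    sums <- ce[converged == TRUE & !is.na(centrality), sum(centrality),
               by = day]
    bad <- sums[abs(V1 - 1) > 1e-8]
    add("centrality_sums_to_one", nrow(bad) == 0L,
        if (nrow(bad)) paste("worst day", bad$day[1L]) else "")
  }

  f <- file.path(out_dir, "metrics_weekly.csv")
  if (file.exists(f)) {
    wk <- unique(fread(f)[, .(week, n_dispensings, n_patients, ratio)])
    bad <- wk[n_patients > 0 & abs(ratio - n_dispensings / n_patients) >
                1e-8]
    add("weekly_ratio_consistent", nrow(bad) == 0L,
        if (nrow(bad)) paste("worst week", bad$week[1L]) else "")
  }

  f <- file.path(out_dir, "coprescription_yearly.csv")
  if (file.exists(f)) {
    cop <- fread(f)
    bad <- cop[abs(same_class_mean * n_persons - same_class_total) >
                 1e-6 * pmax(1, same_class_total) |
                 abs(total_mean * n_persons - total_n) >
                 1e-6 * pmax(1, total_n)]
    add("coprescription_means_match_totals", nrow(bad) == 0L)
  }

  f <- file.path(out_dir, "ssa_components.csv")
  if (file.exists(f)) {
    sc <- dcast(fread(f), series + week ~ component, value.var = "value")
    fcols <- grep("^F[0-9]+$", names(sc), value = TRUE)
    resid <- sc$original - sc$trend - rowSums(sc[, fcols, with = FALSE]) -
      sc$remainder
    scale <- max(abs(sc$original))
    add("ssa_additivity", max(abs(resid)) <= 1e-6 * max(1, scale),
        sprintf("max abs residual %.3g", max(abs(resid))))
    rec <- sc$trend + sc$F1 + sc$F2 - sc$reconstruction
    add("ssa_reconstruction_is_trend_F1_F2",
        max(abs(rec)) <= 1e-6 * max(1, scale))
  }

  res <- rbindlist(checks)
  res[]
}
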