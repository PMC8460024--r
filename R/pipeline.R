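#' Pipeline run configuration
#'
#' One master seed; every stochastic stage derives its own named
#' sub-stream via [derive_seed()], so stages are individually
#' reproducible. The configuration round-trips unchanged through YAML
#' ([write_config()] / [read_config()]).
#'
#' @param seed master seed.
#' @param n_perm permutations for every test (default 5000).
#' @param n_boot bootstrap draws for the day-night mean slope.
#' @param n_bats,n_nights colony size passed to [colony_params()].
#' @param colony named list of further [colony_params()] overrides.
#' @param process named list of [process_config()] overrides.
#' @param cofeed_nights,cofeed_hours captive observation effort.
#' @return A `run_config` list.
#' @export
run_config <- function(seed = 1L, n_perm = 5000, n_boot = 5000,
                       n_bats = 50, n_nights = 9,
                       colony = list(), process = list(),
                       cofeed_nights = 70, cofeed_hours = 15) {
  structure(list(seed = as.integer(seed), n_perm = as.integer(n_perm),
                 n_boot = as.integer(n_boot),
                 n_bats = as.integer(n_bats), n_nights = as.integer(n_nights),
                 colony = colony, process = process,
                 cofeed_nights = as.integer(cofeed_nights),
                 cofeed_hours = as.integer(cofeed_hours)),
            class = "run_config")
}

#' @rdname run_config
#' @param config a `run_config`.
#' @param path YAML file path.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname run_config
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(run_config, raw)
}

config_colony_params <- function(config) {
  args <- c(list(n_bats = config$n_bats, n_nights = config$n_nights,
                 seed = derive_seed(config$seed, "simulate")),
            config$colony)
  do.call(colony_params, args)
}

config_process_config <- function(config) {
  args <- config$process
  cp <- config_colony_params(config)
  if (is.null(args$calendar)) {
    args$calendar <- study_calendar(cp$n_nights, cp$night_s, cp$day_s)
  }
  if (is.null(args$assoc_min_signal)) args$assoc_min_signal <- cp$assoc_signal
  if (is.null(args$close_min_signal)) args$close_min_signal <- cp$close_signal
  do.call(process_config, args)
}

stage <- function(report, name, expr) {
  res <- tryCatch(list(ok = TRUE, value = expr),
                  error = function(e) list(ok = FALSE, error = conditionMessage(e)))
  report$stages[[name]] <- if (res$ok) "ok" else paste("error:", res$error)
  list(report = report, value = if (res$ok) res$value else NULL)
}

#' Run the full pipeline: simulate, process, build networks, test
#'
#' Chains the synthetic-data generator, sensor processing, network
#' construction, and the inferential suite under one master seed, and
#' returns a single structured report. Stage failures are recorded in the
#' report; later stages that do not depend on the failed one still run.
#'
#' @param config a [run_config()].
#' @param out_dir optional directory: the dataset tables and the report
#'   JSON are written there.
#' @return The report (a nested list; see `$stages` for per-stage status).
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  report <- list(
    package_version = as.character(utils::packageVersion("proxinet")),
    seed = config$seed, n_perm = config$n_perm, stages = list())

  s <- stage(report, "simulate", {
    simulate_study(config_colony_params(config),
                   cofeed_nights = config$cofeed_nights,
                   cofeed_hours = config$cofeed_hours)
  })
  report <- s$report; study <- s$value
  if (is.null(study)) return(finish_report(report, out_dir))
  if (!is.null(out_dir)) write_dataset(study, file.path(out_dir, "dataset"))

  cfg <- config_process_config(config)
  bats <- study$truth$bats$bat_id
  np <- config$n_perm

  s <- stage(report, "process", {
    bouts <- detect_bouts(study$stations, study$events, cfg, bats = bats)
    enc <- classify_context(study$events, bouts, study$stations, cfg)
    list(bouts = bouts, enc = enc)
  })
  report <- s$report; proc <- s$value
  if (!is.null(proc)) {
    fdur <- proc$enc$duration_s[proc$enc$context == "foraging" &
                                  !is.na(proc$enc$proximity_class)]
    report$processing <- list(
      n_events = nrow(proc$enc),
      context_counts = as.list(table(proc$enc$context)),
      n_bouts = sum(!is.na(proc$bouts$night_index)),
      n_foraging_encounters = length(fdur),
      median_foraging_duration_s = if (length(fdur)) stats::median(fdur) else NA,
      max_foraging_duration_s = if (length(fdur)) max(fdur) else NA,
      co_departures_5s = nrow(co_departures(proc$bouts, 5)))
  }

  nets <- NULL
  if (!is.null(proc)) {
    s <- stage(report, "networks", {
      list(
        roost_day = roosting_network(proc$enc, study$stations, "association",
                                     "per_day", cfg, bats = bats),
        roost_agg = roosting_network(proc$enc, study$stations, "association",
                                     "aggregate", cfg, bats = bats),
        close_agg = roosting_network(proc$enc, study$stations, "close_contact",
                                     "aggregate", cfg, bats = bats),
        forage_sec = foraging_seconds_network(proc$enc, bats),
        forage_sec_night = foraging_seconds_network(proc$enc, bats,
                                                    per_night = TRUE,
                                                    bouts = proc$bouts, cfg = cfg),
        forage_nights = foraging_nights_network(proc$enc, bats, cfg),
        coforage = hourly_coforaging(proc$enc, proc$bouts, cfg),
        overlap = bout_overlap(proc$bouts, bats))
    })
    report <- s$report; nets <- s$value
  }
  if (!is.null(nets)) {
    fsec <- dyad_values(unclass(nets$forage_sec))
    fnig <- dyad_values(unclass(nets$forage_nights))
    cofc <- dyad_values(unclass(coforaging_counts(nets$coforage,
                                                  bats = bats)))
    report$networks <- list(
      n_dyads_with_foraging = sum(fsec > 0, na.rm = TRUE),
      n_repeat_pairs = sum(fnig > 1, na.rm = TRUE),
      total_foraging_seconds = sum(fsec, na.rm = TRUE),
      max_nights_with_encounter = max(fnig),
      max_coforaging_count = max(cofc))
  }

  tests <- list()
  if (!is.null(nets)) {
    tseed <- function(lbl) derive_seed(config$seed, lbl)
    tests$differentiation <- run_test(report, "differentiation", {
      r <- differentiation_test(nets$coforage, n_perm = np,
                                seed = tseed("differentiation"))
      list(observed_cv = r$observed, centered = r$centered,
           p_value = r$p_value, n_perm = r$n_perm)
    })
    kin <- study$truth$kinship
    tests$qap_kinship_nights <- run_test(report, "qap_kinship_nights", {
      r <- qap_regression(nets$forage_nights, list(kinship = kin),
                          n_perm = np, seed = tseed("qap_kin_nights"))
      qap_summary(r)
    })
    tests$qap_assoc_seconds <- run_test(report, "qap_assoc_seconds", {
      r <- qap_regression(nets$forage_sec_night,
                          list(association = nets$roost_agg),
                          n_perm = np, seed = tseed("qap_assoc_sec"))
      qap_summary(r)
    })
    tests$mrqap_assoc_overlap <- run_test(report, "mrqap_assoc_overlap", {
      r <- qap_regression(nets$forage_sec,
                          list(association = nets$roost_agg),
                          covariate = nets$overlap,
                          n_perm = np, seed = tseed("mrqap"), mode = "dsp")
      qap_summary(r)
    })
    tests$daynight <- run_test(report, "daynight", {
      r <- daynight_paired_qap(nets$roost_day, nets$forage_sec_night,
                               n_perm = min(np, 1000), n_boot = config$n_boot,
                               seed = tseed("daynight"))
      list(mean_slope = r$mean_slope, ci_low = r$ci[1], ci_high = r$ci[2],
           n_days = nrow(r$per_day))
    })
    tests$centrality <- run_test(report, "centrality", {
      rp <- degree_centrality_profiles(nets$roost_day)
      fp <- degree_centrality_profiles(nets$forage_sec_night)
      r <- centrality_consistency_test(rp$mean_degree, fp$degree,
                                       n_perm = np, seed = tseed("centrality"))
      list(slope = r$observed, centered = r$centered, p_value = r$p_value,
           tail = r$tail)
    })
  }
  captive <- study$truth$bats$bat_id[study$truth$bats$type != "control"]
  tests$cofeeding <- run_test(report, "cofeeding", {
    sharing <- dyadic_matrix(unclass(study$truth$sharing)[captive, captive],
                             bats = captive, role = "rate")
    cof <- study$cofeeding
    dp <- double_permutation_test(cof$events, cof$presence, sharing,
                                  n_perm = np,
                                  seed = derive_seed(config$seed, "doubleperm"))
    mt <- mantel_test(cofeeding_network(cof$events, captive), sharing,
                      n_perm = np, seed = derive_seed(config$seed, "mantel"))
    list(double_perm_r = dp$result$observed, double_perm_p = dp$result$p_value,
         mantel_r = mt$observed, mantel_p = mt$p_value)
  })
  if (!is.null(proc)) {
    tests$icc_departure <- run_test(report, "icc_departure", {
      b <- proc$bouts[!is.na(proc$bouts$night_index) & !proc$bouts$censored_depart, ]
      b$after_sunset <- b$depart_s - (b$night_index - 1) *
        cfg$calendar$cycle_s
      typ <- study$truth$bats$type[match(b$bat, study$truth$bats$bat_id)]
      out <- list()
      for (tp in unique(typ)) {
        x <- b[typ == tp, ]
        out[[tp]] <- tryCatch(icc_unadjusted(x$after_sunset, x$bat)$icc,
                              error = function(e) NA_real_)
      }
      out
    })
  }
  report$tests <- tests
  finish_report(report, out_dir)
}

run_test <- function(report, name, expr) {
  tryCatch(expr, error = function(e) list(error = conditionMessage(e)))
}

qap_summary <- function(r) {
  tm <- setdiff(names(r$coefficients), "(Intercept)")
  list(coefficients = as.list(r$coefficients[tm]),
       p_values = as.list(r$p_values[tm]),
       mode = r$mode, n_perm = r$n_perm, n_dyads = r$n_dyads)
}

finish_report <- function(report, out_dir) {
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = 10, na = "null",
                         pretty = TRUE)
  }
  report
}
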