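# Shared fixtures, built in code at test time.

# a small processed colony used across modules (cached per test run)
small_processed <- local({
  cache <- new.env(parent = emptyenv())
  function(seed = 42, n_bats = 15, n_nights = 6, ...) {
    key <- paste(seed, n_bats, n_nights, ...)
    if (!is.null(cache[[key]])) return(cache[[key]])
    p <- colony_params(n_bats = n_bats, n_nights = n_nights, seed = seed, ...)
    study <- simulate_study(p, cofeed_nights = 20, cofeed_hours = 8)
    cfg <- process_config(calendar = study$truth$calendar)
    proc <- process_sensors(study$events, study$stations, cfg,
                            bats = study$truth$bats$bat_id)
    out <- list(params = p, study = study, cfg = cfg,
                bats = study$truth$bats$bat_id,
                bouts = proc$bouts, enc = proc$encounters)
    cache[[key]] <- out
    out
  }
})

# quick truth-based tables for calibration loops: skips sensor detection and
# uses the generator's own bouts/encounters (classification is exercised
# elsewhere; these loops test the inference engines)
truth_tables <- function(p) {
  truth <- simulate_colony(p)
  forage <- simulate_foraging_nights(truth)
  te <- forage$true_encounters
  bouts <- forage$bouts
  bouts$censored_depart <- FALSE
  outside <- NULL
  if (nrow(bouts) > 0) {
    rows <- lapply(seq_len(nrow(bouts)), function(i) {
      hrs <- seq(floor(bouts$depart_s[i] / 3600),
                 ceiling(bouts$return_s[i] / 3600) - 1)
      ov <- pmin(bouts$return_s[i], (hrs + 1) * 3600) -
        pmax(bouts$depart_s[i], hrs * 3600)
      data.frame(night = bouts$night_index[i], hour = hrs[ov >= 1],
                 bat = bouts$bat[i], stringsAsFactors = FALSE)
    })
    outside <- unique(do.call(rbind, rows))
  }
  recs <- unique(te[, c("night", "hour", "bat_a", "bat_b")])
  tab <- structure(list(records = recs, outside = outside,
                        bats = truth$bats$bat_id),
                   class = "hourly_coforaging")
  list(truth = truth, bouts = bouts, table = tab, encounters = te)
}

# per-night foraging-seconds stratified network straight from truth tables
truth_forage_network <- function(tt) {
  bats <- tt$truth$bats$bat_id
  cal <- tt$truth$calendar
  layers <- list(); presence <- list()
  for (ni in seq_len(cal$n_nights)) {
    m <- matrix(0, length(bats), length(bats), dimnames = list(bats, bats))
    e <- tt$encounters[tt$encounters$night == ni, , drop = FALSE]
    if (nrow(e) > 0) {
      agg <- stats::aggregate(duration_s ~ bat_a + bat_b, data = e, FUN = sum)
      m[cbind(agg$bat_a, agg$bat_b)] <- agg$duration_s
      m[cbind(agg$bat_b, agg$bat_a)] <- agg$duration_s
    }
    layers[[paste0("night", ni)]] <- dyadic_matrix(m, bats = bats, role = "seconds")
    presence[[paste0("night", ni)]] <-
      unique(tt$bouts$bat[tt$bouts$night_index == ni])
  }
  day_stratified_network(layers, presence)
}

# hand-buildable hourly co-foraging table
make_cofor_table <- function(records, outside) {
  structure(list(records = records, outside = outside,
                 bats = sort(unique(c(outside$bat, records$bat_a, records$bat_b)))),
            class = "hourly_coforaging")
}

# per-day roosting-association day-stratified network straight from the
# daytime generator output (all events are roosting context by construction)
roosting_degree_network <- function(ro, truth) {
  cal <- truth$calendar
  bats <- truth$bats$bat_id
  layers <- list(); pres <- list()
  for (d in seq_len(cal$n_nights)) {
    db0 <- (d - 1) * cal$cycle_s + cal$night_s
    e <- ro$events[ro$events$start_s >= db0 &
                     ro$events$start_s < db0 + cal$day_s, , drop = FALSE]
    m <- matrix(0, length(bats), length(bats), dimnames = list(bats, bats))
    if (nrow(e) > 0) {
      ag <- stats::aggregate(duration_s ~ bat_a + bat_b, e, sum)
      m[cbind(ag$bat_a, ag$bat_b)] <- ag$duration_s
      m[cbind(ag$bat_b, ag$bat_a)] <- ag$duration_s
    }
    layers[[paste0("day", d)]] <- dyadic_matrix(m, role = "seconds")
    pres[[paste0("day", d)]] <-
      unique(ro$stations$bat[ro$stations$start_s >= db0 &
                               ro$stations$start_s < db0 + cal$day_s])
  }
  day_stratified_network(layers, pres)
}
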