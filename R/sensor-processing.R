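#' Normalize raw encounter durations to the beacon convention
#'
#' Proximity sensors update an encounter every 2 s, so an encounter shorter
#' than two successive signals has no measured length; such encounters are
#' assigned a duration of 1 s. Longer raw durations are rounded to whole
#' seconds.
#'
#' @param raw_duration_s non-negative numeric vector of raw durations.
#' @return Integer seconds (>= 1).
#' @export
normalize_duration <- function(raw_duration_s) {
  if (any(raw_duration_s < 0)) stop("durations must be non-negative")
  out <- round(raw_duration_s)
  out[raw_duration_s < 2] <- 1
  as.integer(out)
}

#' Classify encounter proximity from peak signal strength
#'
#' Two nested proximity classes are defined by signal-strength thresholds
#' (approximately 50 cm and 2 cm in the original calibration): peak signal
#' at or above the close threshold is a `close_contact` (which also
#' qualifies as an association); at or above the association threshold an
#' `association`; below that the event carries no proximity class (`NA`)
#' and is dropped from networks. Threshold boundaries are inclusive.
#'
#' @param max_signal numeric vector of peak signal strengths.
#' @param thresholds list/vector with `assoc_min_signal` and
#'   `close_min_signal` (close >= assoc).
#' @return Character vector in `c("close_contact", "association", NA)`.
#' @export
classify_proximity <- function(max_signal, thresholds) {
  a <- thresholds[["assoc_min_signal"]]
  k <- thresholds[["close_min_signal"]]
  if (is.null(a) || is.null(k)) stop("thresholds must name assoc_min_signal and close_min_signal")
  if (k < a) stop("close_min_signal must be >= assoc_min_signal")
  out <- rep(NA_character_, length(max_signal))
  out[max_signal >= a] <- "association"
  out[max_signal >= k] <- "close_contact"
  out
}

#' Processing configuration
#'
#' @param assoc_min_signal,close_min_signal signal thresholds defining the
#'   association and close-contact proximity classes.
#' @param roost_station station id of the roost base station.
#' @param many,few associate-count bounds for departure detection: a
#'   departure requires the trailing associate count to have dropped from
#'   `>= many` typical in-roost levels to `<= few`.
#' @param min_away_s minimum credible bout length (shorter roost-contact
#'   gaps are ignored), also the span over which the associate count must
#'   stay low.
#' @param min_home_s minimum roost-contact block length that counts as a
#'   return; briefer contacts (a bat passing near the roost tree) do not
#'   split a bout, though they still trigger the near-roost exclusion of
#'   overlapping encounters.
#' @param assoc_window_s trailing window for the associate count.
#' @param margin_s transition margin: encounters within this many seconds of
#'   a bat's departure or return are excluded from foraging.
#' @param calendar a [study_calendar()] used to index nights.
#' @return A `process_config` list.
#' @export
process_config <- function(assoc_min_signal = 20, close_min_signal = 40,
                           roost_station = "roost",
                           many = 4, few = 3, min_away_s = 300,
                           min_home_s = 300,
                           assoc_window_s = 120, margin_s = 60,
                           calendar = study_calendar()) {
  stopifnot(close_min_signal >= assoc_min_signal, few < many,
            min_away_s > 0, min_home_s > 0, assoc_window_s > 0, margin_s >= 0)
  structure(list(assoc_min_signal = assoc_min_signal,
                 close_min_signal = close_min_signal,
                 roost_station = roost_station, many = many, few = few,
                 min_away_s = min_away_s, min_home_s = min_home_s,
                 assoc_window_s = assoc_window_s,
                 margin_s = margin_s, calendar = calendar),
            class = "process_config")
}

# merged roost-station coverage intervals for one bat
roost_coverage <- function(bat, stations, cfg) {
  s <- stations[stations$bat == bat & stations$station_id == cfg$roost_station, ]
  merge_intervals(s$start_s, s$start_s + s$duration_s)
}

# distinct associates of `bat` with events intersecting [t0, t1]
associate_count <- function(bat, events, t0, t1) {
  ev <- events[(events$bat_a == bat | events$bat_b == bat) &
                 events$start_s <= t1 &
                 (events$start_s + events$duration_s) >= t0, , drop = FALSE]
  if (nrow(ev) == 0) return(0L)
  length(unique(ifelse(ev$bat_a == bat, ev$bat_b, ev$bat_a)))
}

#' Detect foraging bouts from roost-station contact gaps
#'
#' A bat's departure is declared where roost-station contact ceases and the
#' count of distinct tagged associates stays at or below `cfg$few` (the
#' "sudden drop from many bats down to 0-3") through the first
#' `cfg$min_away_s` seconds away; the return is the symmetric condition at
#' the end of the gap. Gaps shorter than `cfg$min_away_s` are discarded.
#' Bats with no roost-station contact at all cannot be bouted from
#' contact gaps; they are flagged (full-window bout, both ends censored,
#' with a warning) rather than silently dropped.
#'
#' @param stations station-contact table (bat, station_id, start_s, duration_s).
#' @param events proximity-event table (used for associate counts).
#' @param cfg a [process_config()].
#' @param bats bat ids to process (default: all bats in either table).
#' @return data.frame of bouts: bat, night_index, depart_s, return_s,
#'   censored_depart, censored_return.
#' @export
detect_bouts <- function(stations, events, cfg = process_config(),
                         bats = NULL) {
  cal <- cfg$calendar
  if (is.null(bats)) {
    bats <- sort(unique(c(stations$bat, events$bat_a, events$bat_b)))
  }
  pad <- cfg$assoc_window_s
  out <- list()
  flagged <- character()
  for (b in bats) {
    cov <- roost_coverage(b, stations, cfg)
    cov <- cov[cov$end - cov$start >= cfg$min_home_s, , drop = FALSE]
    if (nrow(cov) == 0) {
      flagged <- c(flagged, b)
      out[[b]] <- data.frame(bat = b, night_index = NA_integer_,
                             depart_s = 0, return_s = cal$end_s,
                             censored_depart = TRUE, censored_return = TRUE,
                             stringsAsFactors = FALSE)
      next
    }
    # gaps in coverage within the study window
    gs <- c(0, cov$end)
    ge <- c(cov$start, cal$end_s)
    keep <- (ge - gs) >= cfg$min_away_s
    gs <- gs[keep]; ge <- ge[keep]
    if (length(gs) == 0) next
    rows <- list()
    for (i in seq_along(gs)) {
      cd <- gs[i] <= 0          # gap truncated at study start
      cr <- ge[i] >= cal$end_s  # gap truncated at study end
      dep_ok <- cd ||
        associate_count(b, events, gs[i] - pad, gs[i] + cfg$min_away_s) <= cfg$few
      ret_ok <- cr ||
        associate_count(b, events, ge[i] - cfg$min_away_s, ge[i]) <= cfg$few
      if (!dep_ok || !ret_ok) next
      ni <- night_of(cal, gs[i])
      if (is.na(ni)) ni <- night_of(cal, min(ge[i] - 1, cal$end_s - 1))
      rows[[length(rows) + 1]] <- data.frame(
        bat = b, night_index = ni, depart_s = gs[i], return_s = ge[i],
        censored_depart = cd, censored_return = cr, stringsAsFactors = FALSE)
    }
    if (length(rows)) out[[b]] <- do.call(rbind, rows)
  }
  if (length(flagged)) {
    warning("no roost-station contact for bat(s) ",
            paste(flagged, collapse = ", "),
            "; flagged as all-window-out (censored)")
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(bat = character(), night_index = integer(), depart_s = numeric(),
               return_s = numeric(), censored_depart = logical(),
               censored_return = logical(), stringsAsFactors = FALSE)
  rownames(res) <- NULL
  attr(res, "no_contact_bats") <- flagged
  res
}

#' Classify every encounter's context
#'
#' Assigns exactly one context to every input event:
#' \describe{
#'   \item{foraging}{both bats are inside a foraging bout, the encounter
#'     starts more than `margin_s` after each bat's departure and ends more
#'     than `margin_s` before each return, and neither bat has a
#'     roost-station contact overlapping the encounter.}
#'   \item{excluded_near_roost}{both bats in a bout and outside the
#'     margins, but a roost-station contact overlaps the encounter (the
#'     bats were at the entrance or outside of the roost tree).}
#'   \item{excluded_transition}{both bats in a bout but inside the 1-minute
#'     transition margins.}
#'   \item{roosting}{all remaining encounters.}
#' }
#' The margin rule is applied to each bat's own bout independently, and the
#' transition margin is evaluated before the roost-contact exclusion.
#' Proximity class is attached from [classify_proximity()].
#'
#' @param events proximity-event table; raw durations are normalized.
#' @param bouts bout table from [detect_bouts()] (or generator truth).
#' @param stations station-contact table.
#' @param cfg a [process_config()].
#' @return The events with added `duration_s` (normalized),
#'   `proximity_class`, and `context` columns.
#' @export
classify_context <- function(events, bouts, stations, cfg = process_config()) {
  ev <- events
  ev$duration_s <- normalize_duration(ev$duration_s)
  ev$proximity_class <- classify_proximity(
    ev$max_signal, list(assoc_min_signal = cfg$assoc_min_signal,
                        close_min_signal = cfg$close_min_signal))
  n <- nrow(ev)
  ev$context <- rep("roosting", n)
  if (n == 0) return(ev)
  end_s <- ev$start_s + ev$duration_s

  # enclosing bout (containing the event's start) per bat of each event;
  # bouts of one bat are non-overlapping, so findInterval suffices. An
  # encounter running past the return time stays attached to the bout its
  # start falls in; the margin rule then classifies it as a transition.
  enclosing_bout <- function(bat, t0, t1) {
    out <- rep(NA_integer_, length(bat))
    for (u in unique(bat)) {
      rows <- which(bouts$bat == u)
      if (length(rows) == 0) next
      rows <- rows[order(bouts$depart_s[rows])]
      sel <- which(bat == u)
      k <- findInterval(t0[sel], bouts$depart_s[rows])
      ok <- k >= 1
      ok[ok] <- bouts$return_s[rows[k[ok]]] >= t0[sel][ok]
      out[sel[ok]] <- rows[k[ok]]
    }
    out
  }
  ba <- enclosing_bout(ev$bat_a, ev$start_s, end_s)
  bb <- enclosing_bout(ev$bat_b, ev$start_s, end_s)
  in_bout <- !is.na(ba) & !is.na(bb)

  inside_margin <- rep(FALSE, n)
  idx <- which(in_bout)
  if (length(idx)) {
    inside_margin[idx] <-
      ev$start_s[idx] <= bouts$depart_s[ba[idx]] + cfg$margin_s |
      end_s[idx] >= bouts$return_s[ba[idx]] - cfg$margin_s |
      ev$start_s[idx] <= bouts$depart_s[bb[idx]] + cfg$margin_s |
      end_s[idx] >= bouts$return_s[bb[idx]] - cfg$margin_s
  }

  roost_touch <- rep(FALSE, n)
  cand <- which(in_bout & !inside_margin)
  if (length(cand)) {
    rs <- stations[stations$station_id == cfg$roost_station, , drop = FALSE]
    rs_end <- rs$start_s + rs$duration_s
    roost_touch[cand] <- vapply(cand, function(i) {
      hit <- (rs$bat == ev$bat_a[i] | rs$bat == ev$bat_b[i]) &
        rs$start_s < end_s[i] & rs_end > ev$start_s[i]
      any(hit)
    }, logical(1))
  }

  ev$context[in_bout & inside_margin] <- "excluded_transition"
  ev$context[in_bout & !inside_margin & roost_touch] <- "excluded_near_roost"
  ev$context[in_bout & !inside_margin & !roost_touch] <- "foraging"
  ev
}

#' Co-departures within a time window
#'
#' Lists every dyad whose same-night departures fall within `window_s`
#' seconds of each other, with the gap. Used to quantify how often bats
#' leave the roost together.
#'
#' @param bouts bout table.
#' @param window_s window in seconds (e.g., 5).
#' @return data.frame: night_index, bat_a, bat_b, gap_s, ordered by time.
#' @export
co_departures <- function(bouts, window_s) {
  b <- bouts[!is.na(bouts$night_index) & !bouts$censored_depart, , drop = FALSE]
  out <- list()
  for (ni in sort(unique(b$night_index))) {
    x <- b[b$night_index == ni, ]
    if (nrow(x) < 2) next
    idx <- utils::combn(nrow(x), 2)
    gap <- abs(x$depart_s[idx[1, ]] - x$depart_s[idx[2, ]])
    keep <- gap <= window_s
    if (!any(keep)) next
    o <- order_dyad(x$bat[idx[1, keep]], x$bat[idx[2, keep]])
    out[[length(out) + 1]] <- data.frame(
      night_index = ni, bat_a = o$bat_a, bat_b = o$bat_b,
      gap_s = gap[keep],
      t_first = pmin(x$depart_s[idx[1, keep]], x$depart_s[idx[2, keep]]),
      stringsAsFactors = FALSE)
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(night_index = integer(), bat_a = character(), bat_b = character(),
               gap_s = numeric(), t_first = numeric(), stringsAsFactors = FALSE)
  res <- res[order(res$t_first), setdiff(names(res), "t_first"), drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Run the full sensor-processing chain
#'
#' Convenience wrapper: detects bouts, then classifies every encounter.
#'
#' @param events raw proximity-event table.
#' @param stations station-contact table.
#' @param cfg a [process_config()].
#' @param bats bat universe.
#' @return list with `bouts` and `encounters` (classified).
#' @export
process_sensors <- function(events, stations, cfg = process_config(),
                            bats = NULL) {
  bouts <- detect_bouts(stations, events, cfg, bats = bats)
  list(bouts = bouts,
       encounters = classify_context(events, bouts, stations, cfg))
}
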