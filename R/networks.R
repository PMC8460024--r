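#' Roosting association-rate network
#'
#' Edge = summed roosting-context encounter seconds at or above the given
#' proximity level, divided by the dyad's co-presence time (seconds both
#' bats held roost-station contact) in the window. Dyads never co-present
#' are structurally missing, not zero. With `window = "per_day"` a
#' [day_stratified_network()] of daily layers is returned; bats with no
#' roost contact that day are absent.
#'
#' @param encounters classified encounters from [classify_context()].
#' @param stations station-contact table (the co-presence denominator).
#' @param level `"association"` (default) or `"close_contact"`; close
#'   contacts are nested inside associations.
#' @param window `"aggregate"` or `"per_day"`.
#' @param cfg a [process_config()].
#' @param bats bat universe (default: all bats in the station table).
#' @return A [dyadic_matrix()] (rate) or [day_stratified_network()].
#' @export
roosting_network <- function(encounters, stations,
                             level = c("association", "close_contact"),
                             window = c("aggregate", "per_day"),
                             cfg = process_config(), bats = NULL) {
  level <- match.arg(level)
  window <- match.arg(window)
  cal <- cfg$calendar
  if (is.null(bats)) bats <- sort(unique(stations$bat))
  keep <- encounters$context == "roosting" &
    !is.na(encounters$proximity_class) &
    (if (level == "association") !is.na(encounters$proximity_class)
     else encounters$proximity_class == "close_contact")
  enc <- encounters[keep, , drop = FALSE]
  rs <- stations[stations$station_id == cfg$roost_station, , drop = FALSE]

  day_layer <- function(d) {
    db <- day_bounds(cal, d)
    # roost coverage clipped to this day, per bat
    cov <- lapply(bats, function(b) {
      s <- rs[rs$bat == b, ]
      m <- merge_intervals(pmax(s$start_s, db[["start"]]),
                           pmin(s$start_s + s$duration_s, db[["end"]]))
      m[m$end > m$start, , drop = FALSE]
    })
    names(cov) <- bats
    present <- bats[vapply(cov, nrow, 1L) > 0]
    n <- length(bats)
    sec <- matrix(0, n, n, dimnames = list(bats, bats))
    e <- enc[enc$start_s >= db[["start"]] & enc$start_s < db[["end"]], ]
    if (nrow(e) > 0) {
      agg <- stats::aggregate(duration_s ~ bat_a + bat_b, data = e, FUN = sum)
      sec[cbind(agg$bat_a, agg$bat_b)] <- agg$duration_s
      sec[cbind(agg$bat_b, agg$bat_a)] <- agg$duration_s
    }
    denom <- matrix(NA_real_, n, n, dimnames = list(bats, bats))
    for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
      ov <- intervals_intersect_length(cov[[i]], cov[[j]])
      if (ov > 0) denom[i, j] <- denom[j, i] <- ov
    }
    rate <- sec / denom  # zero co-presence stays NA (missing, not zero)
    diag(rate) <- 0
    list(rate = dyadic_matrix(rate, bats = bats, role = "rate"),
         present = present, sec = sec, denom = denom)
  }

  layers <- lapply(seq_len(cal$n_nights), day_layer)
  names(layers) <- paste0("day", seq_len(cal$n_nights))
  if (window == "per_day") {
    return(day_stratified_network(
      layers = lapply(layers, `[[`, "rate"),
      presence = lapply(layers, `[[`, "present")))
  }
  sec_tot <- Reduce(`+`, lapply(layers, `[[`, "sec"))
  den_tot <- Reduce(function(a, b) {
    out <- a
    out[is.na(a)] <- b[is.na(a)]
    both <- !is.na(a) & !is.na(b)
    out[both] <- a[both] + b[both]
    out
  }, lapply(layers, `[[`, "denom"))
  rate <- sec_tot / den_tot
  diag(rate) <- 0
  dyadic_matrix(rate, bats = bats, role = "rate")
}

foraging_only <- function(encounters) {
  encounters[encounters$context == "foraging" &
               !is.na(encounters$proximity_class), , drop = FALSE]
}

#' Foraging encounter-time network (seconds)
#'
#' Per dyad, the summed duration of all foraging-context encounters.
#'
#' @param encounters classified encounters.
#' @param bats bat universe.
#' @param per_night if `TRUE`, return a [day_stratified_network()] of
#'   nightly layers (presence = bats with a bout that night, from `bouts`).
#' @param bouts bout table, required for `per_night` presence.
#' @param cfg a [process_config()].
#' @return A [dyadic_matrix()] (seconds) or [day_stratified_network()].
#' @export
foraging_seconds_network <- function(encounters, bats, per_night = FALSE,
                                     bouts = NULL, cfg = process_config()) {
  enc <- foraging_only(encounters)
  if (!per_night) {
    m <- matrix(0, length(bats), length(bats), dimnames = list(bats, bats))
    if (nrow(enc) > 0) {
      agg <- stats::aggregate(duration_s ~ bat_a + bat_b, data = enc, FUN = sum)
      m[cbind(agg$bat_a, agg$bat_b)] <- agg$duration_s
      m[cbind(agg$bat_b, agg$bat_a)] <- agg$duration_s
    }
    return(dyadic_matrix(m, bats = bats, role = "seconds"))
  }
  if (is.null(bouts)) stop("per_night foraging network needs the bout table")
  cal <- cfg$calendar
  enc$night <- night_of(cal, enc$start_s)
  layers <- list(); presence <- list()
  for (ni in seq_len(cal$n_nights)) {
    m <- matrix(0, length(bats), length(bats), dimnames = list(bats, bats))
    e <- enc[!is.na(enc$night) & enc$night == ni, ]
    if (nrow(e) > 0) {
      agg <- stats::aggregate(duration_s ~ bat_a + bat_b, data = e, FUN = sum)
      m[cbind(agg$bat_a, agg$bat_b)] <- agg$duration_s
      m[cbind(agg$bat_b, agg$bat_a)] <- agg$duration_s
    }
    layers[[paste0("night", ni)]] <- dyadic_matrix(m, bats = bats, role = "seconds")
    presence[[paste0("night", ni)]] <-
      intersect(bats, bouts$bat[!is.na(bouts$night_index) & bouts$night_index == ni])
  }
  day_stratified_network(layers, presence)
}

#' Nights-with-foraging-encounter network (0 to n_nights)
#'
#' Per dyad, the number of distinct nights with at least one
#' foraging-context encounter — the conservative response that only counts
#' repeats across different nights.
#'
#' @param encounters classified encounters.
#' @param bats bat universe.
#' @param cfg a [process_config()] (supplies the night calendar).
#' @return A [dyadic_matrix()] (count).
#' @export
foraging_nights_network <- function(encounters, bats, cfg = process_config()) {
  enc <- foraging_only(encounters)
  m <- matrix(0, length(bats), length(bats), dimnames = list(bats, bats))
  if (nrow(enc) > 0) {
    enc$night <- night_of(cfg$calendar, enc$start_s)
    enc <- enc[!is.na(enc$night), ]
    key <- unique(data.frame(a = enc$bat_a, b = enc$bat_b, n = enc$night))
    agg <- stats::aggregate(n ~ a + b, data = key, FUN = length)
    m[cbind(agg$a, agg$b)] <- agg$n
    m[cbind(agg$b, agg$a)] <- agg$n
  }
  dyadic_matrix(m, bats = bats, role = "count")
}

#' Hourly co-foraging presence/absence table
#'
#' For every (night, clock hour): which bats are outside the roost (bout
#' overlapping the hour by at least 1 s) and which dyads had at least one
#' foraging encounter starting in that hour. Two encounters of a dyad in
#' the same hour still count as one. This is the unit the
#' social-differentiation data-stream permutation acts on.
#'
#' @param encounters classified encounters.
#' @param bouts bout table.
#' @param cfg a [process_config()].
#' @return An `hourly_coforaging` list: `records` (night, hour, bat_a,
#'   bat_b), `outside` (night, hour, bat), `bats`.
#' @export
hourly_coforaging <- function(encounters, bouts, cfg = process_config()) {
  cal <- cfg$calendar
  b <- bouts[!is.na(bouts$night_index), , drop = FALSE]
  outside <- list()
  for (i in seq_len(nrow(b))) {
    hrs <- seq(floor(b$depart_s[i] / 3600), ceiling(b$return_s[i] / 3600) - 1)
    ov <- pmin(b$return_s[i], (hrs + 1) * 3600) - pmax(b$depart_s[i], hrs * 3600)
    hrs <- hrs[ov >= 1]
    if (length(hrs)) {
      outside[[length(outside) + 1]] <- data.frame(
        night = b$night_index[i], hour = hrs, bat = b$bat[i],
        stringsAsFactors = FALSE)
    }
  }
  outside <- if (length(outside)) unique(do.call(rbind, outside)) else
    data.frame(night = integer(), hour = integer(), bat = character(),
               stringsAsFactors = FALSE)
  enc <- foraging_only(encounters)
  if (nrow(enc) > 0) {
    recs <- unique(data.frame(night = night_of(cal, enc$start_s),
                              hour = hour_of(enc$start_s),
                              bat_a = enc$bat_a, bat_b = enc$bat_b,
                              stringsAsFactors = FALSE))
    recs <- recs[!is.na(recs$night), ]
  } else {
    recs <- data.frame(night = integer(), hour = integer(),
                       bat_a = character(), bat_b = character(),
                       stringsAsFactors = FALSE)
  }
  rownames(recs) <- rownames(outside) <- NULL
  structure(list(records = recs, outside = outside,
                 bats = sort(unique(c(outside$bat, recs$bat_a, recs$bat_b)))),
            class = "hourly_coforaging")
}

#' @export
print.hourly_coforaging <- function(x, ...) {
  cat("<hourly_coforaging>", nrow(x$records), "marked dyad-hours,",
      nrow(x$outside), "bat-hours outside,", length(x$bats), "bats\n")
  invisible(x)
}

#' Per-dyad co-foraging totals of an hourly table
#'
#' @param table an [hourly_coforaging()] table.
#' @param bats bat universe (default: the table's).
#' @return A [dyadic_matrix()] (count) of distinct marked (night, hour) bins.
#' @export
coforaging_counts <- function(table, bats = table$bats) {
  m <- matrix(0, length(bats), length(bats), dimnames = list(bats, bats))
  r <- table$records
  if (nrow(r) > 0) {
    agg <- stats::aggregate(night ~ bat_a + bat_b, data = r, FUN = length)
    m[cbind(agg$bat_a, agg$bat_b)] <- agg$night
    m[cbind(agg$bat_b, agg$bat_a)] <- agg$night
  }
  dyadic_matrix(m, bats = bats, role = "count")
}

#' Foraging-bout overlap covariate (seconds)
#'
#' Per dyad, total seconds both bats were simultaneously outside the
#' roost, summed over nights.
#'
#' @param bouts bout table.
#' @param bats bat universe.
#' @return A [dyadic_matrix()] (overlap).
#' @export
bout_overlap <- function(bouts, bats) {
  m <- matrix(0, length(bats), length(bats), dimnames = list(bats, bats))
  b <- bouts[bouts$bat %in% bats, , drop = FALSE]
  if (nrow(b) >= 2) {
    for (i in seq_len(nrow(b) - 1)) for (j in seq(i + 1, nrow(b))) {
      if (b$bat[i] == b$bat[j]) next
      ov <- min(b$return_s[i], b$return_s[j]) - max(b$depart_s[i], b$depart_s[j])
      if (ov > 0) {
        m[b$bat[i], b$bat[j]] <- m[b$bat[i], b$bat[j]] + ov
        m[b$bat[j], b$bat[i]] <- m[b$bat[i], b$bat[j]]
      }
    }
  }
  dyadic_matrix(m, bats = bats, role = "overlap")
}

#' Captive co-feeding count network
#'
#' @param cofeeding_events data.frame night, hour, bat_a, bat_b.
#' @param bats bat universe.
#' @return A [dyadic_matrix()] (count).
#' @export
cofeeding_network <- function(cofeeding_events, bats) {
  m <- matrix(0, length(bats), length(bats), dimnames = list(bats, bats))
  e <- cofeeding_events
  if (nrow(e) > 0) {
    agg <- stats::aggregate(night ~ bat_a + bat_b, data = e, FUN = length)
    m[cbind(agg$bat_a, agg$bat_b)] <- agg$night
    m[cbind(agg$bat_b, agg$bat_a)] <- agg$night
  }
  dyadic_matrix(m, bats = bats, role = "count")
}

#' Per-bat, per-period degree centrality with the missing-if-absent rule
#'
#' Degree is the number of distinct partners with a nonzero edge in that
#' period's layer. A bat absent from the period, or present but with no
#' encounters, is missing for that period — never zero. The per-bat mean
#' is taken over non-missing periods only.
#'
#' @param network a [day_stratified_network()].
#' @return list with `degree` (bats x periods matrix, NA = missing) and
#'   `mean_degree` (named vector, NA when no period has encounters).
#' @export
degree_centrality_profiles <- function(network) {
  bats <- network$bats
  deg <- matrix(NA_real_, length(bats), length(network$periods),
                dimnames = list(bats, network$periods))
  for (p in network$periods) {
    lay <- unclass(network$layers[[p]])
    d <- rowSums(lay > 0, na.rm = TRUE)
    d[!(bats %in% network$presence[[p]])] <- NA
    d[d == 0] <- NA  # zero encounters => missing, not zero degree
    deg[, p] <- d
  }
  mean_deg <- apply(deg, 1, function(v) {
    if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  })
  list(degree = deg, mean_degree = mean_deg)
}
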