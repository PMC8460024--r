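#' Draw a synthetic colony with known ground truth
#'
#' Creates the latent state every downstream dataset is generated from:
#' a Beta-distributed differentiated relationship matrix (few strong, many
#' weak dyads when the concentration is low), the kinship matrix, per-bat
#' departure-time and bout-duration intercepts, and — for the previously
#' captive subset — grooming and food-sharing rate networks generated as
#' noisy monotone transforms of the latent relationship.
#'
#' @param params a [colony_params()] object.
#' @return A `synthetic_truth` list: `params`, `bats` (id, type,
#'   dropout_night, intercepts), `relationship`, `kinship`, `grooming`,
#'   `sharing` ([dyadic_matrix()] objects) and the [study_calendar()].
#' @export
simulate_colony <- function(params) {
  stopifnot(inherits(params, "colony_params"))
  set.seed(derive_seed(params$seed, "colony"))
  bats <- params$bat_ids
  n <- params$n_bats
  types <- params$type_assignment

  drop_n <- rep(NA_integer_, n)
  if (!is.null(params$dropout_nights)) {
    drop_n[match(names(params$dropout_nights), bats)] <-
      as.integer(params$dropout_nights)
  }
  bat_tab <- data.frame(
    bat_id = bats, type = types, dropout_night = drop_n,
    depart_intercept_s = stats::rnorm(n, 0, type_value(params$between_bat_sd, types)),
    bout_intercept_log = stats::rnorm(n, 0, type_value(params$bout_between_sdlog, types)),
    stringsAsFactors = FALSE
  )

  mu <- params$relationship_mean
  kap <- params$relationship_concentration
  nd <- n * (n - 1) / 2
  w <- if (is.infinite(kap)) rep(mu, nd) else stats::rbeta(nd, mu * kap, (1 - mu) * kap)
  rel <- matrix(0, n, n, dimnames = list(bats, bats))
  rel[lower.tri(rel)] <- w
  rel <- dyadic_matrix(rel, bats = bats, role = "rate")

  kin <- matrix(0, n, n, dimnames = list(bats, bats))
  kp <- params$kin_pairs
  if (!is.null(kp) && nrow(kp) > 0) {
    kin[cbind(kp$bat_a, kp$bat_b)] <- kp$kinship
    kin[cbind(kp$bat_b, kp$bat_a)] <- kp$kinship
  }
  kin <- dyadic_matrix(kin, bats = bats, role = "kinship")

  # captive cooperation networks exist only for the previously captive subset
  captive <- bats[types != "control"]
  groom <- share <- matrix(NA_real_, n, n, dimnames = list(bats, bats))
  if (length(captive) >= 2) {
    sub <- unclass(rel)[captive, captive]
    sym_noise <- function(k, sd) {
      m <- matrix(0, k, k)
      m[lower.tri(m)] <- stats::rnorm(k * (k - 1) / 2, 0, sd)
      m[upper.tri(m)] <- t(m)[upper.tri(m)]
      m
    }
    groom[captive, captive] <- sub * exp(sym_noise(length(captive), 0.4))
    share[captive, captive] <- sub * exp(sym_noise(length(captive), 0.4))
  }
  groom <- dyadic_matrix(groom, bats = bats, role = "rate")
  share <- dyadic_matrix(share, bats = bats, role = "rate")

  structure(list(params = params, bats = bat_tab,
                 relationship = rel, kinship = kin,
                 grooming = groom, sharing = share,
                 calendar = study_calendar(params$n_nights,
                                           params$night_s, params$day_s)),
            class = "synthetic_truth")
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat("<synthetic_truth>", nrow(x$bats), "bats,", x$params$n_nights,
      "nights, seed", x$params$seed, "\n")
  invisible(x)
}

# which bats still use the roost in period i (dropout bats leave after
# their dropout night, so night/day i requires i <= dropout_night)
present_in_period <- function(truth, i) {
  keep <- is.na(truth$bats$dropout_night) | i <= truth$bats$dropout_night
  truth$bats$bat_id[keep]
}

#' Closed-form expected daytime association seconds for a dyad-day
#'
#' Events per dyad-day are Poisson with rate
#' `day_hours * (base + slope * relationship)`; durations are
#' `1 + Poisson(mean_dur - 1)`, so the expected total is the product of the
#' two means. Used by parameter-recovery tests.
#'
#' @param truth a [simulate_colony()] result.
#' @param bat_a,bat_b bat ids.
#' @return Expected association seconds per day for the dyad.
#' @export
expected_roosting_seconds <- function(truth, bat_a, bat_b) {
  p <- truth$params
  r <- unclass(truth$relationship)[bat_a, bat_b]
  lam <- (p$day_s / 3600) * (p$assoc_events_per_hour_base +
                             p$assoc_events_per_hour_slope * r)
  lam * p$assoc_dur_mean_s
}

#' Per-hour reunion probability from the generator's cloglog link
#'
#' @param params a [colony_params()].
#' @param relationship,kinship covariate values in `[0, 1]`.
#' @return Probability that a dyad outside the roost in the same hour has at
#'   least one foraging encounter that hour.
#' @export
reunion_probability <- function(params, relationship, kinship = 0) {
  eta0 <- log(-log(1 - params$baseline_encounter_rate))
  1 - exp(-exp(eta0 + params$beta_relationship * relationship +
                 params$beta_kinship * kinship))
}

draw_signal <- function(n, params) {
  u <- stats::runif(n)
  sig <- numeric(n)
  sub <- u < params$p_subthreshold
  clo <- !sub & u < params$p_subthreshold + params$p_close
  mid <- !sub & !clo
  sig[sub] <- stats::runif(sum(sub), params$assoc_signal - 10, params$assoc_signal - 1e-6)
  sig[clo] <- stats::runif(sum(clo), params$close_signal, params$close_signal + 20)
  sig[mid] <- stats::runif(sum(mid), params$assoc_signal, params$close_signal - 1e-6)
  round(sig, 2)
}

#' Simulate the daytime (roosting) sensor streams
#'
#' For each day and each dyad of in-roost bats, association events are drawn
#' with expectation increasing in the latent relationship weight; every
#' in-roost bat holds continuous roost-station contact through the day.
#'
#' @param truth a [simulate_colony()] result.
#' @return list with `events` (bat_a, bat_b, start_s, duration_s, max_signal)
#'   and `stations` (bat, station_id, start_s, duration_s).
#' @export
simulate_roosting_days <- function(truth) {
  p <- truth$params
  cal <- truth$calendar
  set.seed(derive_seed(p$seed, "roosting"))
  ev <- vector("list", p$n_nights)
  st <- vector("list", p$n_nights)
  rel <- unclass(truth$relationship)
  for (d in seq_len(p$n_nights)) {
    bd <- day_bounds(cal, d)
    present <- present_in_period(truth, d)
    st[[d]] <- data.frame(bat = present, station_id = "roost",
                          start_s = bd[["start"]],
                          duration_s = bd[["end"]] - bd[["start"]],
                          stringsAsFactors = FALSE)
    if (length(present) < 2) next
    dy <- all_dyads(present)
    lam <- (p$day_s / 3600) *
      (p$assoc_events_per_hour_base +
         p$assoc_events_per_hour_slope * rel[cbind(dy$bat_a, dy$bat_b)])
    nev <- stats::rpois(nrow(dy), lam)
    if (sum(nev) == 0) next
    ia <- rep(dy$bat_a, nev); ib <- rep(dy$bat_b, nev)
    start <- floor(stats::runif(sum(nev), bd[["start"]], bd[["end"]] - 2))
    dur <- 1 + stats::rpois(sum(nev), p$assoc_dur_mean_s - 1)
    dur <- pmin(dur, bd[["end"]] - start)
    ev[[d]] <- data.frame(bat_a = ia, bat_b = ib, start_s = start,
                          duration_s = dur, max_signal = draw_signal(sum(nev), p),
                          stringsAsFactors = FALSE)
  }
  events <- do.call(rbind, ev[!vapply(ev, is.null, TRUE)])
  if (is.null(events)) {
    events <- data.frame(bat_a = character(), bat_b = character(),
                         start_s = numeric(), duration_s = numeric(),
                         max_signal = numeric(), stringsAsFactors = FALSE)
  }
  events <- canonicalize_events(events)
  stations <- do.call(rbind, st)
  list(events = events, stations = stations[order(stations$start_s, stations$bat), ])
}

canonicalize_events <- function(events) {
  if (nrow(events) == 0) return(events)
  o <- order_dyad(events$bat_a, events$bat_b)
  events$bat_a <- o$bat_a; events$bat_b <- o$bat_b
  events <- events[order(events$start_s, events$bat_a, events$bat_b), ]
  rownames(events) <- NULL
  events
}

#' Simulate nightly departures, foraging bouts, and foraging reunions
#'
#' Per bat and night, departure time is
#' `type mean + drift * (night - 1) + bat intercept + noise`; departures are
#' pushed apart so no two fall within the minimum gap. Bats hold
#' roost-station contact while in the roost (with a short margin after
#' departure / before return, plus occasional brief mid-bout revisits near
#' the roost tree). For every clock hour in which both bats of a dyad are
#' outside, a reunion occurs with cloglog-linear probability in
#' relationship and kinship; encounter durations are a mixture of a 1-s
#' point mass and a log-normal tail truncated below 30 minutes.
#'
#' @param truth a [simulate_colony()] result.
#' @return list with `events`, `stations`, `bouts` (bat, night_index,
#'   depart_s, return_s, censored) and `true_encounters` (night, hour,
#'   bat_a, bat_b, start_s, duration_s).
#' @export
simulate_foraging_nights <- function(truth) {
  p <- truth$params
  cal <- truth$calendar
  set.seed(derive_seed(p$seed, "foraging"))
  rel <- unclass(truth$relationship)
  kin <- unclass(truth$kinship)
  eta0 <- log(-log(1 - p$baseline_encounter_rate))

  bouts <- list(); stats_l <- list(); evs <- list(); tru <- list()
  for (ni in seq_len(p$n_nights)) {
    nb <- night_bounds(cal, ni)
    present <- present_in_period(truth, ni)
    if (length(present) == 0) next
    bt <- truth$bats[match(present, truth$bats$bat_id), ]
    dep <- nb[["start"]] +
      type_value(p$depart_mean_by_type, bt$type) +
      p$depart_drift * (ni - 1) +
      bt$depart_intercept_s +
      stats::rnorm(length(present), 0, p$within_bat_sd)
    dep <- pmin(pmax(dep, nb[["start"]] + 600), nb[["end"]] - 3600)
    # enforce the minimum departure gap by pushing later bats back
    o <- order(dep)
    dep_o <- dep[o]
    for (i in seq_along(dep_o)[-1]) {
      if (dep_o[i] - dep_o[i - 1] < p$min_depart_gap_s) {
        dep_o[i] <- dep_o[i - 1] + p$min_depart_gap_s
      }
    }
    dep[o] <- dep_o
    dep <- round(dep)
    dur <- exp(log(type_value(p$bout_mean_s, bt$type)) +
                 bt$bout_intercept_log +
                 stats::rnorm(length(present), 0, p$bout_within_sdlog))
    ret <- round(dep + dur)
    censored <- ret > nb[["end"]] - 60
    ret <- pmin(ret, nb[["end"]] - 60)
    bouts[[ni]] <- data.frame(bat = present, night_index = ni,
                              depart_s = dep, return_s = ret,
                              censored = censored, stringsAsFactors = FALSE)

    # roost-station contacts: in-roost spans plus the contact margin,
    # plus occasional mid-bout revisits
    m <- p$contact_margin_s
    pre <- data.frame(bat = present, station_id = "roost",
                      start_s = nb[["start"]],
                      duration_s = pmax(0, dep + m - nb[["start"]]),
                      stringsAsFactors = FALSE)
    post <- data.frame(bat = present, station_id = "roost",
                       start_s = ret - m,
                       duration_s = nb[["end"]] - (ret - m),
                       stringsAsFactors = FALSE)
    revisit <- stats::runif(length(present)) < p$roost_revisit_prob &
      (ret - dep) > 1200
    if (any(revisit)) {
      rs <- floor(stats::runif(sum(revisit), dep[revisit] + 300,
                               ret[revisit] - 420))
      post <- rbind(post, data.frame(bat = present[revisit],
                                     station_id = "roost", start_s = rs,
                                     duration_s = 120, stringsAsFactors = FALSE))
    }
    stats_l[[ni]] <- rbind(pre, post)

    # hourly reunions among dyads simultaneously outside
    if (length(present) >= 2) {
      dy <- all_dyads(present)
      ia <- match(dy$bat_a, present); ib <- match(dy$bat_b, present)
      hours <- seq(floor(nb[["start"]] / 3600), ceiling(nb[["end"]] / 3600) - 1)
      p_reu <- 1 - exp(-exp(eta0 +
                              p$beta_relationship * rel[cbind(dy$bat_a, dy$bat_b)] +
                              p$beta_kinship * kin[cbind(dy$bat_a, dy$bat_b)]))
      for (h in hours) {
        h0 <- h * 3600; h1 <- h0 + 3600
        ov0 <- pmax(pmax(dep[ia], dep[ib]), h0)
        ov1 <- pmin(pmin(ret[ia], ret[ib]), h1)
        open <- which(ov1 - ov0 >= 2)
        if (length(open) == 0) next
        meet <- open[stats::runif(length(open)) < p_reu[open]]
        if (length(meet) == 0) next
        n_enc <- 1 + stats::rpois(length(meet), p$extra_encounter_rate)
        idx <- rep(meet, n_enc)
        start <- floor(stats::runif(length(idx), ov0[idx], ov1[idx] - 1))
        kv <- kin[cbind(dy$bat_a[idx], dy$bat_b[idx])]
        short <- stats::runif(length(idx)) < p$p_short_encounter
        raw <- numeric(length(idx))
        raw[short] <- stats::runif(sum(short), 0.3, 1.99)
        raw[!short] <- pmin(
          stats::rlnorm(sum(!short),
                        p$enc_dur_meanlog + p$kin_dur_effect * kv[!short],
                        p$enc_dur_sdlog),
          1799)
        raw <- pmin(raw, ov1[idx] - start)
        raw <- pmax(raw, 0.3)
        df <- data.frame(bat_a = dy$bat_a[idx], bat_b = dy$bat_b[idx],
                         start_s = start, duration_s = round(raw, 1),
                         max_signal = pmax(draw_signal(length(idx), p),
                                           p$assoc_signal),
                         stringsAsFactors = FALSE)
        evs[[length(evs) + 1]] <- df
        tru[[length(tru) + 1]] <- data.frame(
          night = ni, hour = h, bat_a = dy$bat_a[idx], bat_b = dy$bat_b[idx],
          start_s = start, duration_s = normalize_duration(raw),
          stringsAsFactors = FALSE)
      }
    }
  }
  events <- if (length(evs)) do.call(rbind, evs) else
    data.frame(bat_a = character(), bat_b = character(), start_s = numeric(),
               duration_s = numeric(), max_signal = numeric(),
               stringsAsFactors = FALSE)
  truths <- if (length(tru)) do.call(rbind, tru) else
    data.frame(night = integer(), hour = integer(), bat_a = character(),
               bat_b = character(), start_s = numeric(), duration_s = numeric(),
               stringsAsFactors = FALSE)
  stations <- do.call(rbind, stats_l)
  stations <- stations[stations$duration_s > 0, ]
  list(events = canonicalize_events(events),
       stations = stations[order(stations$start_s, stations$bat), ],
       bouts = do.call(rbind, bouts),
       true_encounters = truths)
}

#' Simulate captive co-feeding observation streams
#'
#' Emulates hourly feeder watches of the previously captive subset: per
#' hour a random set of bats is observed at the blood-spout feeders, and
#' each observed dyad co-feeds with a probability that is flat by default
#' (identity-independent) or weakly increasing in the latent relationship.
#'
#' @param truth a [simulate_colony()] result (previously captive subset
#'   must be non-empty).
#' @param n_nights observation nights (default 70).
#' @param hours_per_night observation hours per night (default 15).
#' @return list with `events` (night, hour, bat_a, bat_b) and `presence`
#'   (night, hour, bat).
#' @export
simulate_captive_feeding <- function(truth, n_nights = 70, hours_per_night = 15) {
  p <- truth$params
  if (hours_per_night <= 0) stop("hours_per_night must be positive")
  captive <- truth$bats$bat_id[truth$bats$type != "control"]
  if (length(captive) < 2) stop("previously captive subset must contain >= 2 bats")
  set.seed(derive_seed(p$seed, "cofeeding"))
  rel <- unclass(truth$relationship)
  # per-bat presence probabilities (recycled); unequal values create the
  # shared-feeding-time confound the double permutation adjusts for
  pp <- rep(p$cofeed_presence_p, length.out = length(captive))
  pres <- list(); evs <- list()
  for (ni in seq_len(n_nights)) {
    for (h in seq_len(hours_per_night)) {
      here <- captive[stats::runif(length(captive)) < pp]
      if (length(here) == 0) next
      pres[[length(pres) + 1]] <- data.frame(night = ni, hour = h, bat = here,
                                             stringsAsFactors = FALSE)
      if (length(here) < 2) next
      dy <- all_dyads(here)
      pr <- p$cofeed_base_p *
        (1 + p$cofeed_rel_effect * rel[cbind(dy$bat_a, dy$bat_b)])
      hit <- stats::runif(nrow(dy)) < pr
      if (any(hit)) {
        evs[[length(evs) + 1]] <- data.frame(night = ni, hour = h,
                                             bat_a = dy$bat_a[hit],
                                             bat_b = dy$bat_b[hit],
                                             stringsAsFactors = FALSE)
      }
    }
  }
  events <- if (length(evs)) do.call(rbind, evs) else
    data.frame(night = integer(), hour = integer(), bat_a = character(),
               bat_b = character(), stringsAsFactors = FALSE)
  presence <- do.call(rbind, pres)
  rownames(events) <- rownames(presence) <- NULL
  list(events = events, presence = presence)
}

#' Generate a complete synthetic study dataset
#'
#' Runs [simulate_colony()] and all stream generators, merging the daytime
#' and nighttime sensor streams into single event and station tables.
#'
#' @param params a [colony_params()].
#' @param cofeed_nights,cofeed_hours captive observation effort.
#' @return A `synthetic_study` list: `truth`, `events`, `stations`,
#'   `bouts` (true bouts), `true_encounters`, `cofeeding`.
#' @export
simulate_study <- function(params, cofeed_nights = 70, cofeed_hours = 15) {
  truth <- simulate_colony(params)
  roost <- simulate_roosting_days(truth)
  forage <- simulate_foraging_nights(truth)
  events <- canonicalize_events(rbind(roost$events, forage$events))
  stations <- rbind(roost$stations, forage$stations)
  stations <- stations[order(stations$start_s, stations$bat), ]
  rownames(stations) <- NULL
  cofeed <- simulate_captive_feeding(truth, cofeed_nights, cofeed_hours)
  structure(list(truth = truth, events = events, stations = stations,
                 bouts = forage$bouts, true_encounters = forage$true_encounters,
                 cofeeding = cofeed),
            class = "synthetic_study")
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat("<synthetic_study>", nrow(x$truth$bats), "bats |",
      nrow(x$events), "proximity events |", nrow(x$bouts), "true bouts |",
      nrow(x$cofeeding$events), "co-feeding events\n")
  invisible(x)
}
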