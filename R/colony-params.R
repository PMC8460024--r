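#' Parameters of a synthetic vampire-bat colony
#'
#' Bundles every knob of the synthetic study generator. Defaults reproduce
#' the field-study conditions: 50 tagged female bats (27 never-captive
#' controls, 17 previously captive adults, 6 captive-born daughters), 9
#' study nights, departure times drifting 14 min later per night,
#' previously captive bats departing 1.6 h (captive-born 2.0 h) earlier
#' than controls, departure-time repeatability targets of 0.58 / 0.21 / 0
#' by type, and 9 of the 23 previously captive bats (including all
#' captive-born) leaving the roost mid-study.
#'
#' @param n_bats number of bats (>= 2).
#' @param type_assignment per-bat label in `control`, `previously_captive`,
#'   `captive_born`. Defaults to the 27/17/6 study split (scaled
#'   proportionally if `n_bats` differs).
#' @param n_nights number of study nights (default 9).
#' @param relationship_mean mean of the latent Beta relationship weights.
#' @param relationship_concentration Beta concentration; small values give a
#'   right-skewed, highly differentiated colony (few strong, many weak
#'   dyads); `Inf` collapses all weights to the mean (no differentiation).
#' @param kin_pairs data.frame `bat_a`, `bat_b`, `kinship` of known kin
#'   dyads (all others default to 0). Mother-daughter pairs get 0.5.
#' @param baseline_encounter_rate per-hour reunion probability for a dyad
#'   with zero relationship and kinship, both bats outside the roost.
#' @param beta_relationship,beta_kinship log-scale (cloglog-link) effects of
#'   relationship weight and kinship on the hourly reunion probability.
#' @param depart_mean_by_type named vector, mean departure time by type in
#'   seconds after sunset (defaults 8.3 h / 6.7 h / 6.3 h).
#' @param depart_drift seconds later per night (default 840 s = 14 min).
#' @param between_bat_sd named vector, between-bat SD of departure time by
#'   type. Together with `within_bat_sd` and the shared nightly drift
#'   (which adds to the within-bat variance of unadjusted repeatability)
#'   the defaults target departure-time ICCs of 0.58 / 0.21 / 0 by type.
#' @param within_bat_sd within-bat (night-to-night) departure SD, seconds.
#' @param bout_mean_s named vector, median foraging-bout duration by type.
#' @param bout_between_sdlog,bout_within_sdlog log-scale variance components
#'   of bout duration (set the per-type bout-duration repeatability).
#' @param dropout_nights named integer vector (bat id -> last night the bat
#'   uses the roost), `NULL` for no dropout, or `"study"` (default) for the
#'   study pattern: all captive-born bats plus three previously captive
#'   bats leave the roost mid-study.
#' @param min_depart_gap_s departures of different bats are pushed at least
#'   this far apart (default 6 s, so no two within 5 s).
#' @param assoc_events_per_hour_base,assoc_events_per_hour_slope daytime
#'   association events per dyad-hour: base + slope * relationship.
#' @param assoc_dur_mean_s mean duration of a daytime association event.
#' @param p_close probability an event reaches close-contact signal level.
#' @param p_subthreshold probability an event's peak signal stays below the
#'   association threshold (dropped during classification).
#' @param assoc_signal,close_signal generator-side signal thresholds
#'   (arbitrary units, larger = closer).
#' @param contact_margin_s roost-station contact persists this long past a
#'   departure (and precedes a return): sensor-range slack near the roost.
#' @param roost_revisit_prob per-bout probability of a brief mid-bout
#'   roost-station contact (bat lingering near the roost tree).
#' @param extra_encounter_rate Poisson rate of additional same-hour
#'   encounters given a dyad reunited in an hour.
#' @param p_short_encounter probability a foraging encounter is shorter
#'   than two beacon intervals (logged duration < 2 s, normalized to 1 s).
#' @param enc_dur_meanlog,enc_dur_sdlog log-normal tail of foraging
#'   encounter durations, truncated below 30 min.
#' @param kin_dur_effect additive meanlog shift per unit kinship (close kin
#'   have longer encounters).
#' @param cofeed_base_p per-shared-hour probability of a co-feeding event
#'   for an unrelated dyad.
#' @param cofeed_rel_effect multiplicative relationship effect on co-feeding
#'   (0 = identity-independent co-feeding, the study's weak-preference
#'   regime).
#' @param cofeed_presence_p per-hour probability a captive bat is observed
#'   at the feeders; a vector is recycled over the captive bats, and
#'   unequal values create heterogeneous shared feeding time (the
#'   confound the double permutation test adjusts for).
#' @param night_s,day_s night/day lengths in seconds (12 h / 12 h default).
#' @param seed integer master seed for the generator.
#' @return A validated `colony_params` list.
#' @export
colony_params <- function(n_bats = 50,
                          type_assignment = NULL,
                          n_nights = 9,
                          relationship_mean = 0.15,
                          relationship_concentration = 0.8,
                          kin_pairs = NULL,
                          baseline_encounter_rate = 0.002,
                          beta_relationship = 5.5,
                          beta_kinship = 1.5,
                          depart_mean_by_type = c(control = 29880,
                                                  previously_captive = 24120,
                                                  captive_born = 22680),
                          depart_drift = 840,
                          between_bat_sd = c(control = 3312,
                                             previously_captive = 1453,
                                             captive_born = 0),
                          within_bat_sd = 1800,
                          bout_mean_s = c(control = 9000,
                                          previously_captive = 8400,
                                          captive_born = 8400),
                          bout_between_sdlog = c(control = 0.379,
                                                 previously_captive = 0.257,
                                                 captive_born = 0.147),
                          bout_within_sdlog = 0.35,
                          dropout_nights = "study",
                          min_depart_gap_s = 6,
                          assoc_events_per_hour_base = 0.2,
                          assoc_events_per_hour_slope = 2,
                          assoc_dur_mean_s = 90,
                          p_close = 0.3,
                          p_subthreshold = 0.05,
                          assoc_signal = 20,
                          close_signal = 40,
                          contact_margin_s = 20,
                          roost_revisit_prob = 0.1,
                          extra_encounter_rate = 0.2,
                          p_short_encounter = 0.6,
                          enc_dur_meanlog = log(3),
                          enc_dur_sdlog = 1.2,
                          kin_dur_effect = 1.5,
                          cofeed_base_p = 0.003,
                          cofeed_rel_effect = 0,
                          cofeed_presence_p = 0.5,
                          night_s = 43200,
                          day_s = 43200,
                          seed = 1L) {
  if (n_bats < 2) stop("n_bats must be >= 2")
  if (is.null(type_assignment)) {
    type_assignment <- default_type_assignment(n_bats)
  }
  type_assignment <- match.arg(type_assignment,
                               c("control", "previously_captive", "captive_born"),
                               several.ok = TRUE)
  if (length(type_assignment) != n_bats) {
    stop("type_assignment must have one label per bat")
  }
  bat_ids <- default_bat_ids(type_assignment)
  if (is.null(kin_pairs)) kin_pairs <- default_kin_pairs(bat_ids, type_assignment)
  if (nrow(kin_pairs) > 0) {
    unknown <- setdiff(c(kin_pairs$bat_a, kin_pairs$bat_b), bat_ids)
    if (length(unknown) > 0) {
      stop("kin pair references unknown bat(s): ", paste(unknown, collapse = ", "))
    }
    if (any(kin_pairs$kinship < 0 | kin_pairs$kinship > 1)) {
      stop("kinship values must lie in [0, 1]")
    }
  }
  if (identical(dropout_nights, "study")) {
    dropout_nights <- default_dropout(bat_ids, type_assignment, n_nights)
  }
  if (!is.null(dropout_nights)) {
    unknown <- setdiff(names(dropout_nights), bat_ids)
    if (length(unknown) > 0) stop("dropout for unknown bat(s): ",
                                  paste(unknown, collapse = ", "))
  }
  stopifnot(relationship_mean > 0, relationship_mean < 1,
            relationship_concentration > 0,
            baseline_encounter_rate >= 0, baseline_encounter_rate < 1,
            within_bat_sd >= 0, all(between_bat_sd >= 0),
            n_nights >= 1, depart_drift >= 0,
            assoc_events_per_hour_base >= 0, assoc_dur_mean_s >= 1,
            cofeed_base_p >= 0, cofeed_presence_p >= 0, cofeed_presence_p <= 1)
  p <- list(n_bats = as.integer(n_bats), bat_ids = bat_ids,
            type_assignment = type_assignment, n_nights = as.integer(n_nights),
            relationship_mean = relationship_mean,
            relationship_concentration = relationship_concentration,
            kin_pairs = kin_pairs,
            baseline_encounter_rate = baseline_encounter_rate,
            beta_relationship = beta_relationship, beta_kinship = beta_kinship,
            depart_mean_by_type = depart_mean_by_type,
            depart_drift = depart_drift,
            between_bat_sd = between_bat_sd, within_bat_sd = within_bat_sd,
            bout_mean_s = bout_mean_s,
            bout_between_sdlog = bout_between_sdlog,
            bout_within_sdlog = bout_within_sdlog,
            dropout_nights = dropout_nights,
            min_depart_gap_s = min_depart_gap_s,
            assoc_events_per_hour_base = assoc_events_per_hour_base,
            assoc_events_per_hour_slope = assoc_events_per_hour_slope,
            assoc_dur_mean_s = assoc_dur_mean_s, p_close = p_close,
            p_subthreshold = p_subthreshold,
            assoc_signal = assoc_signal, close_signal = close_signal,
            contact_margin_s = contact_margin_s,
            roost_revisit_prob = roost_revisit_prob,
            extra_encounter_rate = extra_encounter_rate,
            p_short_encounter = p_short_encounter,
            enc_dur_meanlog = enc_dur_meanlog, enc_dur_sdlog = enc_dur_sdlog,
            kin_dur_effect = kin_dur_effect,
            cofeed_base_p = cofeed_base_p,
            cofeed_rel_effect = cofeed_rel_effect,
            cofeed_presence_p = cofeed_presence_p,
            night_s = night_s, day_s = day_s, seed = as.integer(seed))
  class(p) <- "colony_params"
  p
}

# 27/17/6 study split, scaled proportionally for other colony sizes
default_type_assignment <- function(n_bats) {
  if (n_bats == 50) {
    counts <- c(control = 27, previously_captive = 17, captive_born = 6)
  } else {
    counts <- round(n_bats * c(control = 27, previously_captive = 17,
                               captive_born = 6) / 50)
    counts["control"] <- n_bats - sum(counts[-1])
    if (counts["control"] < 1) {
      counts <- c(control = n_bats, previously_captive = 0, captive_born = 0)
    }
  }
  rep(names(counts), counts)
}

default_bat_ids <- function(types) {
  prefix <- c(control = "c", previously_captive = "p", captive_born = "j")[types]
  idx <- stats::ave(seq_along(types), types, FUN = seq_along)
  sprintf("%s%02d", prefix, idx)
}

# captive-born daughters paired with previously captive mothers at kinship 0.5
default_kin_pairs <- function(bat_ids, types) {
  daughters <- bat_ids[types == "captive_born"]
  mothers <- bat_ids[types == "previously_captive"]
  k <- min(length(daughters), length(mothers))
  if (k == 0) {
    return(data.frame(bat_a = character(), bat_b = character(),
                      kinship = numeric(), stringsAsFactors = FALSE))
  }
  o <- order_dyad(daughters[seq_len(k)], mothers[seq_len(k)])
  data.frame(bat_a = o$bat_a, bat_b = o$bat_b, kinship = 0.5,
             stringsAsFactors = FALSE)
}

# 9-of-23 dropout: all captive-born plus previously captive bats from the end
default_dropout <- function(bat_ids, types, n_nights) {
  born <- bat_ids[types == "captive_born"]
  prev <- bat_ids[types == "previously_captive"]
  extra <- utils::tail(prev, max(0, min(3, length(prev))))
  who <- c(born, extra)
  if (length(who) == 0) return(NULL)
  lastn <- max(2, n_nights - 1)
  nights <- rep(seq(2, lastn), length.out = length(who))
  stats::setNames(as.integer(nights), who)
}

#' @export
print.colony_params <- function(x, ...) {
  cat("<colony_params>", x$n_bats, "bats (",
      paste(names(table(x$type_assignment)), table(x$type_assignment),
            sep = "=", collapse = ", "),
      "),", x$n_nights, "nights, seed", x$seed, "\n")
  invisible(x)
}

# per-type lookup tolerating scalar parameters
type_value <- function(v, type) {
  if (length(v) == 1 && is.null(names(v))) rep(v, length(type)) else unname(v[type])
}
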