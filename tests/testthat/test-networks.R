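test_that("dyadic matrices enforce symmetry, zero diagonal, and role signs", {
  m <- matrix(c(0, 1, 2, 1, 0, 3, 2, 3, 0), 3,
              dimnames = list(letters[1:3], letters[1:3]))
  dm <- dyadic_matrix(m, role = "count")
  expect_true(isSymmetric(unclass(dm)))
  expect_true(all(diag(unclass(dm)) == 0))
  expect_error(dyadic_matrix(-m, role = "count"), "negative")
  expect_error(dyadic_matrix(m * 2, role = "kinship"), "0, 1")
  dyadic_matrix(-m, role = "adjusted")  # negatives allowed for adjusted
  tab <- dyad_table(dm)
  expect_identical(tab$value, c(1, 2, 3))
  # missingness propagates to both triangles
  m[2, 1] <- NA
  dm2 <- dyadic_matrix(m, role = "count")
  expect_true(is.na(unclass(dm2)["a", "b"]) && is.na(unclass(dm2)["b", "a"]))
})

test_that("roosting rate is association seconds over co-presence seconds", {
  cal <- study_calendar(n_nights = 1, night_s = 43200, day_s = 43200)
  cfg <- process_config(calendar = cal)
  # day 1 spans [43200, 86400); both bats in roost 36000 s, together 3600 s
  stations <- data.frame(bat = c("a", "b"), station_id = "roost",
                         start_s = 43200, duration_s = 36000,
                         stringsAsFactors = FALSE)
  enc <- data.frame(bat_a = "a", bat_b = "b", start_s = 50000,
                    duration_s = 3600, max_signal = 30,
                    proximity_class = "association", context = "roosting",
                    stringsAsFactors = FALSE)
  r <- roosting_network(enc, stations, "association", "aggregate", cfg)
  expect_equal(unclass(r)["a", "b"], 0.1)
  # a dyad never co-present is missing, not zero
  stations2 <- rbind(stations,
                     data.frame(bat = "c", station_id = "roost",
                                start_s = 200, duration_s = 100))  # nighttime only
  r2 <- roosting_network(enc, stations2, "association", "aggregate", cfg)
  expect_true(is.na(unclass(r2)["a", "c"]))
})

test_that("close-contact network is entrywise below the association network", {
  sp <- small_processed()
  ra <- roosting_network(sp$enc, sp$study$stations, "association",
                         "aggregate", sp$cfg, bats = sp$bats)
  rc <- roosting_network(sp$enc, sp$study$stations, "close_contact",
                         "aggregate", sp$cfg, bats = sp$bats)
  d <- unclass(ra) - unclass(rc)
  expect_true(all(d >= -1e-12, na.rm = TRUE))
})

test_that("aggregate roosting rate is the co-presence-weighted mean of daily rates", {
  sp <- small_processed()
  per_day <- roosting_network(sp$enc, sp$study$stations, "association",
                              "per_day", sp$cfg, bats = sp$bats)
  agg <- roosting_network(sp$enc, sp$study$stations, "association",
                          "aggregate", sp$cfg, bats = sp$bats)
  # reconstruct the weighted mean from daily rates and denominators
  rs <- sp$study$stations[sp$study$stations$station_id == "roost", ]
  cal <- sp$cfg$calendar
  pick <- c("c01", "c02")
  num <- 0; den <- 0
  for (d in seq_len(cal$n_nights)) {
    db <- (d - 1) * cal$cycle_s + cal$night_s
    cov <- lapply(pick, function(b) {
      s <- rs[rs$bat == b, ]
      lo <- pmax(s$start_s, db); hi <- pmin(s$start_s + s$duration_s, db + cal$day_s)
      sum(pmax(0, hi - lo))
    })
    ov_rate <- unclass(per_day$layers[[paste0("day", d)]])[pick[1], pick[2]]
    w <- interval_copresence <- NULL
    # co-presence seconds for the dyad that day (both full-day in this fixture)
    s1 <- rs[rs$bat == pick[1], ]; s2 <- rs[rs$bat == pick[2], ]
    cp <- 0
    for (i in seq_len(nrow(s1))) for (j in seq_len(nrow(s2))) {
      lo <- max(s1$start_s[i], s2$start_s[j], db)
      hi <- min(s1$start_s[i] + s1$duration_s[i],
                s2$start_s[j] + s2$duration_s[j], db + cal$day_s)
      cp <- cp + max(0, hi - lo)
    }
    if (!is.na(ov_rate) && cp > 0) {
      num <- num + ov_rate * cp
      den <- den + cp
    }
  }
  expect_equal(unclass(agg)[pick[1], pick[2]], num / den, tolerance = 1e-8)
})

test_that("foraging seconds and nights networks match a brute-force tally", {
  sp <- small_processed()
  fsec <- foraging_seconds_network(sp$enc, sp$bats)
  fnig <- foraging_nights_network(sp$enc, sp$bats, sp$cfg)
  f <- sp$enc[sp$enc$context == "foraging" & !is.na(sp$enc$proximity_class), ]
  for (dy in unique(paste(f$bat_a, f$bat_b))) {
    parts <- strsplit(dy, " ")[[1]]
    rows <- f[f$bat_a == parts[1] & f$bat_b == parts[2], ]
    expect_equal(unclass(fsec)[parts[1], parts[2]], sum(rows$duration_s))
    nights <- unique(night_of(sp$cfg$calendar, rows$start_s))
    expect_equal(unclass(fnig)[parts[1], parts[2]], length(nights))
  }
  expect_lte(max(unclass(fnig)), sp$cfg$calendar$n_nights)
  # empty input gives zero matrices
  none <- sp$enc[0, ]
  expect_true(all(unclass(foraging_seconds_network(none, sp$bats)) == 0))
})

test_that("hourly co-foraging counts one encounter per dyad-hour", {
  cal <- study_calendar(n_nights = 1)
  cfg <- process_config(calendar = cal)
  bouts <- data.frame(bat = c("a", "b"), night_index = 1L,
                      depart_s = 10000, return_s = 21000,
                      censored_depart = FALSE, censored_return = FALSE,
                      stringsAsFactors = FALSE)
  mk <- function(starts) data.frame(
    bat_a = "a", bat_b = "b", start_s = starts, duration_s = 2,
    max_signal = 30, proximity_class = "association", context = "foraging",
    stringsAsFactors = FALSE)
  # 14:05 and 14:40 (hour bin 3 within the night) -> one marked hour
  t1 <- hourly_coforaging(mk(c(3 * 3600 + 300, 3 * 3600 + 2400)), bouts, cfg)
  expect_equal(nrow(t1$records), 1)
  # 14:59 and 15:01 -> two marked hours
  t2 <- hourly_coforaging(mk(c(4 * 3600 - 60, 4 * 3600 + 60)), bouts, cfg)
  expect_equal(nrow(t2$records), 2)
  # per-dyad totals bounded by shared outside-hours
  cnt <- coforaging_counts(t2)
  shared <- sum(table(t2$outside$hour) == 2)
  expect_lte(unclass(cnt)["a", "b"], shared)
})

test_that("per-dyad co-foraging totals match the distinct night-hour count", {
  sp <- small_processed()
  tab <- hourly_coforaging(sp$enc, sp$bouts, sp$cfg)
  cnt <- coforaging_counts(tab)
  f <- sp$enc[sp$enc$context == "foraging" & !is.na(sp$enc$proximity_class), ]
  f$night <- night_of(sp$cfg$calendar, f$start_s)
  f$hour <- floor(f$start_s / 3600)
  for (dy in unique(paste(f$bat_a, f$bat_b))) {
    parts <- strsplit(dy, " ")[[1]]
    rows <- f[f$bat_a == parts[1] & f$bat_b == parts[2], ]
    expect_equal(unclass(cnt)[parts[1], parts[2]],
                 nrow(unique(rows[, c("night", "hour")])))
  }
  # totals never exceed shared outside-hours
  ok <- paste(tab$outside$night, tab$outside$hour)
  for (dy in unique(paste(tab$records$bat_a, tab$records$bat_b))) {
    parts <- strsplit(dy, " ")[[1]]
    sh <- length(intersect(ok[tab$outside$bat == parts[1]],
                           ok[tab$outside$bat == parts[2]]))
    expect_lte(unclass(cnt)[parts[1], parts[2]], sh)
  }
})

test_that("bout overlap equals the interval intersection formula", {
  bats <- c("a", "b", "c")
  bouts <- data.frame(
    bat = c("a", "b", "c", "a", "b"), night_index = c(1, 1, 1, 2, 2),
    depart_s = c(0, 0, 7200, 90000, 91000),
    return_s = c(3600, 3600, 10800, 95000, 96000),
    censored_depart = FALSE, censored_return = FALSE,
    stringsAsFactors = FALSE)
  ov <- bout_overlap(bouts, bats)
  expect_equal(unclass(ov)["a", "b"], 3600 + (95000 - 91000))
  expect_equal(unclass(ov)["a", "c"], 0)   # disjoint
  # brute-force per-second tally
  secs <- 0:11000
  in_a <- secs >= 0 & secs < 3600
  in_c <- secs >= 7200 & secs < 10800
  expect_equal(unclass(ov)["a", "c"], sum(in_a & in_c))
})

test_that("co-feeding network counts events symmetrically", {
  ev <- data.frame(night = c(1, 1, 2), hour = c(1, 2, 1),
                   bat_a = c("p1", "p1", "p1"), bat_b = c("p2", "p2", "p3"),
                   stringsAsFactors = FALSE)
  m <- cofeeding_network(ev, c("p1", "p2", "p3"))
  expect_equal(unclass(m)["p1", "p2"], 2)
  expect_equal(unclass(m)["p2", "p1"], 2)
  expect_equal(unclass(m)["p1", "p3"], 1)
  expect_true(all(unclass(cofeeding_network(ev[0, ], c("p1", "p2"))) == 0))
})

test_that("degree centrality treats zero-encounter periods as missing", {
  bats <- c("a", "b", "c", "d")
  lay <- function(edges) {
    m <- matrix(0, 4, 4, dimnames = list(bats, bats))
    for (e in edges) m[e[1], e[2]] <- m[e[2], e[1]] <- 1
    dyadic_matrix(m, role = "count")
  }
  net <- day_stratified_network(
    layers = list(p1 = lay(list(c("a", "b"), c("a", "c"), c("a", "d"), c("b", "c"))),
                  p2 = lay(list(c("b", "c"))),
                  p3 = lay(list(c("a", "b"), c("a", "c"), c("a", "d"),
                                c("b", "c"), c("b", "d"), c("c", "d")))),
    presence = list(p1 = bats, p2 = bats, p3 = c("a", "b", "c")))
  prof <- degree_centrality_profiles(net)
  # a: degrees 3, missing (no encounters), then 2 among the present trio
  expect_equal(unname(prof$degree["a", ]), c(3, NA, 2))
  expect_equal(unname(prof$mean_degree["a"]), 2.5)
  # d absent in p3 -> missing even though the full layer had edges
  expect_true(is.na(prof$degree["d", "p3"]))
  # bat with no encounters anywhere stays NA, never zero
  net2 <- day_stratified_network(
    layers = list(p1 = lay(list(c("a", "b")))),
    presence = list(p1 = bats))
  prof2 <- degree_centrality_profiles(net2)
  expect_true(is.na(prof2$mean_degree["c"]))
})

test_that("stratified networks blank absent bats and aggregate with missingness", {
  bats <- c("a", "b", "c")
  m <- matrix(1, 3, 3, dimnames = list(bats, bats)); diag(m) <- 0
  net <- day_stratified_network(
    layers = list(p1 = dyadic_matrix(m, role = "seconds"),
                  p2 = dyadic_matrix(m * 2, role = "seconds")),
    presence = list(p1 = bats, p2 = c("a", "b")))
  expect_true(is.na(unclass(net$layers$p2)["a", "c"]))
  agg <- aggregate_layers(net)
  expect_equal(unclass(agg)["a", "b"], 3)
  expect_equal(unclass(agg)["a", "c"], 1)  # only p1 observed
})
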