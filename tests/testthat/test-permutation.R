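test_that("permutation p-values follow the add-one convention", {
  expect_equal(p_value(rep(0, 4999), 1, "greater"), 1 / 5000)
  expect_equal(p_value(rep(2, 100), 1, "greater"), 1)
  expect_equal(p_value(rep(2, 100), 1, "less"), 1 / 101)
  # matches enumeration on a 10-draw toy
  null <- c(0.1, 0.2, 0.3, 0.4, 0.5, 0.6, 0.7, 0.8, 0.9, 1.0)
  obs <- 0.75
  expect_equal(p_value(null, obs, "greater"), (1 + 3) / 11)
  expect_equal(p_value(null, obs, "less"), (1 + 7) / 11)
  expect_equal(p_value(null, obs, "two_sided"), 2 * (1 + 3) / 11)
  # two-sided caps at 1
  expect_equal(p_value(c(1, 1, 1), 1, "two_sided"), 1)
})

test_that("the coefficient of variation behaves like the textbook formula", {
  expect_equal(cv_statistic(c(2, 2, 2)), 0)
  expect_equal(cv_statistic(c(0, 0, 6)), sqrt(12) / 2)
  v <- c(0, 1, 4, 2, 7)
  expect_equal(cv_statistic(v * 3.7), cv_statistic(v))  # scale invariance
  expect_error(cv_statistic(c(0, 0, 0)), class = "proxinet_degenerate")
  expect_error(cv_statistic(2), "at least 2")
})

test_that("ICC recovers the degenerate endpoints and matches REML when balanced", {
  # zero within-group variance -> ICC exactly 1
  r1 <- icc_unadjusted(rep(c(1, 5, 9), each = 4), rep(1:3, each = 4))
  expect_identical(r1$icc, 1)
  # identical group means with positive within variance -> ICC exactly 0
  r0 <- icc_unadjusted(c(1, 3, 1, 3, 1, 3), rep(1:3, each = 2))
  expect_identical(r0$icc, 0)
  expect_error(icc_unadjusted(1:5, rep(1, 5)), "fewer than 2 groups")
  expect_error(icc_unadjusted(1:3, 1:3), "singleton")
  # balanced positive-variance case agrees with the mixed-model estimator
  set.seed(7)
  g <- rep(1:12, each = 6)
  y <- rnorm(12, sd = 2)[g] + rnorm(72)
  ours <- icc_unadjusted(y, g)
  fit <- lme4::lmer(y ~ 1 + (1 | g), REML = TRUE)
  vc <- as.data.frame(lme4::VarCorr(fit))
  icc_lmm <- vc$vcov[1] / sum(vc$vcov)
  expect_equal(ours$icc, icc_lmm, tolerance = 1e-6)
})

test_that("differentiation test matches exhaustive enumeration on a toy table", {
  outside <- expand.grid(night = 1L, hour = 1:2, bat = c("a", "b", "c"),
                         stringsAsFactors = FALSE)[, c(1, 2, 3)]
  records <- data.frame(night = 1L, hour = c(1L, 2L),
                        bat_a = c("a", "a"), bat_b = c("b", "b"),
                        stringsAsFactors = FALSE)
  tab <- make_cofor_table(records, outside)
  enum <- enum_differentiation_tail(tab)
  got <- differentiation_test(tab, n_perm = 4000, seed = 99)
  expect_equal(got$observed, enum$observed, tolerance = 1e-10)
  expect_lt(abs(got$p_value - enum$tail), mc_tolerance(enum$tail, 4000))
  # determinism under a fixed seed
  again <- differentiation_test(tab, n_perm = 200, seed = 5)
  expect_identical(differentiation_test(tab, n_perm = 200, seed = 5), again)
})

test_that("records without randomization freedom are kept and counted", {
  outside <- data.frame(night = 1L, hour = 1L, bat = c("a", "b"),
                        stringsAsFactors = FALSE)
  records <- data.frame(night = 1L, hour = c(1L, 1L),
                        bat_a = c("a", "a"), bat_b = c("b", "b"),
                        stringsAsFactors = FALSE)
  records <- unique(records)
  outside2 <- rbind(outside,
                    data.frame(night = 1L, hour = 2L, bat = c("a", "b", "c")))
  records2 <- rbind(records,
                    data.frame(night = 1L, hour = 2L, bat_a = "a", bat_b = "b"))
  got <- differentiation_test(make_cofor_table(records2, outside2),
                              n_perm = 50, seed = 1)
  expect_equal(attr(got, "n_frozen_records"), 1L)
  # a record naming a bat not outside errors
  bad <- make_cofor_table(
    data.frame(night = 1L, hour = 1L, bat_a = "a", bat_b = "z"),
    outside)
  expect_error(differentiation_test(bad, n_perm = 10, seed = 1),
               "at least 2")
  bad2 <- make_cofor_table(
    data.frame(night = 1L, hour = c(1L, 1L), bat_a = c("a", "a"),
               bat_b = c("z", "b")), outside)
  expect_error(differentiation_test(bad2, n_perm = 10, seed = 1),
               "not outside")
})

test_that("within-hour relabeling conserves marginals and matches enumeration", {
  presence <- data.frame(night = 1L, hour = 1L, bat = c("a", "b", "c"),
                         stringsAsFactors = FALSE)
  events <- data.frame(night = 1L, hour = 1L, bat_a = c("a", "a"),
                       bat_b = c("b", "c"), stringsAsFactors = FALSE)
  n_perm <- 3000
  arr <- within_hour_identity_permutation(events, presence, n_perm = n_perm,
                                          seed = 3)
  # total event mass conserved in every permutation
  expect_true(all(apply(arr, 3, sum) == 2 * nrow(events)))
  # expected null counts match enumeration over all 3! relabelings
  expected <- enum_within_hour_expected(events, presence, c("a", "b", "c"))
  got_mean <- apply(arr, c(1, 2), mean)
  expect_lt(max(abs(got_mean - expected)), 0.06)
  # an hour with exactly 2 bats present fixes its events
  p2 <- data.frame(night = 1L, hour = 1L, bat = c("a", "b"),
                   stringsAsFactors = FALSE)
  e2 <- data.frame(night = 1L, hour = 1L, bat_a = "a", bat_b = "b",
                   stringsAsFactors = FALSE)
  arr2 <- within_hour_identity_permutation(e2, p2, n_perm = 20, seed = 1)
  expect_true(all(arr2["a", "b", ] == 1))
  # naming an absent bat errors
  expect_error(
    within_hour_identity_permutation(
      data.frame(night = 1L, hour = 1L, bat_a = "a", bat_b = "z"), p2,
      bats = c("a", "b", "z"), n_perm = 5, seed = 1),
    "not recorded as present")
})

test_that("double permutation recovers a self-predictor and rejects constants", {
  sp <- small_processed()
  capt <- sp$bats[sp$study$truth$bats$type != "control"]
  cof <- sp$study$cofeeding
  flat <- dyadic_matrix(matrix(1, length(capt), length(capt),
                               dimnames = list(capt, capt)), role = "rate")
  expect_error(double_permutation_test(cof$events, cof$presence, flat,
                                       n_perm = 10, seed = 1), "constant")
  dp0 <- double_permutation_test(cof$events, cof$presence,
                                 dyadic_matrix(unclass(sp$study$truth$sharing)[capt, capt],
                                               bats = capt, role = "rate"),
                                 n_perm = 200, seed = 2)
  # predictor equal to the adjusted matrix itself -> r = 1, p at floor
  dp1 <- double_permutation_test(cof$events, cof$presence, dp0$adjusted,
                                 n_perm = 200, seed = 3)
  expect_equal(dp1$result$observed, 1)
  expect_equal(dp1$result$p_value, 1 / 201)
})

test_that("QAP recovers a built-in coefficient exactly on a noiseless fixture", {
  bats <- paste0("b", 1:8)
  set.seed(11)
  x <- matrix(0, 8, 8, dimnames = list(bats, bats))
  x[lower.tri(x)] <- runif(28)
  xm <- dyadic_matrix(x, role = "rate")
  ym <- dyadic_matrix(unclass(xm) * 2, role = "seconds")
  q <- qap_regression(ym, list(x = xm), n_perm = 400, seed = 1)
  expect_equal(unname(q$coefficients[["x"]]), 2, tolerance = 1e-10)
  expect_equal(unname(q$coefficients[["(Intercept)"]]), 0, tolerance = 1e-10)
  expect_equal(unname(q$p_values[["x"]]), 2 / 401)  # two-sided floor
  # collinear predictors are refused
  expect_error(qap_regression(ym, list(a = xm, b = xm), n_perm = 10, seed = 1),
               "collinear")
})

test_that("constrained QAP null matches enumeration on a 4-bat 2-period toy", {
  bats <- paste0("b", 1:4)
  set.seed(21)
  mk <- function() {
    m <- matrix(0, 4, 4, dimnames = list(bats, bats))
    m[lower.tri(m)] <- round(runif(6) * 10)
    m[upper.tri(m)] <- t(m)[upper.tri(m)]
    m
  }
  l1 <- mk(); l2 <- mk(); xp <- mk()
  net <- day_stratified_network(
    layers = list(p1 = dyadic_matrix(l1, role = "seconds"),
                  p2 = dyadic_matrix(l2, role = "seconds")),
    presence = list(p1 = bats, p2 = bats))
  xm <- dyadic_matrix(xp, role = "rate")
  q <- qap_regression(net, list(x = xm), n_perm = 4000, seed = 2)
  exact <- enum_qap_null(list(unclass(net$layers$p1), unclass(net$layers$p2)),
                         list(bats, bats), bats, list(x = xp))
  obs <- q$coefficients[["x"]]
  # exact two-sided tail by the same doubling convention
  qg <- mean(exact >= obs - 1e-12); ql <- mean(exact <= obs + 1e-12)
  p_exact <- min(1, 2 * min(qg, ql))
  expect_lt(abs(q$p_values[["x"]] - p_exact),
            mc_tolerance(min(qg, ql), 4000) * 2)
  # null mean should also agree
  expect_lt(abs(mean(q$null[, "x"]) - mean(exact)),
            4 * sd(exact) / sqrt(4000))
})

test_that("constrained relabelings never move a bat into a period it missed", {
  bats <- paste0("b", 1:6)
  present <- c("b1", "b3", "b5")
  for (i in 1:50) {
    idx <- proxinet:::constrained_relabeling(bats, present)
    expect_identical(idx[c(2, 4, 6)], c(2L, 4L, 6L))
    expect_setequal(idx[c(1, 3, 5)], c(1L, 3L, 5L))
  }
})

test_that("MRQAP-DSP attributes effects to the right predictor", {
  bats <- paste0("b", 1:12)
  set.seed(31)
  mk <- function(gen) {
    m <- matrix(0, 12, 12, dimnames = list(bats, bats))
    m[lower.tri(m)] <- gen(66)
    m[upper.tri(m)] <- t(m)[upper.tri(m)]
    m
  }
  x1 <- mk(runif); x2 <- mk(runif)
  y <- 3 * x1 + 0 * x2 + mk(function(n) rnorm(n, sd = 0.05))
  diag(y) <- 0
  q <- qap_regression(dyadic_matrix(y, role = "adjusted"),
                      list(x1 = dyadic_matrix(x1, role = "rate"),
                           x2 = dyadic_matrix(x2, role = "rate")),
                      n_perm = 400, seed = 4, mode = "dsp")
  expect_equal(unname(q$coefficients[["x1"]]), 3, tolerance = 0.05)
  expect_lt(q$p_values[["x1"]], 0.01)
  expect_gt(q$p_values[["x2"]], 0.05)
})

test_that("centrality consistency test matches enumeration on a 4-bat toy", {
  bats <- paste0("b", 1:4)
  x <- c(b1 = 1, b2 = 2, b3 = 3, b4 = 4)
  fd <- matrix(c(1, 2, 4, 3,
                 2, 1, 3, 5), 4, 2, dimnames = list(bats, c("n1", "n2")))
  got <- centrality_consistency_test(x, fd, n_perm = 4000, seed = 5)
  exact <- enum_centrality_null(x, fd)
  # the null distribution's center is what the one-tailed p is measured from
  expect_equal(got$centered, got$observed - median(exact), tolerance = 0.15)
  if (got$tail == "greater") {
    q <- mean(exact >= got$observed - 1e-12)
  } else {
    q <- mean(exact <= got$observed + 1e-12)
  }
  expect_lt(abs(got$p_value - q), mc_tolerance(q, 4000))
  # perfect identity between roosting and foraging centrality: slope 1
  fd1 <- matrix(rep(x, 2), 4, 2, dimnames = list(bats, c("n1", "n2")))
  got1 <- centrality_consistency_test(x, fd1, n_perm = 300, seed = 6)
  expect_equal(got1$observed, 1, tolerance = 1e-10)
  expect_equal(got1$p_value, 1 / 301)
})

test_that("Mantel test agrees with the direct formula and with vegan", {
  bats <- paste0("b", 1:6)
  set.seed(41)
  mk <- function() {
    m <- matrix(0, 6, 6, dimnames = list(bats, bats))
    m[lower.tri(m)] <- runif(15)
    m[upper.tri(m)] <- t(m)[upper.tri(m)]
    m
  }
  a <- mk(); b <- mk()
  am <- dyadic_matrix(a, role = "rate"); bm <- dyadic_matrix(b, role = "rate")
  got <- mantel_test(am, bm, n_perm = 999, seed = 7)
  expect_equal(got$observed, cor(a[lower.tri(a)], b[lower.tri(b)]))
  expect_equal(mantel_test(am, am, n_perm = 99, seed = 1)$observed, 1)
  skip_if_not_installed("vegan")
  ref <- vegan::mantel(a, b, permutations = 999)
  expect_equal(got$observed, unname(ref$statistic), tolerance = 1e-10)
  expect_lt(abs(got$p_value - ref$signif), 0.12)
})

test_that("paired day-night QAP bootstraps the mean slope over days", {
  sp <- small_processed()
  rd <- roosting_network(sp$enc, sp$study$stations, "association", "per_day",
                         sp$cfg, bats = sp$bats)
  fs <- foraging_seconds_network(sp$enc, sp$bats, per_night = TRUE,
                                 bouts = sp$bouts, cfg = sp$cfg)
  dn <- daynight_paired_qap(rd, fs, n_perm = 100, n_boot = 2000, seed = 8)
  expect_lte(nrow(dn$per_day), length(rd$periods) - 0)
  expect_equal(dn$mean_slope, mean(dn$per_day$slope))
  expect_lte(dn$ci[1], dn$ci[2])
  # identical per-day slopes collapse the bootstrap CI to a point
  const <- dn; # construct via a degenerate 3-day enumeration instead:
  boot_means <- replicate(500, mean(rep(0.4, 3)[sample.int(3, 3, TRUE)]))
  expect_true(all(boot_means == 0.4))
  # bootstrap distribution on 3 enumerable days (3^3 = 27 equally likely
  # resamples): the MC resampling CDF matches the exact CDF at every atom
  slopes <- c(1, 2, 6)
  exact_means <- apply(expand.grid(1:3, 1:3, 1:3), 1,
                       function(i) mean(slopes[i]))
  set.seed(9)
  mc_means <- replicate(20000, mean(slopes[sample.int(3, 3, TRUE)]))
  for (v in sort(unique(exact_means))) {
    q <- mean(exact_means <= v)
    expect_lt(abs(mean(mc_means <= v) - q), mc_tolerance(q, 20000))
  }
})

test_that("every engine is reproducible under a fixed seed", {
  sp <- small_processed()
  tab <- hourly_coforaging(sp$enc, sp$bouts, sp$cfg)
  expect_identical(differentiation_test(tab, n_perm = 100, seed = 3),
                   differentiation_test(tab, n_perm = 100, seed = 3))
  fn <- foraging_nights_network(sp$enc, sp$bats, sp$cfg)
  kin <- sp$study$truth$kinship
  expect_identical(qap_regression(fn, list(k = kin), n_perm = 50, seed = 4),
                   qap_regression(fn, list(k = kin), n_perm = 50, seed = 4))
  expect_identical(mantel_test(fn, kin, n_perm = 50, seed = 5),
                   mantel_test(fn, kin, n_perm = 50, seed = 5))
})
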