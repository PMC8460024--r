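#' Social-differentiation test via constrained data-stream permutation
#'
#' Tests whether repeated co-foraging occurs among the same pairs more
#' than expected among bats outside the roost at the same time. The
#' observed statistic is the coefficient of variation of per-dyad
#' co-foraging totals (over all dyads of the table's bat universe,
#' zeros included). Each permutation rewrites every marked (night, hour,
#' dyad) record: one member of the dyad is chosen at random and replaced
#' by a uniformly random other bat that was outside the roost in that same
#' night and hour (self-pairing forbidden). Because the records are
#' presence/absence observations being swapped, the rewrite is
#' collision-free: the replacement partner is drawn uniformly among those
#' not already forming that dyad in that hour, so every permutation
#' conserves the number of marked dyad-hours. Records in hours with fewer
#' than 3 bats outside have no randomization freedom; they are kept as-is
#' and counted in the result. Inference is on the raw CV's rank; the
#' result also carries the centered statistic (observed minus null
#' median).
#'
#' @param table an [hourly_coforaging()] table.
#' @param n_perm number of permutations (default 5000).
#' @param seed RNG seed.
#' @return A [perm_result()] (tail = greater) with attribute
#'   `n_frozen_records` (records without randomization freedom).
#' @export
differentiation_test <- function(table, n_perm = 5000, seed = 1L) {
  recs <- table$records
  if (nrow(recs) < 2) stop("need at least 2 marked dyad-hours")
  bats <- table$bats
  n <- length(bats)
  nd <- n * (n - 1) / 2

  key_nh <- paste(recs$night, recs$hour)
  out_key <- paste(table$outside$night, table$outside$hour)
  groups <- unique(key_nh)
  g_of <- match(key_nh, groups)
  cand <- lapply(groups, function(g) {
    match(table$outside$bat[out_key == g], bats)
  })
  a_idx <- match(recs$bat_a, bats)
  b_idx <- match(recs$bat_b, bats)
  # both members of every record must have been outside that night-hour
  pos_a <- mapply(function(a, g) match(a, cand[[g]]), a_idx, g_of)
  pos_b <- mapply(function(b, g) match(b, cand[[g]]), b_idx, g_of)
  if (any(is.na(pos_a)) || any(is.na(pos_b))) {
    bad <- which(is.na(pos_a) | is.na(pos_b))[1]
    stop("record ", bad, " names a bat not outside in that night-hour")
  }
  len <- lengths(cand)[g_of]
  frozen <- len < 3
  cand_flat <- unlist(cand)
  offset <- cumsum(c(0, lengths(cand)))[g_of]

  dyad_code <- function(i, j) pmin(i, j) * n + pmax(i, j)
  cv_of_codes <- function(codes) {
    cnt <- tabulate(match(codes, unique(codes)))
    s <- sum(cnt); ss <- sum(cnt^2)
    mu <- s / nd
    va <- (ss - s^2 / nd) / (nd - 1)
    sqrt(va) / mu
  }
  obs_cv <- cv_of_codes(dyad_code(a_idx, b_idx))

  ev_by_g <- split(seq_len(nrow(recs)), g_of)
  grp_of <- as.integer(names(ev_by_g))
  set.seed(as.integer(seed))
  R <- nrow(recs)
  null_cv <- numeric(n_perm)
  codes <- integer(R)
  used <- logical(n * n + n + 1)  # dyad-code-indexed scratch, reset per group
  set_codes <- integer(R)
  for (p in seq_len(n_perm)) {
    # optimistic vectorized draw: kept member and a uniform partner among
    # the other outside bats, for every record at once
    pick_a <- stats::runif(R) < 0.5
    kept_all <- ifelse(pick_a, a_idx, b_idx)
    kpos <- ifelse(pick_a, pos_a, pos_b)
    j <- 1L + as.integer(floor(stats::runif(R) * (len - 1L)))
    j <- j + (j >= kpos)
    dy0 <- dyad_code(kept_all, cand_flat[offset + j])
    pos <- 0L
    for (gi in seq_along(ev_by_g)) {
      C <- cand[[grp_of[gi]]]
      m <- length(C)
      k <- 0L
      for (r in ev_by_g[[gi]]) {
        dy <- dy0[r]
        if (used[dy]) {
          # collision: redraw sequentially; rejection sampling is exactly
          # uniform over the unused dyads of the kept member
          kept <- kept_all[r]
          dy <- NA_integer_
          for (try in 1:8) {
            jj <- sample.int(m - 1L, 1L)
            if (jj >= kpos[r]) jj <- jj + 1L
            cd <- dyad_code(kept, C[jj])
            if (!used[cd]) {
              dy <- cd
              break
            }
          }
          if (is.na(dy)) {
            cds <- dyad_code(kept, C[-kpos[r]])
            free <- cds[!used[cds]]
            dy <- if (length(free)) free[sample.int(length(free), 1L)] else
              dyad_code(a_idx[r], b_idx[r])
          }
        }
        if (!used[dy]) {
          k <- k + 1L
          set_codes[k] <- dy
          used[dy] <- TRUE
        }
        pos <- pos + 1L
        codes[pos] <- dy
      }
      used[set_codes[seq_len(k)]] <- FALSE
    }
    null_cv[p] <- cv_of_codes(codes)
  }
  res <- perm_result(obs_cv, null_cv, tail = "greater", seed = seed,
                     statistic = "social differentiation (CV)")
  attr(res, "n_frozen_records") <- sum(frozen)
  res
}

#' Within-hour identity permutations of a co-feeding stream
#'
#' The null model for captive co-feeding: within each observation hour,
#' the identities of the bats seen that hour are relabeled by a uniform
#' random permutation (so per-hour marginal participation is conserved),
#' and the dyadic co-feeding count matrix is rebuilt.
#'
#' @param events co-feeding events (night, hour, bat_a, bat_b).
#' @param presence per-hour presence (night, hour, bat).
#' @param bats bat universe for the count matrices.
#' @param n_perm number of permutations (default 5000).
#' @param seed RNG seed.
#' @return A `bats x bats x n_perm` array of null count matrices.
#' @export
within_hour_identity_permutation <- function(events, presence, bats = NULL,
                                             n_perm = 5000, seed = 1L) {
  if (is.null(bats)) bats <- sort(unique(c(presence$bat, events$bat_a, events$bat_b)))
  n <- length(bats)
  key_ev <- paste(events$night, events$hour)
  key_pr <- paste(presence$night, presence$hour)
  groups <- unique(key_ev)
  g_of <- match(key_ev, groups)
  seen <- lapply(groups, function(g) match(presence$bat[key_pr == g], bats))
  a_idx <- match(events$bat_a, bats)
  b_idx <- match(events$bat_b, bats)
  for (r in seq_len(nrow(events))) {
    g <- g_of[r]
    if (!(a_idx[r] %in% seen[[g]]) || !(b_idx[r] %in% seen[[g]])) {
      stop("event ", r, " names a bat not recorded as present in that hour")
    }
  }
  set.seed(as.integer(seed))
  out <- array(0, dim = c(n, n, n_perm), dimnames = list(bats, bats, NULL))
  ev_by_g <- split(seq_along(g_of), g_of)
  for (p in seq_len(n_perm)) {
    m <- matrix(0, n, n)
    for (gi in seq_along(groups)) {
      S <- seen[[gi]]
      sigma <- S[sample.int(length(S))]
      map <- integer(n); map[S] <- sigma
      rows <- ev_by_g[[as.character(gi)]]
      na <- map[a_idx[rows]]; nb <- map[b_idx[rows]]
      lo <- pmin(na, nb); hi <- pmax(na, nb)
      for (k in seq_along(lo)) {
        m[lo[k], hi[k]] <- m[lo[k], hi[k]] + 1
      }
    }
    out[, , p] <- m + t(m)
  }
  out
}

#' Double permutation test of a dyadic rate against a predictor
#'
#' Stage 1 adjusts each dyad's co-feeding count by subtracting its median
#' expected count under [within_hour_identity_permutation()] (controlling
#' for overlap in individual feeding times). Stage 2 correlates the
#' adjusted matrix with the predictor and draws significance from
#' node-label permutations of the adjusted matrix.
#'
#' @param events co-feeding events (night, hour, bat_a, bat_b).
#' @param presence per-hour presence table.
#' @param predictor a [dyadic_matrix()] on the same bat universe.
#' @param n_perm permutations for both stages (default 5000).
#' @param seed RNG seed.
#' @param tail tail for stage 2 (default `"greater"`).
#' @return list with `adjusted` ([dyadic_matrix()], role `adjusted`) and
#'   `result` (a [perm_result()] for the matrix correlation).
#' @export
double_permutation_test <- function(events, presence, predictor,
                                    n_perm = 5000, seed = 1L,
                                    tail = "greater") {
  bats <- rownames(predictor)
  pv <- dyad_values(unclass(predictor))
  if (stats::sd(pv, na.rm = TRUE) == 0) stop("predictor is constant; correlation undefined")
  obs <- unclass(cofeeding_network(events, bats))
  null_arr <- within_hour_identity_permutation(events, presence, bats = bats,
                                               n_perm = n_perm,
                                               seed = derive_seed(seed, "stage1"))
  med <- apply(null_arr, c(1, 2), stats::median)
  adj <- obs - med
  diag(adj) <- 0
  adjusted <- dyadic_matrix(adj, bats = bats, role = "adjusted")

  av <- dyad_values(unclass(adjusted))
  ok <- !is.na(av) & !is.na(pv)
  obs_r <- safe_cor(av[ok], pv[ok])
  if (is.na(obs_r)) stop("adjusted matrix is constant; correlation undefined")
  set.seed(derive_seed(seed, "stage2"))
  null_r <- numeric(n_perm)
  for (p in seq_len(n_perm)) {
    idx <- constrained_relabeling(bats, bats)
    rv <- dyad_values(relabel_matrix(adjusted, idx))
    ok2 <- !is.na(rv) & !is.na(pv)
    null_r[p] <- safe_cor(rv[ok2], pv[ok2])
  }
  list(adjusted = adjusted,
       result = perm_result(obs_r, null_r, tail = tail, seed = seed,
                            statistic = "matrix correlation (adjusted)"))
}

#' Mantel test between two dyadic matrices
#'
#' Pearson correlation of the vectorized non-missing dyads, with the null
#' from whole-matrix node-label permutations of the second matrix. Shares
#' the suite's seeding and p-value conventions.
#'
#' @param a,b [dyadic_matrix()] objects on the same bat universe.
#' @param n_perm number of permutations (default 5000).
#' @param seed RNG seed.
#' @param tail tail convention (default `"greater"`, the classical Mantel
#'   alternative of positive matrix association).
#' @return A [perm_result()].
#' @export
mantel_test <- function(a, b, n_perm = 5000, seed = 1L, tail = "greater") {
  stopifnot(identical(rownames(a), rownames(b)))
  bats <- rownames(a)
  va <- dyad_values(unclass(a)); vb <- dyad_values(unclass(b))
  ok <- !is.na(va) & !is.na(vb)
  if (stats::sd(va[ok]) == 0 || stats::sd(vb[ok]) == 0) {
    stop("constant matrix; Mantel correlation undefined")
  }
  obs_r <- safe_cor(va[ok], vb[ok])
  set.seed(as.integer(seed))
  null_r <- numeric(n_perm)
  for (p in seq_len(n_perm)) {
    idx <- constrained_relabeling(bats, bats)
    vbp <- dyad_values(relabel_matrix(b, idx))
    ok2 <- !is.na(va) & !is.na(vbp)
    null_r[p] <- safe_cor(va[ok2], vbp[ok2])
  }
  perm_result(obs_r, null_r, tail = tail, seed = seed,
              statistic = "Mantel r")
}
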