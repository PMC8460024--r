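# Independent enumeration oracles for the permutation engines. These
# enumerate the exact null distribution on tiny instances by brute force
# and stay independent of the package's Monte-Carlo code paths.

# All constrained collision-free rewrites of a co-foraging table. Records
# are processed hour by hour (table order); each chooses a kept member
# (probability 1/2 each) and a replacement partner uniform among the
# outside bats whose dyad with the kept member is not already marked in
# that hour; if none is free the record keeps its original dyad. Returns
# the exact probability that the null CV >= the observed CV.
enum_differentiation_tail <- function(table) {
  recs <- table$records
  bats <- table$bats
  n <- length(bats)
  nd <- n * (n - 1) / 2
  out_key <- paste(table$outside$night, table$outside$hour)
  g <- paste(recs$night, recs$hour)
  ord <- order(match(g, unique(g)))  # groups in first-seen order
  recs <- recs[ord, , drop = FALSE]
  g <- g[ord]

  cv_of_dyads <- function(dy) {
    cnt <- table(dy)
    v <- c(as.vector(cnt), rep(0, nd - length(cnt)))
    stats::sd(v) / mean(v)
  }
  obs <- cv_of_dyads(paste(pmin(recs$bat_a, recs$bat_b),
                           pmax(recs$bat_a, recs$bat_b)))

  tail_p <- 0
  recurse <- function(r, dyads, used_by_g, prob) {
    if (r > nrow(recs)) {
      if (cv_of_dyads(dyads) >= obs - 1e-12) tail_p <<- tail_p + prob
      return(invisible())
    }
    cand <- table$outside$bat[out_key == g[r]]
    for (keep in c(recs$bat_a[r], recs$bat_b[r])) {
      pool <- setdiff(cand, keep)
      dys <- paste(pmin(keep, pool), pmax(keep, pool))
      free <- dys[!(dys %in% used_by_g[[g[r]]])]
      if (length(free) == 0) {
        free <- paste(pmin(recs$bat_a[r], recs$bat_b[r]),
                      pmax(recs$bat_a[r], recs$bat_b[r]))
      }
      for (dy in free) {
        ub <- used_by_g
        ub[[g[r]]] <- c(ub[[g[r]]], dy)
        recurse(r + 1, c(dyads, dy), ub, prob * 0.5 / length(free))
      }
    }
  }
  ub0 <- stats::setNames(vector("list", length(unique(g))), unique(g))
  recurse(1, character(), ub0, 1)
  list(observed = obs, tail = tail_p)
}

# all permutations of 1..n (n small)
all_perms <- function(n) {
  if (n == 1) return(matrix(1, 1, 1))
  sub <- all_perms(n - 1)
  out <- NULL
  for (i in seq_len(n)) {
    out <- rbind(out, cbind(i, sub + (sub >= i)))
  }
  unname(out)
}

# OLS slope over lower-triangle complete dyads (independent of the package)
ols_beta <- function(y_mat, x_mats) {
  y <- y_mat[lower.tri(y_mat)]
  X <- sapply(x_mats, function(m) m[lower.tri(m)])
  if (is.null(dim(X))) X <- matrix(X, ncol = length(x_mats))
  ok <- stats::complete.cases(cbind(y, X))
  fit <- stats::lm.fit(cbind(1, X[ok, , drop = FALSE]), y[ok])
  fit$coefficients[-1]
}

# exact null distribution of the QAP beta under all tuples of per-period
# relabelings constrained to the present bats
enum_qap_null <- function(layers, presence, bats, x_mats) {
  per_period <- lapply(seq_along(layers), function(k) {
    pos <- which(bats %in% presence[[k]])
    perms <- all_perms(length(pos))
    lapply(seq_len(nrow(perms)), function(i) {
      idx <- seq_along(bats)
      idx[pos] <- pos[perms[i, ]]
      idx
    })
  })
  combos <- expand.grid(lapply(per_period, seq_along))
  betas <- numeric(nrow(combos))
  for (i in seq_len(nrow(combos))) {
    tot <- matrix(0, length(bats), length(bats))
    nas <- matrix(TRUE, length(bats), length(bats))
    for (k in seq_along(layers)) {
      idx <- per_period[[k]][[combos[i, k]]]
      lay <- layers[[k]][idx, idx]
      add <- !is.na(lay)
      tot[add] <- tot[add] + lay[add]
      nas <- nas & !add
    }
    tot[nas] <- NA
    diag(tot) <- 0
    betas[i] <- ols_beta(tot, x_mats)[1]
  }
  betas
}

# exact null slopes of the centrality test: all tuples of within-night
# permutations of the non-missing foraging centralities
enum_centrality_null <- function(x_bat, forage_degree) {
  slope <- function(fd) {
    y <- as.vector(fd)
    x <- rep(x_bat, times = ncol(fd))
    ok <- !is.na(y) & !is.na(x)
    stats::cov(x[ok], y[ok]) / stats::var(x[ok])
  }
  per_night <- lapply(seq_len(ncol(forage_degree)), function(j) {
    have <- which(!is.na(forage_degree[, j]))
    perms <- all_perms(length(have))
    lapply(seq_len(nrow(perms)), function(i) list(have = have, ord = perms[i, ]))
  })
  combos <- expand.grid(lapply(per_night, seq_along))
  vapply(seq_len(nrow(combos)), function(i) {
    fd <- forage_degree
    for (j in seq_len(ncol(fd))) {
      pp <- per_night[[j]][[combos[i, j]]]
      fd[pp$have, j] <- forage_degree[pp$have[pp$ord], j]
    }
    slope(fd)
  }, numeric(1))
}

# exact expected null co-feeding counts under within-hour relabeling
enum_within_hour_expected <- function(events, presence, bats) {
  n <- length(bats)
  key_ev <- paste(events$night, events$hour)
  key_pr <- paste(presence$night, presence$hour)
  expected <- matrix(0, n, n, dimnames = list(bats, bats))
  for (g in unique(key_ev)) {
    seen <- presence$bat[key_pr == g]
    perms <- all_perms(length(seen))
    evs <- events[key_ev == g, , drop = FALSE]
    for (i in seq_len(nrow(perms))) {
      map <- stats::setNames(seen[perms[i, ]], seen)
      for (r in seq_len(nrow(evs))) {
        a <- map[[evs$bat_a[r]]]; b <- map[[evs$bat_b[r]]]
        expected[a, b] <- expected[a, b] + 1 / nrow(perms)
        expected[b, a] <- expected[b, a] + 1 / nrow(perms)
      }
    }
  }
  expected
}

# MC-vs-enumeration comparison bound: 3 binomial SEs plus the add-one bias
mc_tolerance <- function(q, n_perm) {
  3 * sqrt(q * (1 - q) / n_perm) + 2 / n_perm
}
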