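# vectorize a set of matrices over the lower triangle and fit OLS on
# complete dyads; returns coefficients named after the predictors
fit_dyadic_ols <- function(y_mat, x_mats) {
  y <- dyad_values(y_mat)
  X <- vapply(x_mats, function(m) dyad_values(unclass(m)), numeric(length(y)))
  if (is.null(dim(X))) X <- matrix(X, ncol = length(x_mats))
  ok <- stats::complete.cases(cbind(y, X))
  if (sum(ok) == 0) stop("no non-missing dyads shared by response and predictors")
  Xf <- cbind(`(Intercept)` = 1, X[ok, , drop = FALSE])
  colnames(Xf) <- c("(Intercept)", names(x_mats))
  qrx <- qr(Xf)
  if (qrx$rank < ncol(Xf)) stop("collinear predictors: design matrix is rank deficient")
  stats::setNames(qr.coef(qrx, y[ok]), colnames(Xf))
}

as_predictor_list <- function(predictors) {
  if (inherits(predictors, "dyadic_matrix")) {
    predictors <- stats::setNames(list(predictors), "predictor")
  }
  if (is.null(names(predictors)) || any(names(predictors) == "")) {
    names(predictors) <- paste0("predictor", seq_along(predictors))
  }
  predictors
}

#' QAP / MRQAP network regression with constrained node-label permutations
#'
#' Fits ordinary least squares on the vectorized non-missing dyads of the
#' response against one or more predictor matrices (plus an optional
#' bout-overlap covariate), then draws the null by permuting the response.
#'
#' With `mode = "node_label_constrained"` (the default) each permutation
#' draws one independent node relabeling per period, uniform over the bats
#' present in that period (absent bats are never moved), applies it to
#' that period's response layer, re-aggregates and refits. This preserves
#' the daily/nightly network structure and the presence/absence of bats in
#' each period. A plain (unstratified) response is treated as a single
#' period with all bats present.
#'
#' With `mode = "dsp"` (aggregate responses, 2+ regressors) significance
#' uses Dekker-style double semi-partialling: each focal predictor is
#' residualized on the remaining regressors, the residual matrix is
#' node-label permuted, and the model is refit with the permuted residuals
#' in place of the focal predictor.
#'
#' @param response a [dyadic_matrix()] or [day_stratified_network()].
#' @param predictors a [dyadic_matrix()] or named list of them.
#' @param covariate optional [dyadic_matrix()] covariate (e.g., bout
#'   overlap), appended to the regressors.
#' @param n_perm number of permutations (default 5000).
#' @param seed RNG seed.
#' @param mode `"node_label_constrained"` or `"dsp"`.
#' @param tail tail convention per predictor (default two-sided).
#' @return A `qap_result`: `coefficients` (including intercept), `null`
#'   (matrix of null coefficient draws, one column per regressor),
#'   `p_values`, `n_perm`, `seed`, `mode`, `tail`, `n_dyads`.
#' @export
qap_regression <- function(response, predictors, covariate = NULL,
                           n_perm = 5000, seed = 1L,
                           mode = c("node_label_constrained", "dsp"),
                           tail = "two_sided") {
  mode <- match.arg(mode)
  predictors <- as_predictor_list(predictors)
  if (!is.null(covariate)) predictors <- c(predictors, list(bout_overlap = covariate))
  stratified <- inherits(response, "day_stratified_network")
  agg <- if (stratified) aggregate_layers(response) else response
  bats <- rownames(agg)
  for (x in predictors) {
    if (!identical(rownames(x), bats)) stop("predictor bat universe differs from response")
  }
  coefs <- fit_dyadic_ols(unclass(agg), predictors)
  terms <- names(predictors)
  n_ok <- sum(stats::complete.cases(
    cbind(dyad_values(unclass(agg)),
          vapply(predictors, function(m) dyad_values(unclass(m)),
                 numeric(length(dyad_values(unclass(agg))))))))

  set.seed(as.integer(seed))
  null <- matrix(NA_real_, n_perm, length(terms), dimnames = list(NULL, terms))
  if (mode == "node_label_constrained") {
    layers <- if (stratified) response$layers else list(all = agg)
    presence <- if (stratified) response$presence else list(all = bats)
    for (p in seq_len(n_perm)) {
      perm_layers <- lapply(names(layers), function(nm) {
        relabel_matrix(layers[[nm]], constrained_relabeling(bats, presence[[nm]]))
      })
      arr <- simplify2array(perm_layers)
      tot <- if (length(perm_layers) == 1) perm_layers[[1]] else {
        s <- rowSums(arr, dims = 2, na.rm = TRUE)
        s[rowSums(!is.na(arr), dims = 2) == 0] <- NA
        s
      }
      diag(tot) <- 0
      b <- tryCatch(fit_dyadic_ols(tot, predictors), error = function(e) NULL)
      if (!is.null(b)) null[p, ] <- b[terms]
    }
  } else {
    if (length(predictors) < 2) {
      stop("dsp mode needs at least 2 regressors (predictors + covariate)")
    }
    for (j in seq_along(terms)) {
      others <- predictors[-j]
      bfit <- fit_dyadic_ols(unclass(predictors[[j]]), others)
      # residual matrix of the focal predictor given the others
      e <- unclass(predictors[[j]])
      pred <- matrix(bfit[1], nrow(e), ncol(e))
      for (k in seq_along(others)) {
        pred <- pred + bfit[k + 1] * unclass(others[[k]])
      }
      e <- e - pred
      diag(e) <- 0
      for (p in seq_len(n_perm)) {
        ep <- relabel_matrix(e, constrained_relabeling(bats, bats))
        xs <- c(others, list(focal = dyadic_matrix(ep, bats = bats, role = "adjusted")))
        b <- tryCatch(fit_dyadic_ols(unclass(agg), xs), error = function(e2) NULL)
        if (!is.null(b)) null[p, j] <- b[["focal"]]
      }
    }
  }
  pvals <- vapply(terms, function(tm) {
    p_value(null[, tm], coefs[[tm]], tail)
  }, numeric(1))
  structure(list(coefficients = coefs, null = null, p_values = pvals,
                 n_perm = n_perm, seed = seed, mode = mode, tail = tail,
                 n_dyads = n_ok, n_bats = length(bats)),
            class = "qap_result")
}

#' @export
print.qap_result <- function(x, ...) {
  cat("<qap_result> mode =", x$mode, "|", x$n_perm, "permutations |",
      x$n_dyads, "dyads,", x$n_bats, "bats\n")
  tm <- setdiff(names(x$coefficients), "(Intercept)")
  for (t in tm) {
    cat(sprintf("  %-18s beta = %10.4g   p (%s) = %.4g\n",
                t, x$coefficients[[t]], x$tail, x$p_values[[t]]))
  }
  invisible(x)
}

#' Paired day-to-night QAP with bootstrapped mean slope
#'
#' For each day, regresses that night's foraging network on the preceding
#' day's roosting network among the bats present in both periods
#' (node-label permutations among those bats give the per-day p); then
#' bootstraps the mean of the per-day slopes (days resampled with
#' replacement) for an overall paired day-night effect.
#'
#' @param roosting a [day_stratified_network()] of per-day roosting layers.
#' @param foraging a [day_stratified_network()] of per-night foraging
#'   layers; night `d + 1` is paired with day `d`.
#' @param n_perm permutations per day (default 1000).
#' @param n_boot bootstrap draws for the mean slope (default 5000).
#' @param seed RNG seed.
#' @param min_shared_bats minimum shared bats to analyse a day (default 3).
#' @return list: `per_day` (data.frame day, slope, p, n_bats), `skipped`
#'   (day labels with too few shared bats), `mean_slope`, `ci` (percentile
#'   95% CI), `boot_means`.
#' @export
daynight_paired_qap <- function(roosting, foraging, n_perm = 1000,
                                n_boot = 5000, seed = 1L,
                                min_shared_bats = 3) {
  nd <- length(roosting$periods)
  nn <- length(foraging$periods)
  pairs <- seq_len(min(nd, nn - 1))
  if (length(pairs) < 2) stop("need at least 2 paired day-night layers")
  bats <- roosting$bats
  rows <- list(); skipped <- character()
  for (d in pairs) {
    day_p <- roosting$periods[d]
    night_p <- foraging$periods[d + 1]
    shared <- intersect(roosting$presence[[day_p]], foraging$presence[[night_p]])
    if (length(shared) < min_shared_bats) {
      skipped <- c(skipped, day_p)
      next
    }
    x <- unclass(roosting$layers[[day_p]])[shared, shared]
    y <- unclass(foraging$layers[[night_p]])[shared, shared]
    xs <- stats::setNames(list(dyadic_matrix(x, bats = shared, role = "rate")),
                          "roosting")
    b <- tryCatch(fit_dyadic_ols(y, xs), error = function(e) NULL)
    if (is.null(b)) {
      skipped <- c(skipped, day_p)
      next
    }
    set.seed(derive_seed(seed, day_p))
    null <- numeric(n_perm)
    for (p in seq_len(n_perm)) {
      yp <- relabel_matrix(y, constrained_relabeling(shared, shared))
      bp <- tryCatch(fit_dyadic_ols(yp, xs), error = function(e) NULL)
      null[p] <- if (is.null(bp)) NA else bp[["roosting"]]
    }
    rows[[length(rows) + 1]] <- data.frame(
      day = day_p, slope = b[["roosting"]],
      p_value = p_value(null, b[["roosting"]], "two_sided"),
      n_bats = length(shared), stringsAsFactors = FALSE)
  }
  per_day <- if (length(rows)) do.call(rbind, rows) else
    data.frame(day = character(), slope = numeric(), p_value = numeric(),
               n_bats = integer(), stringsAsFactors = FALSE)
  if (nrow(per_day) == 0) stop("no day had enough shared bats")
  set.seed(derive_seed(seed, "bootstrap"))
  k <- nrow(per_day)
  boot_means <- vapply(seq_len(n_boot), function(i) {
    mean(per_day$slope[sample.int(k, k, replace = TRUE)])
  }, numeric(1))
  list(per_day = per_day, skipped = skipped,
       mean_slope = mean(per_day$slope),
       ci = stats::quantile(boot_means, c(0.025, 0.975), names = FALSE,
                            type = 7),
       boot_means = boot_means)
}

#' Consistency of individual centrality between roosting and foraging
#'
#' Tests whether bats with more in-roost partners also meet more partners
#' while foraging. The observed statistic is the pooled OLS slope of
#' per-night foraging degree on each bat's mean daytime roosting degree;
#' the null permutes foraging centralities among bats within each night,
#' which controls for bats simply being sampled on more nights. The
#' p-value is one-tailed for the stated alternative and is measured
#' against the null slope distribution itself, whose center is generally
#' not zero (the result's `centered` field reports observed minus null
#' median).
#'
#' @param roost_mean_degree named per-bat mean roosting degree (from
#'   [degree_centrality_profiles()]).
#' @param forage_degree bats-by-nights matrix of foraging degree (NA =
#'   missing-if-absent).
#' @param n_perm number of permutations (default 5000).
#' @param seed RNG seed.
#' @param alternative direction of the alternative hypothesis: `"greater"`
#'   (default; in-roost centrality carries over to foraging) or `"less"`.
#' @return A [perm_result()] (statistic = slope); attribute `n_obs` gives
#'   the bat-nights used.
#' @export
centrality_consistency_test <- function(roost_mean_degree, forage_degree,
                                        n_perm = 5000, seed = 1L,
                                        alternative = c("greater", "less")) {
  alternative <- match.arg(alternative)
  bats <- rownames(forage_degree)
  x_bat <- roost_mean_degree[bats]
  slope_of <- function(fd) {
    y <- as.vector(fd)
    x <- rep(x_bat, times = ncol(fd))
    ok <- !is.na(y) & !is.na(x)
    if (sum(ok) < 3 || stats::sd(x[ok]) == 0) return(NA_real_)
    stats::cov(x[ok], y[ok]) / stats::var(x[ok])
  }
  obs <- slope_of(forage_degree)
  if (is.na(obs)) stop("not enough non-missing centralities to fit a slope")
  set.seed(as.integer(seed))
  null <- numeric(n_perm)
  fd <- forage_degree
  for (p in seq_len(n_perm)) {
    fp <- fd
    for (j in seq_len(ncol(fd))) {
      have <- which(!is.na(fd[, j]))
      if (length(have) > 1) fp[have, j] <- fd[have[sample.int(length(have))], j]
    }
    null[p] <- slope_of(fp)
  }
  res <- perm_result(obs, null, tail = alternative, seed = seed,
                     statistic = "centrality slope")
  attr(res, "n_obs") <- sum(!is.na(forage_degree) & !is.na(x_bat[row(forage_degree)]))
  res
}
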