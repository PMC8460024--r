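#' Permutation p-value with the add-one convention
#'
#' `p = (1 + #tail exceedances) / (1 + n_perm)`, so p = 0 is impossible and
#' the smallest attainable p is `1 / (1 + n_perm)`. The two-sided p doubles
#' the smaller tail, capped at 1. Ties count as exceedances in both tails.
#'
#' @param null_draws numeric vector of null statistics.
#' @param observed observed statistic.
#' @param tail `"greater"`, `"less"`, or `"two_sided"`.
#' @return p-value in `(0, 1]`.
#' @export
p_value <- function(null_draws, observed, tail = c("greater", "less", "two_sided")) {
  tail <- match.arg(tail)
  null_draws <- null_draws[!is.na(null_draws)]
  n <- length(null_draws)
  if (n < 1) stop("need at least one null draw")
  pg <- (1 + sum(null_draws >= observed)) / (1 + n)
  pl <- (1 + sum(null_draws <= observed)) / (1 + n)
  switch(tail,
         greater = pg,
         less = pl,
         two_sided = min(1, 2 * min(pg, pl)))
}

#' Construct a permutation-test result
#'
#' @param observed observed statistic.
#' @param null_draws vector of null statistics (length = `n_perm`).
#' @param tail tail convention used for `p`.
#' @param seed RNG seed the draws were generated under.
#' @param statistic label of the statistic.
#' @return A `perm_result` with `observed`, `null_draws`, `n_perm`, `seed`,
#'   `p_value`, `tail`, and `centered` (observed minus null median).
#' @export
perm_result <- function(observed, null_draws,
                        tail = c("greater", "less", "two_sided"),
                        seed = NA_integer_, statistic = "statistic") {
  tail <- match.arg(tail)
  structure(list(observed = observed, null_draws = null_draws,
                 n_perm = length(null_draws), seed = seed,
                 p_value = p_value(null_draws, observed, tail), tail = tail,
                 centered = observed - stats::median(null_draws, na.rm = TRUE),
                 statistic = statistic),
            class = "perm_result")
}

#' @export
print.perm_result <- function(x, ...) {
  cat(sprintf("<perm_result> %s = %.4g | centered = %.4g | p (%s) = %.4g | %d permutations\n",
              x$statistic, x$observed, x$centered, x$tail, x$p_value, x$n_perm))
  invisible(x)
}

# a node relabeling constrained to `present`: integer permutation of
# seq_along(bats) that permutes positions of present bats uniformly and
# fixes everything else
constrained_relabeling <- function(bats, present) {
  idx <- seq_along(bats)
  pos <- which(bats %in% present)
  if (length(pos) > 1) idx[pos] <- pos[sample.int(length(pos))]
  idx
}

relabel_matrix <- function(m, idx) {
  out <- unclass(m)[idx, idx, drop = FALSE]
  dimnames(out) <- dimnames(m)
  out
}

#' Coefficient of variation of dyadic rates (social differentiation)
#'
#' Sample standard deviation over mean; increases when some pairs have
#' many more repeated encounters than others, zero when all dyads are
#' equal. Undefined for an all-zero (zero-mean) vector, which raises a
#' condition of class `proxinet_degenerate`.
#'
#' @param values numeric vector of dyadic counts or rates (NA dropped).
#' @return The coefficient of variation.
#' @export
cv_statistic <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) < 2) stop("need at least 2 non-missing dyads")
  m <- mean(values)
  if (m <= 0) {
    stop(structure(class = c("proxinet_degenerate", "error", "condition"),
                   list(message = "coefficient of variation undefined: mean is zero",
                        call = sys.call(-1))))
  }
  stats::sd(values) / m
}

#' Unadjusted repeatability (intraclass correlation coefficient)
#'
#' One-way ANOVA variance components: `ICC = sigma2_b / (sigma2_b +
#' sigma2_w)` with the between-group component estimated by the
#' method of moments (Searle's n0 for unbalanced designs) and truncated at
#' zero, so an ICC of exactly 0 is attainable.
#'
#' @param values numeric vector of repeated measurements.
#' @param group grouping factor (individual identity).
#' @return An `icc_result`: `icc`, `sigma2_between`, `sigma2_within`,
#'   `n_groups`, `group_sizes`.
#' @export
icc_unadjusted <- function(values, group) {
  ok <- !is.na(values) & !is.na(group)
  values <- values[ok]
  group <- factor(group[ok])
  group <- droplevels(group)
  ni <- as.vector(table(group))
  k <- length(ni)
  N <- sum(ni)
  if (k < 2) stop("ICC undefined with fewer than 2 groups")
  if (all(ni < 2)) stop("ICC undefined when every group is a singleton")
  gm <- mean(values)
  means <- tapply(values, group, mean)
  ssb <- sum(ni * (means - gm)^2)
  ssw <- sum((values - means[group])^2)
  msb <- ssb / (k - 1)
  msw <- ssw / (N - k)
  n0 <- (N - sum(ni^2) / N) / (k - 1)
  s2b <- max(0, (msb - msw) / n0)
  s2w <- msw
  icc <- if (s2b + s2w <= 0) NaN else s2b / (s2b + s2w)
  structure(list(icc = icc, sigma2_between = s2b, sigma2_within = s2w,
                 n_groups = k, group_sizes = ni),
            class = "icc_result")
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf("<icc_result> ICC = %.3f (sigma2_b = %.3g, sigma2_w = %.3g, %d groups)\n",
              x$icc, x$sigma2_between, x$sigma2_within, x$n_groups))
  invisible(x)
}
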