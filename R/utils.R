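#' @keywords internal
"_PACKAGE"

#' Derive a named sub-stream seed from a master seed
#'
#' All stochastic stages derive their own seed deterministically from one
#' master seed plus a stage label, so stages are individually reproducible
#' and never share an RNG stream.
#'
#' @param master integer master seed.
#' @param label character stage label.
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(master, label) {
  stopifnot(is.numeric(master), length(master) == 1L, is.character(label))
  m <- 2147483647  # 2^31 - 1, Mersenne prime; keeps seeds valid R integers
  h <- as.numeric(master) %% m
  for (cc in utf8ToInt(label)) {
    h <- (h * 131 + cc) %% m
  }
  as.integer(h)
}

with_seed <- function(seed, expr) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  expr
}

#' Study calendar of alternating nights and days
#'
#' Time is integer seconds from the study epoch, defined as the first sunset.
#' Night `i` is the half-open interval `[(i-1)*86400, (i-1)*86400 + night_s)`
#' and day `i` is the remainder of that 24-h cycle. Defaults give 12-h nights
#' and days; real sunset/sunrise offsets can be supplied via `night_s`/`day_s`.
#'
#' @param n_nights number of nights in the study (default 9).
#' @param night_s night length in seconds (default 43200).
#' @param day_s day length in seconds (default 43200).
#' @return A `study_calendar` object.
#' @export
study_calendar <- function(n_nights = 9, night_s = 43200, day_s = 43200) {
  stopifnot(n_nights >= 1, night_s > 0, day_s > 0)
  structure(
    list(n_nights = as.integer(n_nights), night_s = night_s, day_s = day_s,
         cycle_s = night_s + day_s, end_s = n_nights * (night_s + day_s)),
    class = "study_calendar"
  )
}

night_bounds <- function(cal, i) {
  s <- (i - 1) * cal$cycle_s
  c(start = s, end = s + cal$night_s)
}

day_bounds <- function(cal, i) {
  s <- (i - 1) * cal$cycle_s + cal$night_s
  c(start = s, end = i * cal$cycle_s)
}

#' Which night (if any) a time falls in
#' @param cal a [study_calendar()].
#' @param t numeric vector of seconds from epoch.
#' @return Integer night index, or `NA` for daytime / out-of-window times.
#' @export
night_of <- function(cal, t) {
  idx <- floor(t / cal$cycle_s) + 1
  within <- t - (idx - 1) * cal$cycle_s
  out <- ifelse(within >= 0 & within < cal$night_s & idx >= 1 & idx <= cal$n_nights,
                idx, NA_integer_)
  as.integer(out)
}

#' Which day (if any) a time falls in
#' @inheritParams night_of
#' @return Integer day index, or `NA` for nighttime / out-of-window times.
#' @export
day_of <- function(cal, t) {
  idx <- floor(t / cal$cycle_s) + 1
  within <- t - (idx - 1) * cal$cycle_s
  out <- ifelse(within >= cal$night_s & within < cal$cycle_s & idx >= 1 & idx <= cal$n_nights,
                idx, NA_integer_)
  as.integer(out)
}

hour_of <- function(t) as.integer(floor(t / 3600))

# canonical dyad ordering: bat_a < bat_b lexicographically
order_dyad <- function(a, b) {
  swap <- a > b
  tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
  list(bat_a = a, bat_b = b)
}

dyad_key <- function(a, b) {
  d <- order_dyad(a, b)
  paste(d$bat_a, d$bat_b, sep = "|")
}

all_dyads <- function(bats) {
  bats <- sort(bats)
  if (length(bats) < 2) {
    return(data.frame(bat_a = character(), bat_b = character(),
                      stringsAsFactors = FALSE))
  }
  idx <- utils::combn(length(bats), 2)
  data.frame(bat_a = bats[idx[1, ]], bat_b = bats[idx[2, ]],
             stringsAsFactors = FALSE)
}

# total pairwise interval overlap: sum over rows of max(0, min(e1,e2)-max(s1,s2))
interval_overlap <- function(s1, e1, s2, e2) {
  sum(pmax(0, pmin(e1, e2) - pmax(s1, s2)))
}

# merge possibly-overlapping intervals into a disjoint union
merge_intervals <- function(start, end) {
  if (length(start) == 0) {
    return(data.frame(start = numeric(), end = numeric()))
  }
  o <- order(start, end)
  start <- start[o]; end <- end[o]
  ms <- start[1]; me <- end[1]
  outs <- numeric(); oute <- numeric()
  for (i in seq_along(start)[-1]) {
    if (start[i] <= me) {
      me <- max(me, end[i])
    } else {
      outs <- c(outs, ms); oute <- c(oute, me)
      ms <- start[i]; me <- end[i]
    }
  }
  data.frame(start = c(outs, ms), end = c(oute, me))
}

# overlap seconds between two sets of disjoint intervals
intervals_intersect_length <- function(a, b) {
  if (nrow(a) == 0 || nrow(b) == 0) return(0)
  tot <- 0
  for (i in seq_len(nrow(a))) {
    tot <- tot + sum(pmax(0, pmin(a$end[i], b$end) - pmax(a$start[i], b$start)))
  }
  tot
}

# Pearson correlation that returns NA (no warning) on degenerate input
safe_cor <- function(x, y) {
  if (length(x) < 3 || stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y)
}
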