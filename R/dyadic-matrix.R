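#' Symmetric dyadic matrix with a role tag and structural missingness
#'
#' The basic container for bat-by-bat quantities: association rates,
#' foraging-encounter seconds, nights-with-encounter counts, kinship,
#' bout overlap, or permutation-adjusted rates. The matrix is symmetric
#' with a zero diagonal; `NA` marks dyads that are structurally
#' unobservable (e.g., never co-present), which is distinct from an
#' observed zero.
#'
#' @param values square numeric matrix (or data that can be coerced to one);
#'   only the lower triangle is consulted, the matrix is symmetrized from it.
#' @param bats character vector of bat ids (defaults to rownames).
#' @param role one of `"rate"`, `"seconds"`, `"count"`, `"kinship"`,
#'   `"overlap"`, `"adjusted"`. All roles except `"adjusted"` require
#'   non-negative values.
#' @return A `dyadic_matrix` object (a numeric matrix with attributes).
#' @export
dyadic_matrix <- function(values, bats = rownames(values),
                          role = c("rate", "seconds", "count", "kinship",
                                   "overlap", "adjusted")) {
  role <- match.arg(role)
  values <- as.matrix(values)
  n <- nrow(values)
  if (ncol(values) != n) stop("dyadic matrix must be square")
  if (is.null(bats)) bats <- paste0("bat", seq_len(n))
  if (length(bats) != n) stop("length(bats) must match matrix dimension")
  # symmetrize from the lower triangle, propagate NA to both triangles
  lower <- values
  lower[upper.tri(lower)] <- t(values)[upper.tri(values)]
  m <- lower
  m[upper.tri(m)] <- t(m)[upper.tri(m)]
  diag(m) <- 0
  if (role != "adjusted" && any(m < 0, na.rm = TRUE)) {
    stop("negative values not allowed for role '", role, "'")
  }
  if (role == "kinship" && any(m > 1, na.rm = TRUE)) {
    stop("kinship values must lie in [0, 1]")
  }
  dimnames(m) <- list(bats, bats)
  structure(m, class = c("dyadic_matrix", "matrix", "array"), role = role)
}

#' @export
print.dyadic_matrix <- function(x, ...) {
  cat("<dyadic_matrix> role =", attr(x, "role"),
      "|", nrow(x), "bats,", sum(is.na(x[lower.tri(x)])), "missing dyads\n")
  print(unclass(x)[seq_len(min(6, nrow(x))), seq_len(min(6, ncol(x))), drop = FALSE])
  invisible(x)
}

dm_role <- function(x) attr(x, "role")

#' Long-form dyad table of a dyadic matrix
#'
#' @param x a [dyadic_matrix()].
#' @param drop_missing drop structurally missing (`NA`) dyads.
#' @return data.frame with columns `bat_a`, `bat_b` (bat_a < bat_b), `value`.
#' @export
dyad_table <- function(x, drop_missing = FALSE) {
  bats <- rownames(x)
  idx <- which(lower.tri(x), arr.ind = TRUE)
  out <- data.frame(bat_a = bats[idx[, 2]], bat_b = bats[idx[, 1]],
                    value = x[idx], stringsAsFactors = FALSE)
  o <- order_dyad(out$bat_a, out$bat_b)
  out$bat_a <- o$bat_a; out$bat_b <- o$bat_b
  out <- out[order(out$bat_a, out$bat_b), , drop = FALSE]
  rownames(out) <- NULL
  if (drop_missing) out <- out[!is.na(out$value), , drop = FALSE]
  out
}

# vectorized lower triangle (includes NA)
dyad_values <- function(x) x[lower.tri(x)]

# build a dyadic matrix from a long-form table (missing dyads -> fill)
dyadic_from_table <- function(tab, bats, role, fill = 0) {
  m <- matrix(fill, length(bats), length(bats), dimnames = list(bats, bats))
  if (nrow(tab) > 0) {
    o <- order_dyad(as.character(tab$bat_a), as.character(tab$bat_b))
    m[cbind(o$bat_a, o$bat_b)] <- tab$value
    m[cbind(o$bat_b, o$bat_a)] <- tab$value
  }
  diag(m) <- 0
  dyadic_matrix(m, bats = bats, role = role)
}

#' Day/night-stratified network
#'
#' An ordered sequence of per-period dyadic matrices plus the set of bats
#' present in each period. Bats absent in a period have `NA` rows in that
#' period's layer (absence is missing, never zero). This is the unit that
#' within-period constrained node-label permutations act on.
#'
#' @param layers named list of [dyadic_matrix()] objects over the same bats.
#' @param presence named list (same names) of character vectors of present bats.
#' @return A `day_stratified_network` object.
#' @export
day_stratified_network <- function(layers, presence) {
  stopifnot(is.list(layers), length(layers) >= 1)
  nm <- names(layers)
  if (is.null(nm) || any(nm == "")) stop("layers must be named by period")
  if (!identical(sort(nm), sort(names(presence)))) {
    stop("presence must be named identically to layers")
  }
  bats <- rownames(layers[[1]])
  for (p in nm) {
    if (!identical(rownames(layers[[p]]), bats)) {
      stop("all layers must share an identical bat index")
    }
    absent <- setdiff(bats, presence[[p]])
    lay <- layers[[p]]
    lay[absent, ] <- NA
    lay[, absent] <- NA
    diag(lay) <- 0
    layers[[p]] <- lay
  }
  structure(list(periods = nm, layers = layers,
                 presence = presence[nm], bats = bats),
            class = "day_stratified_network")
}

#' @export
print.day_stratified_network <- function(x, ...) {
  cat("<day_stratified_network>", length(x$periods), "periods,",
      length(x$bats), "bats\n")
  cat("periods:", paste(x$periods, collapse = ", "), "\n")
  invisible(x)
}

#' Aggregate a stratified network across periods
#'
#' Sums each dyad across layers (ignoring periods where the dyad is
#' missing); dyads missing in every period stay missing.
#'
#' @param x a [day_stratified_network()].
#' @param role role tag for the aggregate matrix.
#' @return A [dyadic_matrix()].
#' @export
aggregate_layers <- function(x, role = "seconds") {
  arr <- simplify2array(lapply(x$layers, unclass))
  tot <- rowSums(arr, dims = 2, na.rm = TRUE)
  tot[rowSums(!is.na(arr), dims = 2) == 0] <- NA_real_
  diag(tot) <- 0
  dyadic_matrix(tot, bats = x$bats, role = role)
}
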