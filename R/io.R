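#' Write a synthetic study dataset as delimited text tables
#'
#' Writes the documented schemas: `events.csv` (bat_a, bat_b, start_s,
#' duration_s, max_signal), `stations.csv` (bat, station_id, start_s,
#' duration_s), `bats.csv` (bat_id, type), `kinship.csv`, `grooming.csv`,
#' `sharing.csv` (long-form dyadic, bat_a < bat_b), `cofeeding_events.csv`,
#' `cofeeding_presence.csv`, and `truth.json` (parameters plus latent
#' matrices, for recovery tests). All times are integer seconds from the
#' study epoch.
#'
#' @param study a [simulate_study()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(x, f) utils::write.csv(x, file.path(dir, f), row.names = FALSE)
  wr(study$events, "events.csv")
  wr(study$stations, "stations.csv")
  wr(study$truth$bats[, c("bat_id", "type", "dropout_night")], "bats.csv")
  wr(dyad_table(study$truth$kinship), "kinship.csv")
  wr(dyad_table(study$truth$grooming, drop_missing = TRUE), "grooming.csv")
  wr(dyad_table(study$truth$sharing, drop_missing = TRUE), "sharing.csv")
  wr(study$cofeeding$events, "cofeeding_events.csv")
  wr(study$cofeeding$presence, "cofeeding_presence.csv")
  truth <- list(
    params = study$truth$params[setdiff(names(study$truth$params), "kin_pairs")],
    kin_pairs = study$truth$params$kin_pairs,
    relationship = dyad_table(study$truth$relationship),
    depart_intercepts = stats::setNames(study$truth$bats$depart_intercept_s,
                                        study$truth$bats$bat_id),
    true_bouts = study$bouts
  )
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(dir)
}

#' Read a study dataset written by [write_dataset()]
#'
#' @param dir dataset directory.
#' @return list: `events`, `stations`, `bats`, `kinship` (dyadic matrix),
#'   `grooming`, `sharing`, `cofeeding` (events + presence), `truth`
#'   (parsed truth.json, or NULL when absent for external data).
#' @export
read_dataset <- function(dir) {
  rd <- function(f) utils::read.csv(file.path(dir, f), stringsAsFactors = FALSE)
  bats_tab <- rd("bats.csv")
  bats <- bats_tab$bat_id
  from_long <- function(f, role) {
    if (!file.exists(file.path(dir, f))) return(NULL)
    tab <- rd(f)
    fill <- if (role == "rate") NA_real_ else 0
    dyadic_from_table(tab, bats, role = role, fill = fill)
  }
  truth_file <- file.path(dir, "truth.json")
  list(events = rd("events.csv"),
       stations = rd("stations.csv"),
       bats = bats_tab,
       kinship = from_long("kinship.csv", "kinship"),
       grooming = from_long("grooming.csv", "rate"),
       sharing = from_long("sharing.csv", "rate"),
       cofeeding = list(events = rd("cofeeding_events.csv"),
                        presence = rd("cofeeding_presence.csv")),
       truth = if (file.exists(truth_file)) jsonlite::read_json(truth_file) else NULL)
}

#' Validate the documented table schemas of a dataset directory
#'
#' Checks schema columns, dyad ordering (bat_a < bat_b), duplicate dyad
#' rows in long-form matrices, non-negative times and durations, and bat
#' ids resolving against `bats.csv`. Returns machine-readable diagnostics;
#' an empty data.frame means a clean dataset.
#'
#' @param dir dataset directory.
#' @return data.frame with columns `table`, `row`, `issue`.
#' @export
validate_tables <- function(dir) {
  diags <- list()
  note <- function(tab, row, issue) {
    diags[[length(diags) + 1]] <<- data.frame(table = tab, row = row,
                                              issue = issue,
                                              stringsAsFactors = FALSE)
  }
  need <- list(
    events.csv = c("bat_a", "bat_b", "start_s", "duration_s", "max_signal"),
    stations.csv = c("bat", "station_id", "start_s", "duration_s"),
    bats.csv = c("bat_id", "type"),
    kinship.csv = c("bat_a", "bat_b", "value")
  )
  tabs <- list()
  for (f in names(need)) {
    path <- file.path(dir, f)
    if (!file.exists(path)) {
      note(f, NA_integer_, "missing required table")
      next
    }
    tab <- utils::read.csv(path, stringsAsFactors = FALSE)
    miss <- setdiff(need[[f]], names(tab))
    if (length(miss)) note(f, NA_integer_, paste("missing column(s):",
                                                 paste(miss, collapse = ", ")))
    tabs[[f]] <- tab
  }
  known <- if (!is.null(tabs$bats.csv)) tabs$bats.csv$bat_id else character()
  for (f in c("events.csv", "kinship.csv")) {
    tab <- tabs[[f]]
    if (is.null(tab) || !all(c("bat_a", "bat_b") %in% names(tab))) next
    bad <- which(tab$bat_a >= tab$bat_b)
    for (r in bad) note(f, r, "dyad not ordered bat_a < bat_b")
    if (length(known)) {
      unk <- which(!(tab$bat_a %in% known) | !(tab$bat_b %in% known))
      for (r in unk) note(f, r, paste("unknown bat id:",
                                      paste(setdiff(c(tab$bat_a[r], tab$bat_b[r]),
                                                    known), collapse = ", ")))
    }
    key <- paste(tab$bat_a, tab$bat_b)
    if (f == "kinship.csv") {
      dup <- which(duplicated(key))
      for (r in dup) note(f, r, "duplicated dyad row")
    }
  }
  ev <- tabs$events.csv
  if (!is.null(ev) && all(c("start_s", "duration_s") %in% names(ev))) {
    for (r in which(ev$start_s < 0)) note("events.csv", r, "negative start_s")
    for (r in which(ev$duration_s < 0)) note("events.csv", r, "negative duration_s")
  }
  st <- tabs$stations.csv
  if (!is.null(st) && "bat" %in% names(st) && length(known)) {
    for (r in which(!(st$bat %in% known))) {
      note("stations.csv", r, paste("unknown bat id:", st$bat[r]))
    }
  }
  if (length(diags)) do.call(rbind, diags) else
    data.frame(table = character(), row = integer(), issue = character(),
               stringsAsFactors = FALSE)
}
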