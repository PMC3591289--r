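#' Results store for the database extension
#'
#' A small relational store with the two tables of the database
#' extension: `states` (one row per determined stationary state, with
#' coordinates, stability, interval label and multistability
#' annotations) and `bifurcations` (one row per detected bifurcation
#' value), both keyed by case id.  The store lives in a directory as
#' two CSV files; floating-point fields are written with 17
#' significant digits, so round trips are exact in binary64.
#'
#' @param dir directory to hold the store (created if missing).
#' @return An object of class `resultsStore`.
#' @export
resultsStore <- function(dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  structure(list(dir = dir,
                 states_path = file.path(dir, "stationary_states.csv"),
                 bifs_path = file.path(dir, "bifurcations.csv")),
            class = "resultsStore")
}

#' @export
print.resultsStore <- function(x, ...) {
  s <- storeTable(x, "states"); b <- storeTable(x, "bifurcations")
  cat(sprintf("<resultsStore %s>  %d stationary states, %d bifurcations, %d cases\n",
              x$dir, nrow(s), nrow(b),
              length(unique(s$case_id))))
  invisible(x)
}

fmt17 <- function(x) {
  if (is.double(x)) sprintf("%.17g", x) else x
}

packState <- function(y) paste(sprintf("%.17g", y), collapse = ";")

#' Unpack a packed state-vector field
#' @param s character vector of `;`-separated state components.
#' @return List of numeric vectors.
#' @export
unpackState <- function(s) lapply(strsplit(s, ";", fixed = TRUE), as.numeric)

writeTable <- function(df, path) {
  out <- df
  for (j in seq_along(out)) out[[j]] <- fmt17(out[[j]])
  tmp <- paste0(path, ".tmp")
  write.csv(out, tmp, row.names = FALSE, quote = TRUE)
  file.rename(tmp, path)   # atomic replace: transactional per write
}

storeTable <- function(store, table = c("states", "bifurcations")) {
  table <- match.arg(table)
  path <- if (table == "states") store$states_path else store$bifs_path
  if (!file.exists(path)) {
    return(if (table == "states")
      data.frame(case_id = integer(), point_id = integer(),
                 parameter = double(), stable = logical(),
                 interval_label = character(), scenario_class = character(),
                 coexistence_at_original = character(), state = character())
      else
        data.frame(case_id = integer(), label = character(),
                   kind = character(), parameter = double(),
                   state = character()))
  }
  df <- read.csv(path, colClasses = "character")
  for (col in c("case_id", "point_id")) if (col %in% names(df))
    df[[col]] <- as.integer(df[[col]])
  if ("parameter" %in% names(df)) df$parameter <- as.numeric(df$parameter)
  if ("stable" %in% names(df)) df$stable <- as.logical(df$stable)
  df
}

#' Record one case into the store
#'
#' Transactional, idempotent insert of a case's stationary-state rows
#' and bifurcation rows.  Re-running with identical payload is a
#' no-op; a duplicate key with a differing payload raises an
#' integrity error.
#'
#' @param store a [resultsStore()].
#' @param states data frame with columns `case_id`, `point_id`,
#'   `parameter`, `stable`, `interval_label`, `scenario_class`,
#'   `coexistence_at_original`, `state` (packed with 17 significant
#'   digits; see [stationaryStateRecords()]).
#' @param bifurcations data frame with columns `case_id`, `label`,
#'   `kind`, `parameter`, `state` (may have zero rows).
#' @return The store, invisibly.
#' @export
writeCase <- function(store, states, bifurcations = NULL) {
  stopifnot(inherits(store, "resultsStore"))
  states$case_id <- as.integer(states$case_id)
  states$point_id <- as.integer(states$point_id)
  if (!is.null(bifurcations) && nrow(bifurcations))
    bifurcations$case_id <- as.integer(bifurcations$case_id)
  if (anyDuplicated(states[c("case_id", "point_id")]))
    stop("duplicate (case_id, point_id) in payload", call. = FALSE)
  if (!is.null(bifurcations) && nrow(bifurcations) &&
      anyDuplicated(bifurcations[c("case_id", "label")]))
    stop("duplicate (case_id, label) in payload", call. = FALSE)
  if (!is.null(bifurcations) && nrow(bifurcations) &&
      !all(bifurcations$case_id %in% states$case_id))
    stop("bifurcation rows reference unknown case ids", call. = FALSE)

  merge1 <- function(existing, new, key) {
    if (!nrow(existing)) return(new)
    new_cases <- unique(new$case_id)
    old <- existing[existing$case_id %in% new_cases, , drop = FALSE]
    if (nrow(old)) {
      # normalize for comparison through the same serialization
      norm <- function(df) {
        df <- df[do.call(order, df[key]), , drop = FALSE]
        rownames(df) <- NULL
        for (j in seq_along(df)) df[[j]] <- fmt17(df[[j]])
        df
      }
      if (!identical(norm(old), norm(new)))
        stop("integrity error: case already stored with different payload",
             call. = FALSE)
      return(existing)   # idempotent re-run
    }
    rbind(existing, new)
  }
  st_all <- merge1(storeTable(store, "states"), states,
                   c("case_id", "point_id"))
  writeTable(st_all[order(st_all$case_id, st_all$point_id), ],
             store$states_path)
  if (!is.null(bifurcations) && nrow(bifurcations)) {
    bf_all <- merge1(storeTable(store, "bifurcations"), bifurcations,
                     c("case_id", "label"))
    writeTable(bf_all[order(bf_all$case_id, bf_all$label), ],
               store$bifs_path)
  }
  invisible(store)
}

#' Query a store table
#'
#' @param store a [resultsStore()].
#' @param table `"states"` or `"bifurcations"`.
#' @param filter optional predicate taking the data frame and
#'   returning a logical row mask.
#' @return The filtered table, stably ordered by key.
#' @export
queryStore <- function(store, table = c("states", "bifurcations"),
                       filter = NULL) {
  table <- match.arg(table)
  df <- storeTable(store, table)
  if (!is.null(filter)) {
    keep <- filter(df)
    if (!is.logical(keep) || length(keep) != nrow(df))
      stop("query error: filter must return one logical per row",
           call. = FALSE)
    df <- df[keep & !is.na(keep), , drop = FALSE]
  }
  key <- if (table == "states") c("case_id", "point_id")
         else c("case_id", "label")
  df <- df[do.call(order, df[key]), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Build stationary-state records from a branch
#'
#' @param case_id case identifier.
#' @param branch a [continueBranch()] result.
#' @param intervals output of [stableIntervals()].
#' @param scenario a `scenarioClass` (or `NULL`).
#' @param at_original output of [multistableAt()] at the case's
#'   original conductance (or `NULL`).
#' @return Data frame ready for [writeCase()].
#' @export
stationaryStateRecords <- function(case_id, branch, intervals = list(),
                                   scenario = NULL, at_original = NULL) {
  m <- length(branch$parameter)
  lab <- rep("", m)
  for (s in intervals) {
    idx <- s$arc_range[1]:s$arc_range[2]
    lab[idx] <- s$label
  }
  coex <- if (is.null(at_original) || !length(at_original)) ""
    else paste(vapply(at_original, function(r)
      paste(r$regimes, collapse = "+"), ""), collapse = " | ")
  data.frame(case_id = as.integer(case_id), point_id = seq_len(m),
             parameter = branch$parameter, stable = branch$stable,
             interval_label = lab,
             scenario_class = if (is.null(scenario)) "" else scenario$class,
             coexistence_at_original = coex,
             state = apply(branch$states, 1, packState))
}

#' Build bifurcation records from detected bifurcations
#'
#' @param case_id case identifier.
#' @param bifurcations output of [detectBifurcations()].
#' @return Data frame ready for [writeCase()].
#' @export
bifurcationRecords <- function(case_id, bifurcations) {
  if (!length(bifurcations))
    return(data.frame(case_id = integer(), label = character(),
                      kind = character(), parameter = double(),
                      state = character()))
  data.frame(case_id = as.integer(case_id),
             label = vapply(bifurcations, `[[`, "", "label"),
             kind = vapply(bifurcations, `[[`, "", "kind"),
             parameter = vapply(bifurcations, `[[`, 0, "parameter"),
             state = vapply(bifurcations, function(b) packState(b$state), ""))
}
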