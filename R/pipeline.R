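#' Analysis options for the per-case pipeline
#'
#' Bundles the protocol parameters of the full per-case analysis with
#' the standard defaults: 400 s settling with 200 s discarded,
#' continuation started from the stable rest state at 20 nS,
#' range scanning from the case's original conductance at 1 nS initial
#' step down to 1e-4 nS precision.  Tests and demonstrations may scale
#' the protocol down through these options.
#'
#' @param settle_total,settle_discard settling protocol (s).
#' @param cont_start_g continuation start conductance (nS).
#' @param cont_args list of extra arguments for [continueBranch()].
#' @param scan_step,scan_precision range-scanner stepping (nS).
#' @param scan_floor lower domain edge (nS).
#' @return A named list of options.
#' @export
pipelineOptions <- function(settle_total = 400, settle_discard = 200,
                            cont_start_g = 20, cont_args = list(),
                            scan_step = 1, scan_precision = 1e-4,
                            scan_floor = 0) {
  list(settle_total = settle_total, settle_discard = settle_discard,
       cont_start_g = cont_start_g, cont_args = cont_args,
       scan_step = scan_step, scan_precision = scan_precision,
       scan_floor = scan_floor)
}

#' Full analysis of one case
#'
#' Runs the complete per-case workflow: settle at the original
#' conductance and classify; if the case is a robust burster, continue
#' the equilibrium branch from the large-conductance rest state,
#' detect bifurcations and stable intervals, scan the bursting range,
#' intersect ranges into coexistence ranges, classify the
#' multistability scenario, compute the prevalence and the
#' multistability status at the original conductance, and optionally
#' record everything into a [resultsStore()].  Stage failures flag the
#' row and do not abort a cohort.
#'
#' @param model an [odeModel()] with a conductance-like scan parameter.
#' @param original_g the case's original conductance (nS).
#' @param y0 initial state for the settling run.
#' @param case_id case identifier.
#' @param store optional [resultsStore()].
#' @param opts options from [pipelineOptions()].
#' @return A one-row data frame (`caseRow`) plus the stage artifacts in
#'   the `"artifacts"` attribute.
#' @export
runCase <- function(model, original_g, y0, case_id = 0L, store = NULL,
                    opts = pipelineOptions()) {
  row <- data.frame(case_id = as.integer(case_id), original_g = original_g,
                    qualifies = FALSE, regime = NA_character_,
                    g_min = NA_real_, g_max = NA_real_,
                    n_bifurcations = NA_integer_,
                    n_stable_intervals = NA_integer_,
                    scenario = NA_character_, prevalence = NA_real_,
                    multistable_at_original = NA,
                    failed_stage = NA_character_)
  art <- list()
  fail <- function(stage, e) {
    row$failed_stage <<- paste0(stage, ": ", conditionMessage(e))
    NULL
  }
  settle_args <- list(total = opts$settle_total,
                      discard = opts$settle_discard)

  reg <- tryCatch({
    m0 <- setModelPar(model, original_g)
    traj <- do.call(settle, c(list(m0, y0), settle_args))
    art$settle_final <- finalState(traj)
    classifyRegime(traj)
  }, error = function(e) fail("settle", e))
  if (is.null(reg)) return(finishRow(row, art))
  row$regime <- reg$label
  row$qualifies <- isRobustBurster(reg)
  if (!row$qualifies) return(finishRow(row, art))

  branchres <- tryCatch({
    mh <- setModelPar(model, opts$cont_start_g)
    rest <- do.call(settle, c(list(mh, y0), settle_args))
    eq <- findEquilibrium(mh, finalState(rest))
    br <- do.call(continueBranch, c(list(mh, eq), opts$cont_args))
    bifs <- detectBifurcations(br, mh)
    ivs <- stableIntervals(br, bifs)
    list(branch = br, bifs = bifs, intervals = ivs)
  }, error = function(e) fail("continuation", e))
  if (is.null(branchres)) return(finishRow(row, art))
  art <- c(art, branchres)
  row$n_bifurcations <- length(branchres$bifs)
  row$n_stable_intervals <- length(branchres$intervals)

  rng <- tryCatch(
    scanBurstingRange(model, original_g, art$settle_final,
                      step_init = opts$scan_step,
                      precision = opts$scan_precision,
                      g_floor = opts$scan_floor,
                      settle_args = settle_args),
    error = function(e) fail("scan", e))
  if (is.null(rng)) return(finishRow(row, art))
  art$range <- rng
  row$g_min <- rng$g_min; row$g_max <- rng$g_max

  multi <- tryCatch({
    cx <- coexistenceRanges(branchres$intervals, rng)
    sc <- classifyScenario(cx)
    prev <- prevalenceOfMultistability(rng, cx)
    at0 <- multistableAt(original_g, cx)
    list(coexistence = cx, scenario = sc, prevalence = prev,
         at_original = at0)
  }, error = function(e) fail("multistability", e))
  if (is.null(multi)) return(finishRow(row, art))
  art <- c(art, multi)
  row$scenario <- multi$scenario$class
  row$prevalence <- multi$prevalence
  row$multistable_at_original <-
    any(vapply(multi$at_original, function(r)
      "bursting" %in% r$regimes, TRUE))

  if (!is.null(store)) {
    tryCatch(writeCase(store,
                       stationaryStateRecords(case_id, branchres$branch,
                                              branchres$intervals,
                                              multi$scenario,
                                              multi$at_original),
                       bifurcationRecords(case_id, branchres$bifs)),
             error = function(e) fail("store", e))
  }
  finishRow(row, art)
}

finishRow <- function(row, art) {
  attr(row, "artifacts") <- art
  class(row) <- c("caseRow", class(row))
  row
}

#' Cohort-level analysis
#'
#' Applies [runCase()] to every case in isolation (a stage failure
#' flags the row; the cohort continues) and aggregates: counts per
#' scenario class, the multistable fraction, the prevalence summary
#' over the cases exhibiting multistability, and a prevalence
#' histogram with 5-percentage-point bins.
#'
#' @param cases list of case descriptions: each a list with `model`,
#'   `original_g`, `y0` and optional `case_id`.
#' @param store optional [resultsStore()] shared by all cases.
#' @param opts options from [pipelineOptions()].
#' @return An object of class `cohortReport` with `rows` (data frame)
#'   and `aggregates`.
#' @export
runCohort <- function(cases, store = NULL, opts = pipelineOptions()) {
  if (!length(cases)) stop("empty cohort", call. = FALSE)
  rows <- vector("list", length(cases))
  for (i in seq_along(cases)) {
    cs <- cases[[i]]
    rows[[i]] <- tryCatch(
      runCase(cs$model, cs$original_g, cs$y0,
              case_id = cs$case_id %||% (i - 1L), store = store,
              opts = opts),
      error = function(e)
        finishRow(data.frame(case_id = cs$case_id %||% (i - 1L),
                             original_g = cs$original_g, qualifies = FALSE,
                             regime = NA_character_, g_min = NA_real_,
                             g_max = NA_real_, n_bifurcations = NA_integer_,
                             n_stable_intervals = NA_integer_,
                             scenario = NA_character_,
                             prevalence = NA_real_,
                             multistable_at_original = NA,
                             failed_stage = paste0("case: ",
                                                   conditionMessage(e))),
                  list()))
  }
  df <- do.call(rbind, lapply(rows, function(r) { attr(r, "artifacts") <- NULL
                                                  class(r) <- "data.frame"; r }))
  multist <- !is.na(df$prevalence) & df$prevalence > 0
  scen <- table(factor(df$scenario[multist],
                       levels = c(LETTERS[1:10], "none", "unclassified")))
  prev_vals <- df$prevalence[multist]
  breaks <- seq(0, 1, by = 0.05)
  histo <- if (length(prev_vals))
    table(cut(prev_vals, breaks, include.lowest = TRUE)) else NULL
  agg <- list(
    n = nrow(df),
    n_qualifying = sum(df$qualifies, na.rm = TRUE),
    n_multistable = sum(multist),
    multistable_fraction = sum(multist) / nrow(df),
    scenario_counts = scen,
    prevalence_summary = if (length(prev_vals))
      summarizePrevalence(prev_vals) else NULL,
    prevalence_histogram = histo,
    histogram_breaks = breaks)
  structure(list(rows = df, aggregates = agg), class = "cohortReport")
}

#' @export
print.cohortReport <- function(x, ...) {
  a <- x$aggregates
  cat(sprintf(paste0("<cohortReport>  %d cases, %d qualifying, %d ",
                     "multistable (fraction %.3g)\n"),
              a$n, a$n_qualifying, a$n_multistable,
              a$multistable_fraction))
  if (!is.null(a$prevalence_summary)) print(a$prevalence_summary)
  invisible(x)
}
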