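#' Scan the conductance range supporting robust bursting
#'
#' Implements the iterative step-refinement protocol with endpoint
#' carry-over.  Starting from `start_g` (which must settle into robust
#' bursting), the parameter is stepped outward by `step_init`
#' (default 1 nS); each probe runs a full settling integration (400 s,
#' first 200 s discarded) from the endpoint of the last accepted
#' bursting trajectory.  When a probe fails to classify as robust
#' bursting, the initial conditions are reset to that last accepted
#' endpoint and the step is reduced tenfold, down to `precision`
#' (default 1e-4 nS) -- five refinement levels per direction.  The
#' carry-over tracks the bursting attractor through coexistence
#' regions, so the scanned range is the attractor's own existence
#' range, not the fresh-initial-condition one.
#'
#' If bursting persists down to `g_floor` (default 0 nS, the physical
#' domain edge) the lower boundary is reported as the floor with label
#' `"domain_edge"`.
#'
#' @param model an [odeModel()] whose scan parameter is the leak-like
#'   conductance.
#' @param start_g starting parameter value (nS).
#' @param y0 initial state at `start_g`.
#' @param step_init initial step (nS).
#' @param precision boundary precision (nS).
#' @param g_floor lower domain edge (nS).
#' @param g_cap safety cap on the upward pass (nS).
#' @param probe probe function `(g, state)` returning a list with
#'   `robust` (logical), `label` (regime beyond the edge) and `state`
#'   (endpoint).  The default runs [settle()] + [classifyRegime()] +
#'   [isRobustBurster()]; injectable for algorithm tests and
#'   instrumentation.
#' @param settle_args list of arguments forwarded to [settle()] by the
#'   default probe.
#' @param verbose print per-probe progress.
#' @return An object of class `burstingRange`: `g_min`, `g_max`,
#'   `precision`, `boundary_labels` (regimes met beyond the lower and
#'   upper edges), `levels` (steps used per direction), `probes`
#'   (probe log), and the endpoint states at both boundaries.
#' @export
scanBurstingRange <- function(model, start_g, y0, step_init = 1,
                              precision = 1e-4, g_floor = 0, g_cap = 1e3,
                              probe = NULL, settle_args = list(),
                              verbose = FALSE) {
  if (is.null(probe)) {
    probe <- function(g, state) {
      m <- setModelPar(model, g)
      traj <- do.call(settle, c(list(m, state), settle_args))
      reg <- classifyRegime(traj)
      list(robust = isRobustBurster(reg), label = reg$label,
           state = finalState(traj))
    }
  }
  log_env <- new.env()
  log_env$rows <- list()
  note <- function(dir, level, g, res) {
    log_env$rows[[length(log_env$rows) + 1]] <-
      data.frame(direction = dir, step = level, g = g,
                 robust = res$robust, label = res$label)
    if (verbose)
      message(sprintf("  dir %+d step %g: g = %.6f -> %s",
                      dir, level, g, res$label))
  }

  first <- probe(start_g, y0)
  note(0L, NA_real_, start_g, first)
  if (!first$robust)
    stop(sprintf("start point g = %g is not a robust burster (got '%s')",
                 start_g, first$label), call. = FALSE)

  sweep <- function(dir) {
    g_cur <- start_g
    state <- first$state
    step <- step_init
    levels <- numeric(0)
    fail_label <- NA_character_
    repeat {
      levels <- c(levels, step)
      repeat {
        g_next <- g_cur + dir * step
        edge <- FALSE
        if (dir < 0 && g_next < g_floor) { g_next <- g_floor; edge <- TRUE }
        if (dir > 0 && g_next > g_cap) { g_next <- g_cap; edge <- TRUE }
        if (g_next == g_cur)
          return(list(g = g_cur, label = "domain_edge", state = state,
                      levels = levels))
        res <- probe(g_next, state)
        note(dir, step, g_next, res)
        if (res$robust) {
          g_cur <- g_next
          state <- res$state
          if (edge)
            return(list(g = g_cur, label = "domain_edge", state = state,
                        levels = levels))
        } else {
          fail_label <- res$label
          break
        }
      }
      if (step <= precision)
        return(list(g = g_cur, label = fail_label, state = state,
                    levels = levels))
      step <- step / 10
    }
  }

  up <- sweep(+1L)
  down <- sweep(-1L)
  probes <- do.call(rbind, log_env$rows)
  structure(list(g_min = down$g, g_max = up$g, precision = precision,
                 start_g = start_g,
                 boundary_labels = c(lower = down$label, upper = up$label),
                 levels = list(down = down$levels, up = up$levels),
                 boundary_states = list(lower = down$state, upper = up$state),
                 probes = probes),
            class = "burstingRange")
}

#' @export
print.burstingRange <- function(x, ...) {
  cat(sprintf(paste0("<burstingRange>  [%.6f, %.6f] nS (precision %g), ",
                     "beyond edges: %s / %s\n"),
              x$g_min, x$g_max, x$precision,
              x$boundary_labels["lower"], x$boundary_labels["upper"]))
  invisible(x)
}

#' Dense carry-over sweep near a bursting boundary (oracle)
#'
#' Uniform fine sweep used as an independent check on
#' [scanBurstingRange()]: probes every parameter value on a regular
#' grid, carrying the endpoint of the last bursting trajectory
#' forward, and reports the last robust-bursting value before the
#' first failure.  Each probe runs the full settling protocol.
#'
#' @param model an [odeModel()].
#' @param g_from,g_to sweep interval (inclusive); the sweep runs from
#'   `g_from` towards `g_to` in steps of `dg` (sign inferred).
#' @param dg grid resolution (nS, > 0).
#' @param y0 initial state at `g_from`.
#' @param probe as in [scanBurstingRange()].
#' @param settle_args forwarded to [settle()].
#' @return List with `boundary` (last robust g), `fail_label`, `fail_g`
#'   (first failing g, `NA` if none failed) and the probe log.
#' @export
denseBoundaryOracle <- function(model, g_from, g_to, dg, y0,
                                probe = NULL, settle_args = list()) {
  stopifnot(dg > 0)
  if (is.null(probe)) {
    probe <- function(g, state) {
      m <- setModelPar(model, g)
      traj <- do.call(settle, c(list(m, state), settle_args))
      reg <- classifyRegime(traj)
      list(robust = isRobustBurster(reg), label = reg$label,
           state = finalState(traj))
    }
  }
  dir <- sign(g_to - g_from)
  gs <- seq(g_from, g_to, by = dir * dg)
  state <- y0
  last_ok <- NA_real_; fail_g <- NA_real_; fail_label <- NA_character_
  rows <- list()
  for (g in gs) {
    res <- probe(g, state)
    rows[[length(rows) + 1]] <-
      data.frame(g = g, robust = res$robust, label = res$label)
    if (res$robust) {
      last_ok <- g
      state <- res$state
    } else {
      fail_g <- g; fail_label <- res$label
      break
    }
  }
  list(boundary = last_ok, fail_g = fail_g, fail_label = fail_label,
       probes = do.call(rbind, rows))
}
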