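#' Extract a time window of a trajectory
#'
#' @param traj a [trajectory()].
#' @param t0,t1 window bounds (s, inclusive).
#' @param rezero shift times so the window starts at 0.
#' @return A [trajectory()].
#' @export
subTrajectory <- function(traj, t0, t1 = max(traj$times), rezero = TRUE) {
  keep <- traj$times >= t0 & traj$times <= t1
  trajectory(times = traj$times[keep] - if (rezero) t0 else 0,
             states = traj$states[keep, , drop = FALSE], meta = traj$meta)
}

# per-cell classification of an HCO trajectory window
classifyCells <- function(traj, v_idx, ...) {
  lapply(v_idx, function(iv) classifyRegime(traj, v_index = iv, ...))
}

# is a silent cell sitting at rest (negligible late movement)?
atRest <- function(traj, iv, window = 10, tol_mv = 1) {
  t1 <- max(traj$times)
  v <- traj$states[traj$times >= t1 - window, iv]
  diff(range(v)) < tol_mv
}

#' Reset-perturbation protocol on a half-center oscillator
#'
#' Three-phase simulation: the coupled system runs for `t_pre` seconds
#' (default 100 s); then one cell's state is reset (not clamped) to a
#' stable stationary state of the isolated cell and the synapses are
#' blocked (maximal conductances set to 0 nS, gating states still
#' evolving) for `t_block` seconds (default 5 s); finally the synaptic
#' currents are restored and the system runs for another `t_post`
#' seconds (default 100 s).  The pre and post segments are classified
#' independently on their last `analyze_last` seconds; the outcome is
#' `"recovered"` exactly when the post segment satisfies
#' [hcoFunctional()], otherwise `"dysfunctional"` with a mode:
#' `both_at_rest` (both cells silent with negligible late movement),
#' `damped_oscillations` (a silent cell still rings), `tonic_spiking`
#' or `irregular`.
#'
#' @param hco an `hcoModel`.
#' @param y0 initial state for the pre segment.
#' @param reset_state an `equilibriumPoint` (must be stable) or a bare
#'   state vector of the isolated cell.
#' @param which_cell cell to reset (1 or 2).
#' @param t_pre,t_block,t_post phase durations (s).
#' @param analyze_last analysis window at the end of the pre and post
#'   segments (s).
#' @param restore_synapses set `FALSE` for the control variant in
#'   which the synapses stay blocked during the final phase.
#' @param keep_trajectories retain the three full-phase trajectories.
#' @param ... forwarded to [integrateModel()].
#' @return An object of class `hcoOutcome`: `outcome`,
#'   `dysfunction_mode`, `pre`/`post` (per-cell labels, burst stats
#'   and the [hcoFunctional()] report), `timing`, and optionally
#'   `phases`.
#' @export
runPerturbation <- function(hco, y0, reset_state, which_cell = 1L,
                            t_pre = 100, t_block = 5, t_post = 100,
                            analyze_last = 50, restore_synapses = TRUE,
                            keep_trajectories = FALSE, ...) {
  stopifnot(inherits(hco, "hcoModel"), which_cell %in% c(1L, 2L))
  if (inherits(reset_state, "equilibriumPoint")) {
    if (!reset_state$stable)
      stop("reset_state must be a stable stationary state", call. = FALSE)
    reset_vec <- reset_state$state
  } else reset_vec <- as.numeric(reset_state)
  idx <- hco$meta$cell_idx[[which_cell]]
  if (length(reset_vec) != length(idx))
    stop("reset state has wrong dimension for one cell", call. = FALSE)
  v_idx <- hco$meta$v_idx

  phase1 <- integrateModel(hco, y0, t_pre, ...)
  u <- finalState(phase1)
  u[idx] <- reset_vec
  phase2 <- integrateModel(synapsesOff(hco), u, t_block, ...)
  m3 <- if (restore_synapses) hco else synapsesOff(hco)
  phase3 <- integrateModel(m3, finalState(phase2), t_post, ...)

  analyze <- function(traj) {
    win <- subTrajectory(traj, max(traj$times) - analyze_last)
    regs <- classifyCells(win, v_idx)
    fn <- tryCatch(hcoFunctional(regs[[1]]$spikes, regs[[2]]$spikes),
                   error = function(e) list(functional = FALSE,
                                            phase = NA_real_,
                                            cv_a = NA_real_,
                                            cv_b = NA_real_))
    list(labels = vapply(regs, `[[`, "", "label"),
         stats = lapply(regs, `[[`, "stats"),
         functional = fn, window = win)
  }
  pre <- analyze(phase1)
  post <- analyze(phase3)

  if (post$functional$functional) {
    outcome <- "recovered"; mode <- "none"
  } else {
    outcome <- "dysfunctional"
    silent <- post$labels == "silent"
    rest <- vapply(seq_along(v_idx), function(i)
      silent[i] && atRest(post$window, v_idx[i]), TRUE)
    mode <- if (all(rest)) "both_at_rest"
      else if (any(silent)) "damped_oscillations"
      else if (any(post$labels == "tonic_spiking")) "tonic_spiking"
      else "irregular"
  }

  pre$window <- NULL; post$window <- NULL
  structure(list(outcome = outcome, dysfunction_mode = mode,
                 pre = pre, post = post,
                 which_cell = which_cell,
                 timing = c(pre = t_pre, block = t_block, post = t_post,
                            total = t_pre + t_block + t_post),
                 phases = if (keep_trajectories)
                   list(pre = phase1, block = phase2, post = phase3)),
            class = "hcoOutcome")
}

#' @export
print.hcoOutcome <- function(x, ...) {
  cat(sprintf("<hcoOutcome>  %s%s; pre: %s | post: %s (phase %.3g)\n",
              x$outcome,
              if (x$outcome == "dysfunctional")
                paste0(" (", x$dysfunction_mode, ")") else "",
              paste(x$pre$labels, collapse = "/"),
              paste(x$post$labels, collapse = "/"),
              x$post$functional$phase))
  invisible(x)
}
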