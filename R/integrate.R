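#' Integrated trajectory
#'
#' @param times sampling times (s), strictly increasing.
#' @param states matrix of states (rows = times).
#' @param state_names column names for `states`.
#' @param meta metadata list (tolerances, duration, transient).
#' @return An object of class `trajectory`.
#' @export
trajectory <- function(times, states, state_names = colnames(states),
                       meta = list()) {
  states <- as.matrix(states)
  if (length(times) != nrow(states))
    stop("times and states disagree in length", call. = FALSE)
  if (any(diff(times) <= 0))
    stop("times must be strictly increasing", call. = FALSE)
  if (any(!is.finite(states)))
    stop("trajectory contains non-finite values", call. = FALSE)
  if (!is.null(state_names)) colnames(states) <- state_names
  structure(list(times = times, states = states, meta = meta),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory>  %d samples over %.6g s, %d states (%s)\n",
              length(x$times), diff(range(x$times)), ncol(x$states),
              paste(colnames(x$states), collapse = ", ")))
  invisible(x)
}

#' Membrane-potential trace of a trajectory
#' @param traj a [trajectory()].
#' @param v_index column holding the membrane potential.
#' @return Numeric vector (mV).
#' @export
voltageTrace <- function(traj, v_index = 1L) traj$states[, v_index]

#' Final state of a trajectory
#' @param traj a [trajectory()].
#' @return Named state vector at the last sample.
#' @export
finalState <- function(traj) {
  y <- traj$states[nrow(traj$states), ]
  names(y) <- colnames(traj$states)
  y
}

#' Stiff integration of a model
#'
#' Integrates with the implicit Runge-Kutta method of order 5
#' (Radau IIa, [deSolve::radau()]), the standard choice for stiff
#' conductance-based neuron models.  Dense output is sampled at a fixed
#' interval (default 1 ms), fine enough for spike detection.
#'
#' When the model carries a compiled right-hand side it is used
#' automatically; set `use_compiled = FALSE` to force the R closure
#' (the two paths agree to solver tolerance and are tested to do so).
#'
#' @param model an [odeModel()].
#' @param y0 initial state.
#' @param duration integration time (s, > 0).
#' @param rel_tol,abs_tol solver tolerances (defaults 1e-9 / 1e-12).
#' @param sample_dt output sampling interval (s).
#' @param use_compiled use the compiled rhs when available.
#' @return A [trajectory()] starting at `y0`.
#' @export
integrateModel <- function(model, y0, duration,
                           rel_tol = 1e-9, abs_tol = 1e-12,
                           sample_dt = 1e-3, use_compiled = TRUE) {
  stopifnot(inherits(model, "odeModel"), duration > 0)
  y0 <- as.numeric(y0)
  if (length(y0) != length(model$state_names))
    stop("initial state has wrong dimension", call. = FALSE)
  times <- seq(0, duration, by = sample_dt)
  if (times[length(times)] < duration) times <- c(times, duration)

  if (!is.null(model$compiled) && use_compiled) {
    cmp <- model$compiled
    out <- deSolve::radau(y = y0, times = times, func = cmp$func,
                          parms = cmp$parms(model$pars),
                          dllname = cmp$dllname, initfunc = cmp$initfunc,
                          rtol = rel_tol, atol = abs_tol)
  } else {
    f <- function(t, y, p) list(model$rhs(t, y, p))
    jf <- if (!is.null(model$jac))
      function(t, y, p) model$jac(t, y, p)
    out <- deSolve::radau(y = y0, times = times, func = f,
                          parms = model$pars, rtol = rel_tol, atol = abs_tol,
                          jacfunc = jf,
                          jactype = if (is.null(jf)) "fullint" else "fullusr")
  }
  st <- attr(out, "istate")
  if (!is.null(st) && st[1] < 0)
    stop(sprintf("integration failed at t = %.6g s (solver state %d)",
                 max(out[, 1]), st[1]), call. = FALSE)
  if (nrow(out) < length(times))
    stop(sprintf("integration stopped early at t = %.6g s", max(out[, 1])),
         call. = FALSE)
  trajectory(times = out[, 1], states = out[, -1, drop = FALSE],
             state_names = model$state_names,
             meta = list(rel_tol = rel_tol, abs_tol = abs_tol,
                         duration = duration, sample_dt = sample_dt,
                         transient_discarded = 0))
}

#' Settle a model past its transient
#'
#' Runs the standard settling protocol: integrate for `total` seconds
#' (default 400 s), discard the first `discard` seconds (default
#' 200 s), and return the remainder time-shifted to start at 0.  The
#' final state is retrievable with [finalState()] for use as a later
#' initial condition.
#'
#' @param model an [odeModel()].
#' @param y0 initial state.
#' @param total total integrated time (s).
#' @param discard leading transient to drop (s).
#' @param ... passed to [integrateModel()].
#' @return A [trajectory()] covering `total - discard` seconds.
#' @export
settle <- function(model, y0, total = 400, discard = 200, ...) {
  stopifnot(total > discard, discard >= 0)
  traj <- integrateModel(model, y0, duration = total, ...)
  keep <- traj$times >= discard
  trajectory(times = traj$times[keep] - discard,
             states = traj$states[keep, , drop = FALSE],
             meta = c(traj$meta[setdiff(names(traj$meta), "transient_discarded")],
                      list(transient_discarded = discard)))
}

#' Write / read a small trajectory as CSV
#'
#' @param traj a [trajectory()].
#' @param path file path.
#' @return `readTrajectoryCSV` returns a [trajectory()].
#' @export
writeTrajectoryCSV <- function(traj, path) {
  df <- data.frame(time = traj$times, traj$states, check.names = FALSE)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeTrajectoryCSV
#' @export
readTrajectoryCSV <- function(path) {
  df <- read.csv(path, check.names = FALSE)
  trajectory(times = df[[1]], states = as.matrix(df[, -1, drop = FALSE]))
}
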