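#' Detect spikes in a voltage trace
#'
#' A spike is a local maximum of the membrane potential whose value
#' exceeds the detection threshold (default -10 mV).  Runs of equal
#' suprathreshold samples (flat tops) count as a single spike at the
#' centre of the run.
#'
#' @param traj a [trajectory()] (at least 3 samples).
#' @param threshold detection threshold (mV).
#' @param v_index state column holding the membrane potential.
#' @return An object of class `spikeTrain` with fields `spike_times`
#'   (s, strictly increasing, possibly empty) and `threshold`.
#' @export
detectSpikes <- function(traj, threshold = -10, v_index = 1L) {
  stopifnot(inherits(traj, "trajectory"))
  v <- traj$states[, v_index]
  n <- length(v)
  if (n < 3) stop("trajectory needs at least 3 samples", call. = FALSE)
  d <- diff(v)
  s <- sign(d)
  locf <- function(x) {                       # carry last nonzero forward
    x[x == 0] <- NA
    idx <- cumsum(!is.na(x))
    out <- rep(NA_real_, length(x))
    out[idx > 0] <- x[!is.na(x)][idx[idx > 0]]
    out
  }
  left <- locf(s)                             # slope sign approaching i+1
  right <- rev(locf(rev(s)))                  # slope sign leaving i
  # interior sample i is a maximum if slope before is + and after is -
  i <- 2:(n - 1)
  is_max <- !is.na(left[i - 1]) & !is.na(right[i]) &
    left[i - 1] > 0 & right[i] < 0 & v[i] > threshold
  idx <- i[is_max]
  if (length(idx) > 1) {
    # collapse flat tops: identical voltage and contiguous plateau
    keep <- c(TRUE, !(diff(idx) == 1 & diff(v[idx]) == 0))
    plateau_runs <- split(idx, cumsum(keep))
    idx <- vapply(plateau_runs, function(r) r[ceiling(length(r) / 2)], 0L)
  }
  structure(list(spike_times = traj$times[idx], threshold = threshold),
            class = "spikeTrain")
}

#' @export
print.spikeTrain <- function(x, ...) {
  cat(sprintf("<spikeTrain>  %d spikes (threshold %g mV)\n",
              length(x$spike_times), x$threshold))
  invisible(x)
}

#' Burst descriptive statistics
#'
#' Delimits bursts as maximal runs of spikes separated by inter-spike
#' intervals below `gap`; an ISI of at least `gap` (default 1 s) opens
#' a new burst.  Burst onset is the first spike of a run and burst end
#' the last, so `period_i = duration_i + interburst_i` holds exactly.
#' Coefficients of variation use the sample standard deviation
#' (`n - 1`); with a single period or interval the CV is 0 by
#' convention.
#'
#' @param spikes a `spikeTrain` or numeric vector of spike times (s).
#' @param gap ISI split threshold (s).
#' @return An object of class `burstStats` with onsets, durations,
#'   interburst intervals, periods, `cv_period` and `cv_ibi`.
#' @export
burstStatistics <- function(spikes, gap = 1) {
  st <- if (inherits(spikes, "spikeTrain")) spikes$spike_times else spikes
  if (length(st) < 2)
    stop("insufficient spikes for burst statistics", call. = FALSE)
  isi <- diff(st)
  brk <- which(isi >= gap)
  onsets <- c(st[1], st[brk + 1])
  ends <- c(st[brk], st[length(st)])
  if (length(onsets) < 2)
    stop("insufficient cycles: fewer than 2 bursts", call. = FALSE)
  cv <- function(x) if (length(x) < 2) 0 else sd(x) / mean(x)
  periods <- diff(onsets)
  ibis <- onsets[-1] - ends[-length(ends)]
  structure(list(burst_onsets = onsets, burst_ends = ends,
                 burst_durations = ends - onsets,
                 interburst_intervals = ibis, periods = periods,
                 cv_period = cv(periods), cv_ibi = cv(ibis)),
            class = "burstStats")
}

#' @export
print.burstStats <- function(x, ...) {
  cat(sprintf(paste0("<burstStats>  %d bursts, period %.4g s ",
                     "(CV %.3g), IBI %.4g s (CV %.3g)\n"),
              length(x$burst_onsets), mean(x$periods), x$cv_period,
              mean(x$interburst_intervals), x$cv_ibi))
  invisible(x)
}

#' Classify the activity regime of a settled trace
#'
#' Applies the database classification rules: traces without spikes are
#' silent (subthreshold oscillations count as silent); all inter-spike
#' intervals below 1 s means tonic spiking; at least one ISI of 1 s or
#' more triggers burst statistics, and a coefficient of variation of
#' the period above 5% marks the trace irregular, otherwise bursting.
#' A spiking trace whose membrane potential also dwells above the
#' spike threshold for more than `plateau_window` seconds with at most
#' one detected maximum in that window is flagged plateau-like;
#' spikeless traces are silent regardless of their potential.
#'
#' @param traj a post-transient [trajectory()] (see [settle()]).
#' @param spikes optional precomputed `spikeTrain`.
#' @param threshold spike threshold (mV).
#' @param gap ISI split threshold (s).
#' @param cv_irregular CV-of-period bound above which a trace is
#'   irregular (strict comparison, default 0.05).
#' @param plateau_window minimal suprathreshold dwell time (s) flagging
#'   a plateau.
#' @param v_index membrane-potential column.
#' @return An object of class `regimeLabel` with fields `label` (one of
#'   `"silent"`, `"tonic_spiking"`, `"bursting"`, `"irregular"`,
#'   `"plateau_like"`), `stats` (a `burstStats` or `NULL`) and
#'   `spikes`.
#' @export
classifyRegime <- function(traj, spikes = NULL, threshold = -10, gap = 1,
                           cv_irregular = 0.05, plateau_window = 1,
                           v_index = 1L) {
  if (is.null(spikes)) spikes <- detectSpikes(traj, threshold, v_index)
  st <- spikes$spike_times
  v <- traj$states[, v_index]

  # plateau: a suprathreshold dwell longer than plateau_window holding at
  # most one detected maximum (a dome crest, not a spike cluster), in a
  # trace that does spike elsewhere.  Traces without spikes stay silent
  # regardless of their potential (a depolarized rest state is a silent
  # regime).
  if (length(st) >= 2) {
    above <- v > threshold
    r <- rle(above)
    stops <- cumsum(r$lengths)
    starts <- stops - r$lengths + 1
    for (k in which(r$values)) {
      t0 <- traj$times[starts[k]]; t1 <- traj$times[stops[k]]
      if (t1 - t0 > plateau_window && sum(st >= t0 & st <= t1) <= 1)
        return(structure(list(label = "plateau_like", stats = NULL,
                              spikes = spikes), class = "regimeLabel"))
    }
  }

  if (length(st) == 0)
    return(structure(list(label = "silent", stats = NULL, spikes = spikes),
                     class = "regimeLabel"))
  isi <- diff(st)
  if (length(isi) == 0 || all(isi < gap)) {
    lab <- if (length(st) == 1) "silent" else "tonic_spiking"
    return(structure(list(label = lab, stats = NULL, spikes = spikes),
                     class = "regimeLabel"))
  }
  stats <- burstStatistics(spikes, gap = gap)
  lab <- if (stats$cv_period > cv_irregular) "irregular" else "bursting"
  structure(list(label = lab, stats = stats, spikes = spikes),
            class = "regimeLabel")
}

#' @export
print.regimeLabel <- function(x, ...) {
  cat(sprintf("<regimeLabel>  %s\n", x$label))
  if (!is.null(x$stats)) print(x$stats)
  invisible(x)
}

#' Robust-burster criterion
#'
#' A bursting trace is a robust burster when the coefficient of
#' variation of the period is below 5% and the coefficient of
#' variation of the interburst interval below 10%; plateau-like traces
#' never qualify.
#'
#' @param x a `regimeLabel` (from [classifyRegime()]) or a
#'   `burstStats` object (then assumed to come from a bursting trace).
#' @param cv_period_max,cv_ibi_max strict upper bounds.
#' @return Logical.
#' @export
isRobustBurster <- function(x, cv_period_max = 0.05, cv_ibi_max = 0.10) {
  if (inherits(x, "regimeLabel")) {
    if (x$label != "bursting") return(FALSE)
    x <- x$stats
  }
  stopifnot(inherits(x, "burstStats"))
  x$cv_period < cv_period_max && x$cv_ibi < cv_ibi_max
}

#' Functional half-center-oscillator criterion
#'
#' An HCO is functional when both cells burst regularly (CV of period
#' below 5%) and their activity is balanced: the mean relative phase of
#' one cell's burst onsets within the other's burst cycles falls in
#' [0.45, 0.55].  The phase of a cycle `[t_i, t_{i+1})` of cell A is
#' `(t_B - t_i) / (t_{i+1} - t_i)` for each B onset in the cycle.
#'
#' @param spikes_a,spikes_b `spikeTrain`s (or numeric spike times) of
#'   the two cells; both must classify as bursting.
#' @param gap ISI split threshold (s).
#' @param phase_range admissible phase interval.
#' @param cv_max CV-of-period bound.
#' @return A list with `functional` (logical), `phase`, `cv_a`, `cv_b`.
#' @export
hcoFunctional <- function(spikes_a, spikes_b, gap = 1,
                          phase_range = c(0.45, 0.55), cv_max = 0.05) {
  sa <- tryCatch(burstStatistics(spikes_a, gap = gap), error = function(e) NULL)
  sb <- tryCatch(burstStatistics(spikes_b, gap = gap), error = function(e) NULL)
  if (is.null(sa) || is.null(sb))
    stop("both spike trains must exhibit bursting", call. = FALSE)
  oa <- sa$burst_onsets; ob <- sb$burst_onsets
  ph <- c()
  for (i in seq_len(length(oa) - 1)) {
    inb <- ob[ob >= oa[i] & ob < oa[i + 1]]
    if (length(inb))
      ph <- c(ph, (inb - oa[i]) / (oa[i + 1] - oa[i]))
  }
  phase <- if (length(ph)) mean(ph) else NA_real_
  ok <- sa$cv_period < cv_max && sb$cv_period < cv_max &&
    !is.na(phase) && phase >= phase_range[1] - 1e-9 &&
    phase <= phase_range[2] + 1e-9
  list(functional = ok, phase = phase,
       cv_a = sa$cv_period, cv_b = sb$cv_period)
}
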