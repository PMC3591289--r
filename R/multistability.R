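#' Coexistence ranges of attracting regimes
#'
#' Intersects the leak-conductance ranges supporting robust bursting
#' and stable stationary states and returns the maximal parameter
#' ranges over which a constant set of at least two regimes coexists,
#' sorted by left edge.  Stationary-stationary coexistences (e.g.
#' `dep1` with `dep2`) are included alongside bursting-stationary
#' ones.  Intervals are treated as closed; zero-width overlaps are
#' kept only when `keep_points = TRUE` (they are excluded from
#' prevalence either way).
#'
#' @param intervals list of `stableInterval` objects (or lists with
#'   `label`, `p_lo`, `p_hi`).
#' @param bursting optional `burstingRange` (or list with `g_min`,
#'   `g_max`).
#' @param keep_points keep zero-width (single point) overlaps.
#' @return A list of `coexistenceRange` objects (fields `p_lo`,
#'   `p_hi`, `regimes` (sorted character vector), `order`).
#' @export
coexistenceRanges <- function(intervals, bursting = NULL,
                              keep_points = FALSE) {
  regs <- lapply(intervals, function(s)
    list(label = s$label, lo = s$p_lo, hi = s$p_hi))
  if (!is.null(bursting))
    regs[[length(regs) + 1]] <- list(label = "bursting",
                                     lo = bursting$g_min, hi = bursting$g_max)
  if (length(regs) < 2) return(list())
  edges <- sort(unique(c(vapply(regs, `[[`, 0, "lo"),
                         vapply(regs, `[[`, 0, "hi"))))
  edges <- edges[is.finite(edges) | edges > 0]  # keep +Inf as last edge
  out <- list()
  flush <- function(lo, hi, set) {
    if (length(set) < 2) return()
    if (hi <= lo && !keep_points) return()
    out[[length(out) + 1]] <<- structure(
      list(p_lo = lo, p_hi = hi, regimes = sort(set),
           order = length(set)),
      class = "coexistenceRange")
  }
  cur_set <- NULL; cur_lo <- NA_real_
  for (i in seq_len(length(edges) - 1)) {
    lo <- edges[i]; hi <- edges[i + 1]
    mid <- if (is.finite(hi)) (lo + hi) / 2 else lo + 1
    set <- vapply(regs, function(r) r$lo <= mid && mid <= r$hi, TRUE)
    set <- sort(vapply(regs[set], `[[`, "", "label"))
    if (identical(set, cur_set)) next
    if (!is.null(cur_set)) flush(cur_lo, lo, cur_set)
    cur_set <- set; cur_lo <- lo
  }
  if (!is.null(cur_set)) flush(cur_lo, edges[length(edges)], cur_set)
  if (keep_points) {
    # single-point intersections at shared endpoints (diagnostics only)
    for (e in edges[is.finite(edges)]) {
      at <- vapply(regs, function(r) r$lo <= e && e <= r$hi, TRUE)
      set <- sort(vapply(regs[at], `[[`, "", "label"))
      if (length(set) >= 2 &&
          !any(vapply(out, function(o)
            o$p_lo <= e && e <= o$p_hi &&
              all(set %in% o$regimes), TRUE)))
        flush(e, e, set)
    }
  }
  out[order(vapply(out, `[[`, 0, "p_lo"))]
}

#' @export
print.coexistenceRange <- function(x, ...) {
  cat(sprintf("<coexistenceRange>  [%.6g, %.6g] nS: {%s}\n",
              x$p_lo, x$p_hi, paste(x$regimes, collapse = ", ")))
  invisible(x)
}

# canonical signature of a multiset of regime sets
scenarioSignature <- function(ranges) {
  sets <- vapply(ranges, function(r) paste(r$regimes, collapse = "+"), "")
  paste(sort(sets), collapse = " | ")
}

scenarioTable <- local({
  sig <- function(...) paste(sort(vapply(list(...), function(s)
    paste(sort(s), collapse = "+"), "")), collapse = " | ")
  tab <- c(
    A = sig(c("bursting", "hyp1")),
    B = sig(c("bursting", "hyp2")),
    C = sig(c("bursting", "hyp1"), c("dep1", "dep2")),
    D = sig(c("bursting", "hyp1"), c("bursting", "dep1")),
    E = sig(c("hyp1", "dep1"), c("dep1", "bursting")),
    F = sig(c("dep1", "dep2"), c("dep1", "bursting"), c("hyp1", "bursting")),
    G = sig(c("bursting", "hyp1", "dep1"), c("hyp1", "dep1"),
            c("dep1", "bursting")),
    H = sig(c("bursting", "hyp1", "dep1"), c("hyp1", "bursting"),
            c("dep1", "bursting")),
    I = sig(c("bursting", "hyp1", "dep1"), c("hyp1", "dep1"),
            c("dep1", "bursting"), c("dep1", "dep2")),
    J = sig(c("bursting", "hyp1", "dep1"), c("hyp1", "dep1"),
            c("hyp1", "dep1")))
  tab
})

#' Classify the multistability scenario of a case
#'
#' Maps the multiset of coexisting-regime sets onto the ten canonical
#' arrangements (A-J) observed across the screened cohort: single
#' bistable ranges of bursting with `hyp1` (A) or `hyp2` (B); pairs of
#' bistable ranges (C, D, E); three bistable ranges (F); a tristable
#' range with two bistable companions (G, H, J); and a tristable range
#' with three bistable companions (I).  Cases with no coexistence map
#' to `"none"`; any other pattern maps to `"unclassified"` with the
#' raw signature attached.
#'
#' @param ranges output of [coexistenceRanges()].
#' @return An object of class `scenarioClass` with fields `class` and
#'   `signature`.
#' @export
classifyScenario <- function(ranges) {
  if (!length(ranges))
    return(structure(list(class = "none", signature = ""),
                     class = "scenarioClass"))
  sig <- scenarioSignature(ranges)
  hit <- names(scenarioTable)[match(sig, scenarioTable)]
  structure(list(class = if (is.na(hit)) "unclassified" else hit,
                 signature = sig),
            class = "scenarioClass")
}

#' @export
print.scenarioClass <- function(x, ...) {
  cat(sprintf("<scenarioClass %s>  %s\n", x$class,
              if (nzchar(x$signature)) x$signature else "(no coexistence)"))
  invisible(x)
}

#' Prevalence of multistability over the bursting range
#'
#' Fraction of the leak-conductance range supporting robust bursting
#' over which bursting coexists with at least one stable stationary
#' state: the total length of the union of bursting-containing
#' coexistence ranges divided by the bursting-range width.
#' Stationary-only coexistences do not enter the numerator.
#'
#' @param bursting a `burstingRange` (width must be positive).
#' @param ranges output of [coexistenceRanges()].
#' @return Fraction in [0, 1].
#' @export
prevalenceOfMultistability <- function(bursting, ranges) {
  width <- bursting$g_max - bursting$g_min
  if (width <= 0)
    stop("bursting range has zero width; prevalence undefined", call. = FALSE)
  keep <- Filter(function(r) "bursting" %in% r$regimes, ranges)
  if (!length(keep)) return(0)
  segs <- lapply(keep, function(r)
    c(max(r$p_lo, bursting$g_min), min(r$p_hi, bursting$g_max)))
  segs <- Filter(function(s) s[2] > s[1], segs)
  if (!length(segs)) return(0)
  m <- do.call(rbind, segs)
  m <- m[order(m[, 1]), , drop = FALSE]
  total <- 0; cur <- m[1, ]
  for (i in seq_len(nrow(m))[-1]) {
    if (m[i, 1] <= cur[2]) cur[2] <- max(cur[2], m[i, 2])
    else { total <- total + cur[2] - cur[1]; cur <- m[i, ] }
  }
  total <- total + cur[2] - cur[1]
  total / width
}

#' Cohort summary of prevalence values
#'
#' Mean and sample standard deviation of per-case prevalences, plus
#' the outlier-adjusted statistics computed on the subset of cases
#' whose prevalence does not exceed twice the raw mean.
#'
#' @param values numeric vector of prevalences in [0, 1] (nonempty).
#' @return An object of class `prevalenceSummary` with `mean`, `sd`,
#'   `adjusted_mean`, `adjusted_sd`, `n`, `n_excluded` and the
#'   exclusion `threshold`.
#' @export
summarizePrevalence <- function(values) {
  if (!length(values)) stop("no prevalence values supplied", call. = FALSE)
  if (any(values < 0 | values > 1))
    stop("prevalence values must lie in [0, 1]", call. = FALSE)
  mu <- mean(values)
  thr <- 2 * mu
  keep <- values <= thr
  structure(list(mean = mu,
                 sd = if (length(values) > 1) sd(values) else 0,
                 threshold = thr,
                 adjusted_mean = mean(values[keep]),
                 adjusted_sd = if (sum(keep) > 1) sd(values[keep]) else 0,
                 n = length(values), n_excluded = sum(!keep)),
            class = "prevalenceSummary")
}

#' @export
print.prevalenceSummary <- function(x, ...) {
  cat(sprintf(paste0("<prevalenceSummary>  mean %.4g (sd %.4g), adjusted ",
                     "%.4g (sd %.4g), %d/%d excluded above %.4g\n"),
              x$mean, x$sd, x$adjusted_mean, x$adjusted_sd,
              x$n_excluded, x$n, x$threshold))
  invisible(x)
}

#' Coexistence ranges active at a parameter value
#'
#' @param g parameter value (nS).
#' @param ranges output of [coexistenceRanges()].
#' @return The sublist of ranges whose closed interval contains `g`.
#' @export
multistableAt <- function(g, ranges) {
  Filter(function(r) r$p_lo <= g && g <= r$p_hi, ranges)
}
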