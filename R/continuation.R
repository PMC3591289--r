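#' Refine an equilibrium by Newton iteration
#'
#' Damped Newton refinement of a stationary state, using the model's
#' analytic Jacobian when available.  Eigenvalues of the Jacobian at
#' the solution give the stability flag (stable iff all real parts are
#' negative).
#'
#' @param model an [odeModel()].
#' @param guess finite initial state vector.
#' @param tol convergence tolerance on the vector-field norm
#'   (default 1e-10).
#' @param max_iter Newton iteration cap.
#' @return An object of class `equilibriumPoint` with fields
#'   `parameter` (value of the model's bifurcation parameter, or `NA`),
#'   `state`, `eigenvalues`, `stable`, `fnorm`.
#' @export
findEquilibrium <- function(model, guess, tol = 1e-10, max_iter = 50) {
  y <- as.numeric(guess)
  if (any(!is.finite(y))) stop("guess must be finite", call. = FALSE)
  f <- evalVectorField(model, y)
  for (it in seq_len(max_iter)) {
    if (sqrt(sum(f^2)) < tol) break
    J <- modelJacobian(model, y)
    dy <- tryCatch(solve(J, -f), error = function(e)
      stop("singular Jacobian in Newton iteration", call. = FALSE))
    lambda <- 1
    repeat {
      y_new <- y + lambda * dy
      f_new <- evalVectorField(model, y_new)
      if (sqrt(sum(f_new^2)) < sqrt(sum(f^2)) || lambda < 1 / 64) break
      lambda <- lambda / 2
    }
    y <- y_new; f <- f_new
  }
  if (sqrt(sum(f^2)) >= tol)
    stop(sprintf("Newton did not converge (||f|| = %.3g after %d iterations)",
                 sqrt(sum(f^2)), max_iter), call. = FALSE)
  ev <- eigen(modelJacobian(model, y), only.values = TRUE)$values
  structure(list(parameter = if (!is.null(model$par_name))
                   model$pars[[model$par_name]] else NA_real_,
                 state = y, eigenvalues = ev,
                 stable = max(Re(ev)) < 0, fnorm = sqrt(sum(f^2))),
            class = "equilibriumPoint")
}

#' @export
print.equilibriumPoint <- function(x, ...) {
  cat(sprintf("<equilibriumPoint>  p = %.6g, %s (max Re eig = %.3g), ||f|| = %.2g\n",
              x$parameter, if (x$stable) "stable" else "unstable",
              max(Re(x$eigenvalues)), x$fnorm))
  invisible(x)
}

# parameter-bound helpers -------------------------------------------------

parF <- function(model) {
  pn <- model$par_name
  function(y, p) {
    model$pars[[pn]] <- p
    as.numeric(model$rhs(0, y, model$pars))
  }
}

parJ <- function(model) {
  pn <- model$par_name
  function(y, p) {
    model$pars[[pn]] <- p
    modelJacobian(model, y)
  }
}

parFp <- function(f) function(y, p) {
  dp <- 1e-7 * max(1, abs(p))
  (f(y, p + dp) - f(y, p - dp)) / (2 * dp)
}

#' Pseudo-arclength continuation of an equilibrium branch
#'
#' Follows the curve of stationary states in the model's bifurcation
#' parameter with a secant predictor and a bordered-Newton corrector,
#' so folds are traversed.  Steps adapt within `[step_min, step_max]`
#' (defaults 1e-12 and 0.02 parameter units, budget 4000 points).  The
#' branch may continue into negative parameter values; clipping to the
#' physical domain happens later, in [stableIntervals()].
#'
#' @param model an [odeModel()] with a `par_name`.
#' @param start an `equilibriumPoint` at the current parameter value
#'   (from [findEquilibrium()]).
#' @param direction initial direction of the parameter (+1/-1;
#'   default -1, i.e. decreasing from the large-conductance start).
#' @param step_max,step_min pseudo-arclength step bounds.
#' @param max_points point budget.
#' @param p_outbound stop once the parameter exceeds this value while
#'   moving away from the start.
#' @param p_floor stop once the parameter falls below this value.
#' @param corrector_tol corrector tolerance on the vector-field norm.
#' @return An object of class `branch`: parameter vector `parameter`,
#'   state matrix `states` (rows in arc order), `eigenvalues` (list),
#'   `stable` (logical), `termination` (reason string).
#' @export
continueBranch <- function(model, start, direction = -1,
                           step_max = 0.02, step_min = 1e-12,
                           max_points = 4000, p_outbound = 25,
                           p_floor = -5, corrector_tol = 1e-10) {
  stopifnot(inherits(start, "equilibriumPoint"), !is.null(model$par_name))
  f <- parF(model); Jy <- parJ(model); fp <- parFp(f)
  n <- length(start$state)

  pts_p <- numeric(0); pts_y <- NULL
  eigs <- list(); stab <- logical(0)
  addPoint <- function(y, p) {
    ev <- eigen(Jy(y, p), only.values = TRUE)$values
    pts_p[length(pts_p) + 1] <<- p
    pts_y <<- rbind(pts_y, y)
    eigs[[length(eigs) + 1]] <<- ev
    stab[length(stab) + 1] <<- max(Re(ev)) < 0
  }

  y <- start$state; p <- start$parameter
  addPoint(y, p)

  # initial tangent from the Jacobian bordered with the parameter column
  dydp <- tryCatch(solve(Jy(y, p), -fp(y, p)), error = function(e) rep(0, n))
  tg <- c(dydp, 1); tg <- tg / sqrt(sum(tg^2))
  if (sign(tg[n + 1]) != sign(direction)) tg <- -tg

  h <- step_max
  termination <- "max_points"
  while (length(pts_p) < max_points) {
    u <- c(y, p)
    ok <- FALSE
    while (!ok) {
      upred <- u + h * tg
      sol <- newtonBordered(f, Jy, fp, upred, tg, upred, corrector_tol)
      if (sol$converged) {
        ok <- TRUE
      } else {
        h <- h / 2
        if (h < step_min) break
      }
    }
    if (!ok) { termination <- "corrector_failure"; break }
    u_new <- sol$u
    step_vec <- u_new - u
    tg <- step_vec / sqrt(sum(step_vec^2))
    y <- u_new[seq_len(n)]; p <- u_new[n + 1]
    addPoint(y, p)
    if (sol$iterations <= 3) h <- min(h * 1.4, step_max)
    if (p > p_outbound && tg[n + 1] > 0) { termination <- "outbound"; break }
    if (p < p_floor && tg[n + 1] < 0) { termination <- "floor"; break }
  }

  structure(list(parameter = pts_p, states = unname(pts_y),
                 eigenvalues = eigs, stable = stab,
                 par_name = model$par_name, model_name = model$name,
                 start_parameter = start$parameter,
                 termination = termination),
            class = "branch")
}

# corrector for the bordered system [f(y,p); t.(u - uref)] = 0
newtonBordered <- function(f, Jy, fp, u0, tg, uref, tol, max_iter = 10) {
  n <- length(u0) - 1
  u <- u0
  for (it in seq_len(max_iter)) {
    y <- u[seq_len(n)]; p <- u[n + 1]
    fv <- f(y, p)
    res <- c(fv, sum(tg * (u - uref)))
    if (sqrt(sum(fv^2)) < tol && abs(res[n + 1]) < 1e-12)
      return(list(u = u, converged = TRUE, iterations = it - 1))
    Jb <- rbind(cbind(Jy(y, p), fp(y, p)), tg)
    du <- tryCatch(solve(Jb, -res), error = function(e) NULL)
    if (is.null(du) || any(!is.finite(du)))
      return(list(u = u, converged = FALSE, iterations = it))
    u <- u + du
  }
  list(u = u, converged = FALSE, iterations = max_iter)
}

#' @export
print.branch <- function(x, ...) {
  cat(sprintf(paste0("<branch>  %d points in '%s' from %.6g ",
                     "(range %.6g .. %.6g), %d stable; terminated: %s\n"),
              length(x$parameter), x$par_name, x$start_parameter,
              min(x$parameter), max(x$parameter), sum(x$stable),
              x$termination))
  invisible(x)
}

# bifurcation test functions ----------------------------------------------

testLP <- function(ev) Re(prod(ev))                 # ~ det(J): one real zero
testAH <- function(ev) {                            # bialternate-style scalar
  n <- length(ev)
  if (n < 2) return(1)
  s <- 1
  for (i in seq_len(n - 1))
    for (j in (i + 1):n)
      s <- s * (ev[i] + ev[j])
  Re(s)
}

#' Detect fold and Andronov-Hopf bifurcations along a branch
#'
#' Scans consecutive branch points for sign changes of two test
#' functions -- the product of eigenvalues (zero at a fold, LP) and the
#' product of all pairwise eigenvalue sums (zero at a Hopf point, AH) --
#' and localizes each crossing on the curve by bisection with
#' pseudo-arclength correction, to a parameter gap below `tol_p`
#' (default 1e-8).  A candidate AH whose crossing eigenvalue pair has
#' an imaginary part below `im_min` is a neutral saddle and is
#' discarded.  Labels (`LP1`, `AH1`, ...) follow arc-length order.
#'
#' @param branch a [continueBranch()] result.
#' @param model the model the branch was computed on.
#' @param tol_p localization tolerance on the parameter (nS).
#' @param im_min minimal imaginary part for a genuine Hopf pair.
#' @return A list of `bifurcationPoint` objects (fields `kind`,
#'   `label`, `parameter`, `state`, `eigenvalues`, `arc_index`).
#' @export
detectBifurcations <- function(branch, model, tol_p = 1e-8, im_min = 1e-4) {
  stopifnot(inherits(branch, "branch"))
  if (length(branch$parameter) < 2)
    stop("branch needs at least 2 points", call. = FALSE)
  f <- parF(model); Jy <- parJ(model); fp <- parFp(f)
  m <- length(branch$parameter)
  lp_vals <- vapply(branch$eigenvalues, testLP, 0)
  ah_vals <- vapply(branch$eigenvalues, testAH, 0)

  found <- list()
  for (i in seq_len(m - 1)) {
    u1 <- c(branch$states[i, ], branch$parameter[i])
    u2 <- c(branch$states[i + 1, ], branch$parameter[i + 1])
    if (lp_vals[i] * lp_vals[i + 1] < 0) {
      loc <- localizeOnCurve(f, Jy, fp, u1, u2, testLP, tol_p)
      if (!is.null(loc))
        found[[length(found) + 1]] <-
          list(kind = "LP", parameter = loc$p, state = loc$y,
               eigenvalues = loc$ev, arc_index = i + loc$frac)
    }
    if (ah_vals[i] * ah_vals[i + 1] < 0) {
      loc <- localizeOnCurve(f, Jy, fp, u1, u2, testAH, tol_p)
      if (!is.null(loc)) {
        # the crossing pair: complex pair with smallest |Re|
        cplx <- loc$ev[abs(Im(loc$ev)) > 0]
        genuine <- length(cplx) > 0 &&
          abs(Im(cplx[which.min(abs(Re(cplx)))])) > im_min
        if (genuine)
          found[[length(found) + 1]] <-
            list(kind = "AH", parameter = loc$p, state = loc$y,
                 eigenvalues = loc$ev, arc_index = i + loc$frac)
      }
    }
  }
  if (!length(found)) return(list())
  ord <- order(vapply(found, `[[`, 0, "arc_index"))
  found <- found[ord]
  counts <- c(LP = 0L, AH = 0L)
  for (k in seq_along(found)) {
    kind <- found[[k]]$kind
    counts[kind] <- counts[kind] + 1L
    found[[k]]$label <- paste0(kind, counts[kind])
    class(found[[k]]) <- "bifurcationPoint"
  }
  found
}

#' @export
print.bifurcationPoint <- function(x, ...) {
  cat(sprintf("<bifurcationPoint %s>  %s at parameter %.8g\n",
              x$label, x$kind, x$parameter))
  invisible(x)
}

# bisection along the curve between two consecutive branch points
localizeOnCurve <- function(f, Jy, fp, u1, u2, testfun, tol_p,
                            max_iter = 80) {
  n <- length(u1) - 1
  evAt <- function(u) eigen(Jy(u[seq_len(n)], u[n + 1]),
                            only.values = TRUE)$values
  t1 <- testfun(evAt(u1))
  frac_lo <- 0; frac_hi <- 1
  for (it in seq_len(max_iter)) {
    if (abs(u1[n + 1] - u2[n + 1]) < tol_p &&
        sqrt(sum((u1 - u2)^2)) < 1e-6) break
    tsec <- (u2 - u1) / sqrt(sum((u2 - u1)^2))
    um <- (u1 + u2) / 2
    sol <- newtonBordered(f, Jy, fp, um, tsec, um, 1e-10)
    if (!sol$converged) return(NULL)
    tm <- testfun(evAt(sol$u))
    if (t1 * tm <= 0) {
      u2 <- sol$u; frac_hi <- (frac_lo + frac_hi) / 2
    } else {
      u1 <- sol$u; t1 <- tm; frac_lo <- (frac_lo + frac_hi) / 2
    }
  }
  um <- (u1 + u2) / 2
  list(y = um[seq_len(n)], p = um[n + 1], ev = evAt(um),
       frac = (frac_lo + frac_hi) / 2)
}

#' Stable intervals of a branch, labeled hyp/dep
#'
#' Extracts the maximal stable sub-arcs of a branch, classifies each as
#' hyperpolarized (`hyp`, membrane potential below -35 mV) or
#' depolarized (`dep`, above -35 mV), splits arcs that straddle the
#' threshold at the crossing, and numbers intervals of each type in
#' arc-length order (so `hyp1` contains the branch start when the
#' start is stable).  Interval ends refined by detected bifurcations
#' use the localized bifurcation parameter.  Parameter ranges are
#' clipped to `[clip_min, Inf)`; the interval containing the branch
#' start is reported as unbounded above, reflecting the assumption
#' that a sufficiently large leak conductance always yields a stable
#' rest state.
#'
#' @param branch a [continueBranch()] result.
#' @param bifurcations output of [detectBifurcations()] (may be empty).
#' @param v_threshold hyp/dep split (mV, default -35).
#' @param v_index membrane-potential column of the state.
#' @param clip_min lower clip of reported ranges (default 0 nS).
#' @return A list of `stableInterval` objects (fields `label`, `kind`,
#'   `p_lo`, `p_hi`, `v_rep`, `arc_range`).
#' @export
stableIntervals <- function(branch, bifurcations = list(),
                            v_threshold = -35, v_index = 1L,
                            clip_min = 0) {
  stopifnot(inherits(branch, "branch"))
  m <- length(branch$parameter)
  stab <- branch$stable
  if (!any(stab)) return(list())
  v <- branch$states[, v_index]
  p <- branch$parameter
  bif_pos <- vapply(bifurcations, `[[`, 0, "arc_index")
  bif_par <- vapply(bifurcations, `[[`, 0, "parameter")

  # boundary parameter of a stability change between arc points i, i+1
  edgePar <- function(i) {
    hit <- which(bif_pos > i & bif_pos < i + 1)
    if (length(hit)) bif_par[hit[1]] else (p[i] + p[i + 1]) / 2
  }

  r <- rle(stab)
  stops <- cumsum(r$lengths); starts <- stops - r$lengths + 1
  segs <- list()
  for (k in which(r$values)) {
    i0 <- starts[k]; i1 <- stops[k]
    idx <- i0:i1
    # split at hyp/dep threshold crossings inside the arc
    side <- v[idx] > v_threshold
    rr <- rle(side)
    sstop <- cumsum(rr$lengths); sstart <- sstop - rr$lengths + 1
    for (j in seq_along(rr$values)) {
      sub <- idx[sstart[j]:sstop[j]]
      plo <- min(p[sub]); phi <- max(p[sub])
      # extend to refined boundaries
      if (sstart[j] == 1 && i0 > 1) {
        bp <- edgePar(i0 - 1); plo <- min(plo, bp); phi <- max(phi, bp)
      }
      if (sstop[j] == length(idx) && i1 < m) {
        bp <- edgePar(i1); plo <- min(plo, bp); phi <- max(phi, bp)
      }
      segs[[length(segs) + 1]] <- list(
        kind = if (rr$values[j]) "dep" else "hyp",
        p_lo = plo, p_hi = phi,
        v_rep = v[sub[ceiling(length(sub) / 2)]],
        arc_range = range(sub),
        contains_start = 1 %in% sub)
    }
  }
  # number in arc order; unbounded above if containing the branch start
  counts <- c(hyp = 0L, dep = 0L)
  out <- list()
  for (s in segs) {
    if (s$contains_start) s$p_hi <- Inf
    if (s$p_hi < clip_min) next
    s$p_lo <- max(s$p_lo, clip_min)
    counts[s$kind] <- counts[s$kind] + 1L
    s$label <- paste0(s$kind, counts[s$kind])
    s$contains_start <- NULL
    class(s) <- "stableInterval"
    out[[length(out) + 1]] <- s
  }
  out
}

#' @export
print.stableInterval <- function(x, ...) {
  cat(sprintf("<stableInterval %s>  [%.6g, %.6g] nS, V ~ %.3g mV\n",
              x$label, x$p_lo, x$p_hi, x$v_rep))
  invisible(x)
}

#' Branch as a data frame
#'
#' @param branch a [continueBranch()] result.
#' @return Data frame with point index, parameter, state components,
#'   largest real eigenvalue part and stability flag.
#' @export
branchToDataFrame <- function(branch) {
  data.frame(index = seq_along(branch$parameter),
             parameter = branch$parameter,
             branch$states,
             max_re_eig = vapply(branch$eigenvalues,
                                 function(e) max(Re(e)), 0),
             stable = branch$stable)
}
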