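#' Fold (saddle-node) normal form
#'
#' One-dimensional surrogate `x' = (mu - mu_c) - x^2` with an exact
#' fold at `mu = mu_c` and equilibria `x = +-sqrt(mu - mu_c)`.
#'
#' @param mu_c fold location.
#' @param mu initial parameter value.
#' @return An [odeModel()] with `ground_truth$LP = mu_c` in its meta.
#' @export
makeFoldModel <- function(mu_c = 0, mu = mu_c + 1) {
  odeModel(name = sprintf("fold(mu_c=%g)", mu_c),
           rhs = function(t, y, p) (p$mu - mu_c) - y[1]^2,
           jac = function(t, y, p) matrix(-2 * y[1], 1, 1),
           pars = list(mu = mu), state_names = "x", par_name = "mu",
           meta = list(ground_truth = list(LP = mu_c)))
}

#' Hopf normal form
#'
#' Two-dimensional supercritical Hopf normal form with equilibrium at
#' the origin for every `mu` and eigenvalues
#' `(mu - mu_c) +- i omega`; the post-Hopf limit cycle has amplitude
#' `sqrt(mu - mu_c)`.
#'
#' @param mu_c Hopf location.
#' @param omega angular frequency (> 0).
#' @param mu initial parameter value.
#' @return An [odeModel()] with `ground_truth$AH = mu_c`.
#' @export
makeHopfModel <- function(mu_c = 0, omega = 1, mu = mu_c + 1) {
  stopifnot(omega > 0)
  odeModel(name = sprintf("hopf(mu_c=%g, omega=%g)", mu_c, omega),
           rhs = function(t, y, p) {
             a <- p$mu - mu_c
             r2 <- y[1]^2 + y[2]^2
             c(a * y[1] - omega * y[2] - y[1] * r2,
               omega * y[1] + a * y[2] - y[2] * r2)
           },
           jac = function(t, y, p) {
             a <- p$mu - mu_c
             matrix(c(a - 3 * y[1]^2 - y[2]^2, -omega - 2 * y[1] * y[2],
                      omega - 2 * y[1] * y[2], a - y[1]^2 - 3 * y[2]^2),
                    2, 2, byrow = TRUE)
           },
           pars = list(mu = mu), state_names = c("x", "y"), par_name = "mu",
           meta = list(ground_truth = list(AH = mu_c, omega = omega)))
}

#' Two-dimensional relaxation oscillator
#'
#' FitzHugh-Nagumo-type surrogate
#' `v' = v - v^3/3 - w + mu`, `w' = eps (v + a0 - b0 w)` whose
#' equilibrium loses stability through an Andronov-Hopf bifurcation as
#' the drive `mu` grows.  The Hopf location has no simple closed form;
#' it is checked against the eigenvalue-scan oracle
#' ([equilibriumScanOracle()]).
#'
#' @param eps time-scale separation.
#' @param a0,b0 recovery-nullcline parameters.
#' @param mu initial drive.
#' @return An [odeModel()].
#' @export
makeRelaxationModel <- function(eps = 0.08, a0 = 0.7, b0 = 0.8, mu = 0) {
  m <- odeModel(name = sprintf("relaxation(eps=%g)", eps),
                rhs = function(t, y, p)
                  c(y[1] - y[1]^3 / 3 - y[2] + p$mu,
                    eps * (y[1] + a0 - b0 * y[2])),
                jac = function(t, y, p)
                  matrix(c(1 - y[1]^2, -1, eps, -eps * b0), 2, 2,
                         byrow = TRUE),
                pars = list(mu = mu), state_names = c("v", "w"),
                par_name = "mu")
  m$meta$equilibrium <- function(p) {
    # v - v^3/3 - (v + a0)/b0 + p = 0, strictly decreasing cubic in v
    fr <- function(v) v - v^3 / 3 - (v + a0) / b0 + p
    v <- uniroot(fr, c(-10, 10), tol = 1e-14)$root
    c(v, (v + a0) / b0)
  }
  m
}

#' Eigenvalue-scan oracle for a stability change
#'
#' Brute-force oracle independent of the continuation code path: the
#' equilibrium is computed from the model's own closed-form or
#' root-solved equilibrium map, the leading real part of the Jacobian
#' spectrum is scanned on a parameter bracket, and the crossing is
#' polished by bisection.
#'
#' @param model an [odeModel()] whose `meta$equilibrium(p)` returns the
#'   equilibrium state at parameter `p`.
#' @param p_lo,p_hi bracket (leading real part must change sign).
#' @param tol bisection tolerance on the parameter.
#' @return Parameter value of the stability change.
#' @export
equilibriumScanOracle <- function(model, p_lo, p_hi, tol = 1e-10) {
  eqf <- model$meta$equilibrium
  if (is.null(eqf)) stop("model has no equilibrium map", call. = FALSE)
  maxre <- function(p) {
    m <- setModelPar(model, p)
    y <- eqf(p)
    max(Re(eigen(modelJacobian(m, y), only.values = TRUE)$values))
  }
  uniroot(maxre, c(p_lo, p_hi), tol = tol)$root
}

# frozen coefficients of the fast-slow surrogate burster
bursterConstants <- function() {
  list(kappa = 50, a = 1, b = 3, c = 1, d = 5, r = 0.002, s = 4,
       xR = -1.6, I0 = 1.65, q = 0.05, vsc = 20, voff = -20)
}

bursterParmsVector <- function(pars) {
  with(pars, c(kappa, a, b, c, d, r, s, xR, I0, q, g, vsc, voff))
}

#' Minimal fast-slow endogenous burster
#'
#' Three-dimensional surrogate burster: a cubic (Hindmarsh-Rose-type)
#' fast subsystem plus a slow linear recovery variable, mapped onto
#' membrane-potential units (`V = 20 x - 20` mV) and real time (one
#' second is 50 fast-subsystem time units), with a leak-like parameter
#' `g` entering the drive as `I = 1.65 - 0.05 g`.  Along `g` the model
#' shows robust square-wave bursting from the domain edge `g = 0` up
#' to the disappearance of the bursting attractor near `g ~ 7.55`, a
#' single equilibrium branch whose rest state (near -46 mV, i.e.
#' hyperpolarized) becomes stable at an Andronov-Hopf bifurcation near
#' `g ~ 7.24`, and silence beyond -- hence a coexistence window of
#' bursting with `hyp1` at the top of the bursting range.
#'
#' The model ships a compiled right-hand side for long settling runs
#' and an analytic Jacobian for continuation.  Its manifest carries
#' the Andronov-Hopf location recomputed at construction time by the
#' eigenvalue-scan oracle, plus the dense-scan provenance for the
#' bursting-range ground truth (recomputed by the oracle in tests).
#'
#' @param g initial leak-like conductance (nS).
#' @return An [odeModel()] with `meta$manifest`.
#' @export
makeMinimalBurster <- function(g = 3) {
  cst <- bursterConstants()
  pars <- c(cst, list(g = g))
  rhs <- function(t, y, p) {
    x <- (y[1] - p$voff) / p$vsc
    I <- p$I0 - p$q * p$g
    c(p$kappa * p$vsc * (y[2] - p$a * x^3 + p$b * x^2 - y[3] + I),
      p$kappa * (p$c - p$d * x^2 - y[2]),
      p$kappa * p$r * (p$s * (x - p$xR) - y[3]))
  }
  jac <- function(t, y, p) {
    x <- (y[1] - p$voff) / p$vsc
    K <- p$kappa
    matrix(c(K * (-3 * p$a * x^2 + 2 * p$b * x), K * p$vsc, -K * p$vsc,
             -2 * K * p$d * x / p$vsc, -K, 0,
             K * p$r * p$s / p$vsc, 0, -K * p$r),
           3, 3, byrow = TRUE)
  }
  m <- odeModel(name = sprintf("minimalBurster(g=%g)", g),
                rhs = rhs, jac = jac, pars = pars,
                state_names = c("V", "y", "z"), par_name = "g",
                compiled = list(func = "burster_derivs",
                                initfunc = "burster_init",
                                dllname = "burstscan",
                                parms = bursterParmsVector))
  m$meta$equilibrium <- function(p) bursterEquilibrium(p, cst)
  ah <- equilibriumScanOracle(m, 5, 10)
  m$meta$manifest <- list(
    AH = ah,
    rest_V = bursterEquilibrium(ah, cst)[1],
    scan_start_g = 3,
    bursting_range_reference = c(g_min = 0, g_max = 7.6245),
    coexistence_reference = c(lo = ah, hi = 7.6245),
    oracle = list(
      AH = "eigenvalue bisection on the closed-form equilibrium, tol 1e-10",
      bursting_range = paste("carry-over dense scan, full 400 s settles,",
                             "1e-5 nS grid near the boundary;",
                             "recomputed by denseBoundaryOracle() in tests")))
  m
}

#' Closed-form equilibrium of the surrogate burster
#'
#' The burster's stationary state solves a strictly decreasing cubic in
#' the dimensionless fast variable, so it is unique for every `g` and
#' computable without integration -- the anchor for the eigenvalue-scan
#' oracle.
#'
#' @param g leak-like conductance (nS).
#' @param cst coefficient set (internal default).
#' @return Named state vector `(V, y, z)`.
#' @export
bursterEquilibrium <- function(g, cst = bursterConstants()) {
  I <- cst$I0 - cst$q * g
  ro <- polyroot(c(cst$c + cst$s * cst$xR + I, -cst$s, cst$b - cst$d, -cst$a))
  x <- Re(ro[abs(Im(ro)) < 1e-8])
  if (length(x) != 1)
    stop("expected a unique equilibrium; got ", length(x), call. = FALSE)
  y <- cst$c - cst$d * x^2
  z <- cst$s * (x - cst$xR)
  c(V = cst$vsc * x + cst$voff, y = y, z = z)
}

#' Half-center oscillator of two surrogate bursters
#'
#' Couples two minimal bursters through reciprocal graded inhibition
#' (first-order synaptic gates driven by the presynaptic potential).
#' State layout: `V1, y1, z1, V2, y2, z2, s1, s2` where `s_i` gates
#' the inhibition from cell i onto the other cell.
#'
#' @param g_a,g_b leak-like conductances of the two cells (nS).
#' @param gs synaptic strength (fast-subsystem current units).
#' @param tau_s synaptic time constant (fast-subsystem time units).
#' @param xrev,xth,xsig synaptic reversal, activation threshold and
#'   slope on the dimensionless fast variable (`x = (V + 20)/20`).
#' @return An `hcoModel` with a compiled right-hand side.
#' @export
makeBursterHCO <- function(g_a, g_b, gs = 1.0, tau_s = 20,
                           xrev = -2.125, xth = 0, xsig = 0.15) {
  cst <- bursterConstants()
  pars <- c(cst, list(g1 = g_a, g2 = g_b, gs = gs, xrev = xrev,
                      xth = xth, xsig = xsig, taus = tau_s))
  rhs <- function(t, y, p) {
    x1 <- (y[1] - p$voff) / p$vsc
    x2 <- (y[4] - p$voff) / p$vsc
    sinf <- function(x) 1 / (1 + exp(-(x - p$xth) / p$xsig))
    i1 <- p$gs * y[8] * (x1 - p$xrev)
    i2 <- p$gs * y[7] * (x2 - p$xrev)
    K <- p$kappa
    c(K * p$vsc * (y[2] - p$a * x1^3 + p$b * x1^2 - y[3] + (p$I0 - p$q * p$g1) - i1),
      K * (p$c - p$d * x1^2 - y[2]),
      K * p$r * (p$s * (x1 - p$xR) - y[3]),
      K * p$vsc * (y[5] - p$a * x2^3 + p$b * x2^2 - y[6] + (p$I0 - p$q * p$g2) - i2),
      K * (p$c - p$d * x2^2 - y[5]),
      K * p$r * (p$s * (x2 - p$xR) - y[6]),
      K * (sinf(x1) - y[7]) / p$taus,
      K * (sinf(x2) - y[8]) / p$taus)
  }
  parms_fn <- function(pars) with(pars, c(kappa, a, b, c, d, r, s, xR, I0, q,
                                          vsc, voff, g1, g2, gs, xrev, xth,
                                          xsig, taus))
  m <- odeModel(name = sprintf("bursterHCO(g=%g/%g, gs=%g)", g_a, g_b, gs),
                rhs = rhs, pars = pars,
                state_names = c("V_a", "y_a", "z_a", "V_b", "y_b", "z_b",
                                "s_a", "s_b"),
                compiled = list(func = "hco_derivs", initfunc = "hco_init",
                                dllname = "burstscan", parms = parms_fn),
                meta = list(cell_idx = list(1:3, 4:6), v_idx = c(1L, 4L),
                            syn_idx = 7:8, cell_g = c(g_a, g_b)))
  class(m) <- c("hcoModel", class(m))
  m
}

#' Reference half-center-oscillator fixtures
#'
#' Two frozen HCO configurations with oracle-verified perturbation
#' outcomes.  `"recovered"`: a symmetric pair of bistable bursters
#' (`g = 7.45` nS, inside the bursting/rest coexistence window) with
#' strong slow inhibition (`gs = 1`, `tau_s = 20`); resetting either
#' cell to its rest state is undone by the partner's bursting, which
#' kicks the resting cell back out of the rest basin.
#' `"both_at_rest"`: an asymmetric pair (`g = 7.40` and `7.65` nS, the
#' second cell monostable at rest) with weak inhibition (`gs = 0.3`);
#' resetting the endogenous cell leaves the network-driven partner
#' without drive, and both cells settle into their rest states.
#'
#' The protocol's initial state is the endpoint of a warmup
#' integration from a standard asymmetric state (one cell active, one
#' near rest).
#'
#' @param kind `"recovered"` or `"both_at_rest"`.
#' @return List with `model` (an `hcoModel`), `reset_cell`, `warmup`
#'   (s), `y0` (warmup initial state) and `manifest` (expected
#'   outcome and provenance).
#' @export
hcoFixture <- function(kind = c("recovered", "both_at_rest")) {
  kind <- match.arg(kind)
  cst <- bursterConstants()
  if (kind == "recovered") {
    model <- makeBursterHCO(7.45, 7.45, gs = 1.0, tau_s = 20)
    reset_cell <- 1L
    expected <- "recovered"
  } else {
    model <- makeBursterHCO(7.40, 7.65, gs = 0.3, tau_s = 20)
    reset_cell <- 1L
    expected <- "both_at_rest"
  }
  eq_b <- bursterEquilibrium(model$meta$cell_g[2], cst)
  y0 <- c(-10, 0, 2, eq_b[1] - 0.3 * cst$vsc, eq_b[2], eq_b[3], 0, 0)
  list(model = model, reset_cell = reset_cell, warmup = 150, y0 = y0,
       manifest = list(
         outcome = expected,
         oracle = paste("full three-phase protocol integrated at the",
                        "settling tolerances; outcome verified at",
                        "fixture-design time and re-verified by the",
                        "acceptance protocol run")))
}

#' Synthesize a voltage trace with prescribed spike timing
#'
#' Piecewise-smooth trace at 1 ms sampling: baseline -50 mV with
#' parabolic spikes (peak 0 mV, half-width 10 ms) exactly at the
#' requested spike times.  Patterns: `tonic` (regular ISI), `burst`
#' (bursts of `n_spikes` at `isi` separated by `gap`, optionally with
#' seeded Gaussian jitter of the burst onsets) and `silent`.
#'
#' @param pattern list describing the pattern: `list(kind = "tonic",
#'   isi, n_spikes)`, `list(kind = "burst", n_spikes, isi, gap,
#'   n_bursts, jitter_sd = 0)` or `list(kind = "silent", duration)`.
#' @param seed RNG seed for jitter (required when `jitter_sd > 0`).
#' @param baseline,peak baseline and spike-peak potentials (mV).
#' @param half_width spike half-width (s).
#' @param dt sampling interval (s).
#' @return List with `traj` (a [trajectory()]), `spike_times` and
#'   `burst_onsets` (ground truth).
#' @export
makeSpikeTrace <- function(pattern, seed = NULL, baseline = -50, peak = 0,
                           half_width = 0.010, dt = 1e-3) {
  kind <- match.arg(pattern$kind, c("tonic", "burst", "silent"))
  onsets <- numeric(0)
  if (kind == "silent") {
    spikes <- numeric(0)
    duration <- pattern$duration %||% 10
  } else if (kind == "tonic") {
    spikes <- pattern$isi * seq_len(pattern$n_spikes)
    duration <- max(spikes) + 0.5
  } else {
    jit <- rep(0, pattern$n_bursts)
    jsd <- pattern$jitter_sd %||% 0
    if (jsd > 0) {
      if (is.null(seed)) stop("jitter requires a seed", call. = FALSE)
      old <- if (exists(".Random.seed", .GlobalEnv))
        get(".Random.seed", .GlobalEnv)
      on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
      set.seed(seed)
      jit <- rnorm(pattern$n_bursts, 0, jsd)
    }
    burst_len <- (pattern$n_spikes - 1) * pattern$isi
    period <- burst_len + pattern$gap
    onsets <- 1 + (seq_len(pattern$n_bursts) - 1) * period + jit
    spikes <- as.vector(outer(0:(pattern$n_spikes - 1) * pattern$isi,
                              onsets, `+`))
    spikes <- sort(spikes)
    duration <- max(spikes) + 0.5
  }
  spikes <- round(spikes / dt) * dt     # align peaks to the sample grid
  if (length(spikes) > 1 && any(diff(spikes) < 2 * half_width))
    stop("overlapping spikes in requested pattern", call. = FALSE)
  times <- seq(0, duration, by = dt)
  v <- rep(baseline, length(times))
  for (t0 in spikes) {
    win <- which(abs(times - t0) <= half_width)
    prof <- peak - (peak - baseline) * ((times[win] - t0) / half_width)^2
    v[win] <- pmax(v[win], prof)
  }
  list(traj = trajectory(times, matrix(v, ncol = 1,
                                       dimnames = list(NULL, "V"))),
       spike_times = spikes,
       burst_onsets = if (length(onsets)) round(onsets / dt) * dt
                      else numeric(0))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
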