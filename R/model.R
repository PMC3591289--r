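#' Declarative single-compartment neuron model
#'
#' Collects membrane currents into a single isopotential compartment.
#' The state layout is the membrane potential `V` (mV) first, followed
#' by every gating variable in the order the currents are listed
#' (activation before inactivation).
#'
#' @param name model identifier.
#' @param capacitance membrane capacitance (nF, > 0).
#' @param currents list of [currentSpec()] objects; a current named
#'   `"leak"` is treated as the leak conductance targeted by
#'   [caseParameters()].
#' @param injected_current constant injected current (nA, default 0).
#'
#' @return An object of class `modelSpec`.
#' @export
modelSpec <- function(name, capacitance, currents, injected_current = 0) {
  stopifnot(is.character(name), capacitance > 0, is.list(currents))
  if (!all(vapply(currents, inherits, TRUE, "currentSpec")))
    stop("currents must be a list of currentSpec objects", call. = FALSE)
  cn <- vapply(currents, `[[`, "", "name")
  if (anyDuplicated(cn))
    stop("duplicate current names: ", paste(cn[duplicated(cn)], collapse = ", "),
         call. = FALSE)
  names(currents) <- cn
  layout <- "V"
  for (cur in currents)
    for (g in list(cur$activation, cur$inactivation))
      if (!is.null(g)) layout <- c(layout, g$name)
  if (anyDuplicated(layout))
    stop("gating-variable names must be unique across currents", call. = FALSE)
  structure(list(name = name, capacitance = capacitance,
                 currents = currents, injected_current = injected_current,
                 state_layout = layout),
            class = "modelSpec")
}

#' One point of the parameter grid
#'
#' A *case* fixes the leak parameters and scales the maximal
#' conductances of named currents relative to their canonical values.
#'
#' @param case_id integer case identifier.
#' @param E_leak leak reversal potential (mV).
#' @param g_leak leak conductance (nS, \eqn{\ge 0} for simulation).
#' @param scale_factors named numeric vector mapping current names to
#'   fractions of the canonical maximal conductance.
#'
#' @return An object of class `caseParameters`.
#' @export
caseParameters <- function(case_id, E_leak, g_leak, scale_factors = numeric()) {
  if (g_leak < 0)
    stop("g_leak must be >= 0 for simulation", call. = FALSE)
  if (length(scale_factors) && is.null(names(scale_factors)))
    stop("scale_factors must be named by current", call. = FALSE)
  if (any(scale_factors < 0))
    stop("scale factors must be >= 0", call. = FALSE)
  structure(list(case_id = as.integer(case_id), E_leak = E_leak,
                 g_leak = g_leak, scale_factors = scale_factors),
            class = "caseParameters")
}

#' General ODE model container
#'
#' Light-weight container used by the integrator, the continuation
#' routines and the range scanner.  `rhs(t, y, pars)` returns the state
#' derivative; `jac(t, y, pars)`, when present, the analytic Jacobian.
#' `par_name` names the entry of `pars` used as the continuation /
#' scanning parameter.  `compiled` optionally points at a compiled
#' right-hand side (deSolve convention) for fast long integrations.
#'
#' @param name model identifier.
#' @param rhs function `(t, y, pars)` returning the derivative vector.
#' @param pars named list of parameters.
#' @param state_names character vector of state names (voltage first
#'   for neuron models).
#' @param jac optional analytic Jacobian function `(t, y, pars)`.
#' @param par_name name of the bifurcation/scan parameter in `pars`.
#' @param compiled optional list `(func, initfunc, dllname, parms)`
#'   where `parms(pars)` returns the numeric parameter block.
#' @param v_index index of the membrane potential in the state vector.
#' @param meta free-form metadata list.
#'
#' @return An object of class `odeModel`.
#' @export
odeModel <- function(name, rhs, pars, state_names, jac = NULL,
                     par_name = NULL, compiled = NULL, v_index = 1L,
                     meta = list()) {
  stopifnot(is.function(rhs), is.list(pars), is.character(state_names))
  if (!is.null(par_name) && !par_name %in% names(pars))
    stop("par_name '", par_name, "' not found in pars", call. = FALSE)
  structure(list(name = name, rhs = rhs, jac = jac, pars = pars,
                 state_names = state_names, par_name = par_name,
                 compiled = compiled, v_index = as.integer(v_index),
                 meta = meta),
            class = "odeModel")
}

#' @export
print.odeModel <- function(x, ...) {
  cat(sprintf("<odeModel %s>  %d states (%s)%s%s\n", x$name,
              length(x$state_names), paste(x$state_names, collapse = ", "),
              if (!is.null(x$par_name))
                sprintf(", parameter '%s' = %g", x$par_name,
                        x$pars[[x$par_name]]) else "",
              if (!is.null(x$compiled)) ", compiled rhs available" else ""))
  invisible(x)
}

#' Replace a model parameter
#'
#' @param model an [odeModel()].
#' @param value new value for the model's scan/bifurcation parameter,
#'   or for the parameter named by `name`.
#' @param name parameter name; defaults to `model$par_name`.
#' @return The modified model.
#' @export
setModelPar <- function(model, value, name = model$par_name) {
  if (is.null(name)) stop("model has no parameter to set", call. = FALSE)
  model$pars[[name]] <- value
  model
}

#' Evaluate the vector field of a model
#'
#' @param model an [odeModel()].
#' @param y state vector.
#' @param t time (models are autonomous; default 0).
#' @return Derivative vector.
#' @export
evalVectorField <- function(model, y, t = 0) {
  as.numeric(model$rhs(t, y, model$pars))
}

#' Build the vector field of a declarative neuron model
#'
#' Combines a [modelSpec()] with one grid case into an executable
#' right-hand side: \eqn{C\,dV/dt = -(\sum_x I_x - I_{inj})},
#' \eqn{dx/dt = (x_\infty(V) - x)/\tau_x(V)}.  The resulting
#' [odeModel()] exposes `g_leak` as its scan/bifurcation parameter and
#' carries an analytic Jacobian derived from the declarative gating
#' structure.
#'
#' @param model a [modelSpec()].
#' @param case a [caseParameters()]; scale factors must reference
#'   existing current names (configuration error otherwise).
#' @return An [odeModel()] in mV/nS/nF/s units.
#' @export
buildVectorField <- function(model, case) {
  stopifnot(inherits(model, "modelSpec"), inherits(case, "caseParameters"))
  unknown <- setdiff(names(case$scale_factors), names(model$currents))
  if (length(unknown))
    stop("scale_factors reference unknown currents: ",
         paste(unknown, collapse = ", "), call. = FALSE)

  # flatten the declarative structure into index tables
  layout <- model$state_layout
  cinfo <- list()
  for (cur in model$currents) {
    gbar <- cur$max_conductance
    E <- cur$reversal_potential
    if (cur$name == "leak") { gbar <- NA_real_; E <- NA_real_ }  # case-owned
    sf <- case$scale_factors[cur$name]
    if (!is.na(sf) && cur$name != "leak") gbar <- gbar * sf
    cinfo[[cur$name]] <- list(
      name = cur$name, gbar = gbar, E = E,
      a_idx = if (!is.null(cur$activation)) match(cur$activation$name, layout) else NA_integer_,
      a_exp = if (!is.null(cur$activation)) cur$activation$exponent else 0L,
      a_gate = cur$activation,
      h_idx = if (!is.null(cur$inactivation)) match(cur$inactivation$name, layout) else NA_integer_,
      h_exp = if (!is.null(cur$inactivation)) cur$inactivation$exponent else 0L,
      h_gate = cur$inactivation)
  }
  gates <- list()
  for (cur in model$currents)
    for (g in list(cur$activation, cur$inactivation))
      if (!is.null(g)) gates[[g$name]] <- g
  gate_idx <- match(names(gates), layout)
  cap <- model$capacitance
  iinj_pa <- model$injected_current * 1000  # nA -> pA

  pars <- list(g_leak = case$g_leak, E_leak = case$E_leak)

  rhs <- function(t, y, pars) {
    v <- y[1]
    ionic <- 0
    for (ci in cinfo) {
      gbar <- if (ci$name == "leak") pars$g_leak else ci$gbar
      E <- if (ci$name == "leak") pars$E_leak else ci$E
      gate <- 1
      if (!is.na(ci$a_idx)) gate <- gate * y[ci$a_idx]^ci$a_exp
      if (!is.na(ci$h_idx)) gate <- gate * y[ci$h_idx]^ci$h_exp
      ionic <- ionic + gbar * gate * (v - E)
    }
    dy <- numeric(length(y))
    dy[1] <- -(ionic - iinj_pa) / cap
    for (k in seq_along(gate_idx)) {
      g <- gates[[k]]
      i <- gate_idx[k]
      dy[i] <- (gateInf(g, v) - y[i]) / tauValue(g$tau, v)
    }
    dy
  }

  jac <- function(t, y, pars) {
    v <- y[1]
    n <- length(y)
    J <- matrix(0, n, n)
    for (ci in cinfo) {
      gbar <- if (ci$name == "leak") pars$g_leak else ci$gbar
      E <- if (ci$name == "leak") pars$E_leak else ci$E
      a <- if (!is.na(ci$a_idx)) y[ci$a_idx] else 1
      h <- if (!is.na(ci$h_idx)) y[ci$h_idx] else 1
      ga <- if (ci$a_exp > 0) a^ci$a_exp else 1
      gh <- if (ci$h_exp > 0) h^ci$h_exp else 1
      J[1, 1] <- J[1, 1] - gbar * ga * gh / cap
      if (!is.na(ci$a_idx))
        J[1, ci$a_idx] <- J[1, ci$a_idx] -
          gbar * ci$a_exp * a^(ci$a_exp - 1L) * gh * (v - E) / cap
      if (!is.na(ci$h_idx))
        J[1, ci$h_idx] <- J[1, ci$h_idx] -
          gbar * ci$h_exp * h^(ci$h_exp - 1L) * ga * (v - E) / cap
    }
    for (k in seq_along(gate_idx)) {
      g <- gates[[k]]
      i <- gate_idx[k]
      tv <- tauValue(g$tau, v)
      J[i, 1] <- gateInfDeriv(g, v) / tv -
        (gateInf(g, v) - y[i]) * tauDeriv(g$tau, v) / tv^2
      J[i, i] <- -1 / tv
    }
    J
  }

  odeModel(name = sprintf("%s/case%d", model$name, case$case_id),
           rhs = rhs, jac = jac, pars = pars, state_names = layout,
           par_name = "g_leak",
           meta = list(spec = model, case = case))
}

#' Jacobian of a model's vector field
#'
#' Returns the analytic Jacobian when the model carries one, otherwise
#' a central finite-difference approximation.
#'
#' @param model an [odeModel()].
#' @param y state vector.
#' @param t time (default 0).
#' @return Square Jacobian matrix.
#' @export
modelJacobian <- function(model, y, t = 0) {
  if (!is.null(model$jac)) return(model$jac(t, y, model$pars))
  numJacobian(function(z) as.numeric(model$rhs(t, z, model$pars)), y)
}

#' Central finite-difference Jacobian
#'
#' @param f function mapping a state vector to a derivative vector.
#' @param y evaluation point.
#' @param eps relative step (absolute floor `eps`).
#' @return Jacobian matrix of `f` at `y`.
#' @export
numJacobian <- function(f, y, eps = 1e-6) {
  n <- length(y)
  f0 <- f(y)
  J <- matrix(0, length(f0), n)
  for (j in seq_len(n)) {
    h <- eps * max(1, abs(y[j]))
    yp <- y; yp[j] <- y[j] + h
    ym <- y; ym[j] <- y[j] - h
    J[, j] <- (f(yp) - f(ym)) / (2 * h)
  }
  J
}

#' Couple two neuron cases into a half-center oscillator
#'
#' Builds the coupled system of two single-compartment cells connected
#' by reciprocal inhibitory synapses.  The state vector is
#' `[cell A states, cell B states, synapse gates A->B..., B->A...]`;
#' each [synapseSpec()] contributes one gating state per direction.
#' With all synaptic conductances zero the two cells are exactly
#' independent.
#'
#' @param model a [modelSpec()] shared by both cells.
#' @param case_a,case_b [caseParameters()] for the two cells (may
#'   differ, e.g. in the leak conductance only).
#' @param synapses list of [synapseSpec()] objects.
#' @return An object of class `c("hcoModel", "odeModel")`.
#' @export
assembleHCO <- function(model, case_a, case_b, synapses) {
  stopifnot(is.list(synapses))
  if (!all(vapply(synapses, inherits, TRUE, "synapseSpec")))
    stop("synapses must be a list of synapseSpec objects", call. = FALSE)
  cell_a <- buildVectorField(model, case_a)
  cell_b <- buildVectorField(model, case_b)
  coupleCells(cell_a, cell_b, synapses, capacitance = model$capacitance)
}

# Generic coupling of two single-cell odeModels through inhibitory
# synapses acting on the membrane potential equation.
coupleCells <- function(cell_a, cell_b, synapses, capacitance) {
  n <- length(cell_a$state_names)
  stopifnot(length(cell_b$state_names) == n)
  ns <- length(synapses)
  syn_names <- vapply(seq_along(synapses), function(i)
    sprintf("s_%s%d", substr(synapses[[i]]$kind, 1, 1), i), "")
  state_names <- c(paste0(cell_a$state_names, "_a"),
                   paste0(cell_b$state_names, "_b"),
                   paste0(syn_names, "_ab"), paste0(syn_names, "_ba"))
  ia <- seq_len(n); ib <- n + seq_len(n)
  iab <- 2 * n + seq_len(ns); iba <- 2 * n + ns + seq_len(ns)
  pars <- list(syn_scale = 1, a = cell_a$pars, b = cell_b$pars)

  rhs <- function(t, y, pars) {
    ya <- y[ia]; yb <- y[ib]
    dya <- cell_a$rhs(t, ya, pars$a)
    dyb <- cell_b$rhs(t, yb, pars$b)
    dy <- numeric(length(y))
    for (k in seq_len(ns)) {
      sp <- synapses[[k]]
      g <- sp$max_conductance * pars$syn_scale
      # a -> b gate driven by V_a, current onto cell b (and vice versa)
      sab <- y[iab[k]]; sba <- y[iba[k]]
      dy[iab[k]] <- (1 / (1 + exp(-(ya[1] - sp$v_threshold) / sp$v_slope)) - sab) / sp$tau
      dy[iba[k]] <- (1 / (1 + exp(-(yb[1] - sp$v_threshold) / sp$v_slope)) - sba) / sp$tau
      dyb[1] <- dyb[1] - g * sab * (yb[1] - sp$reversal_potential) / capacitance
      dya[1] <- dya[1] - g * sba * (ya[1] - sp$reversal_potential) / capacitance
    }
    dy[ia] <- dya; dy[ib] <- dyb
    dy
  }

  m <- odeModel(name = sprintf("hco(%s | %s)", cell_a$name, cell_b$name),
                rhs = rhs, pars = pars, state_names = state_names,
                meta = list(cells = list(cell_a, cell_b), synapses = synapses,
                            cell_idx = list(ia, ib), v_idx = c(1L, n + 1L),
                            syn_idx = c(iab, iba)))
  class(m) <- c("hcoModel", class(m))
  m
}

#' Disable the synapses of a half-center oscillator
#'
#' Returns a copy of the coupled model with all synaptic maximal
#' conductances set to 0 nS; synaptic gating states keep evolving
#' according to their kinetics.
#'
#' @param hco an `hcoModel`.
#' @return The modified model.
#' @export
synapsesOff <- function(hco) {
  stopifnot(inherits(hco, "hcoModel"))
  if (!is.null(hco$compiled)) hco$pars$gs <- 0 else hco$pars$syn_scale <- 0
  hco
}
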