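#' Gating-variable specification
#'
#' Declares one Hodgkin-Huxley gating variable: a sigmoidal
#' voltage-dependent steady state and a strictly positive
#' voltage-dependent time constant.  The steady state is
#' \eqn{x_\infty(V) = 1/(1 + \exp((V - V_{1/2})/k))}; negative `slope`
#' gives an activation gate (increasing with depolarization), positive
#' `slope` an inactivation gate.
#'
#' @param name gate identifier, unique within a model (e.g. `"m_Na"`).
#' @param exponent integer power the gate enters the current with
#'   (\eqn{\ge 1}).
#' @param v_half half-activation voltage (mV).
#' @param slope sigmoid slope factor (mV, nonzero).
#' @param tau time-constant description (seconds): one of
#'   `list(kind = "constant", value)`,
#'   `list(kind = "bell", base, amp, v_peak, width)` with
#'   \eqn{\tau(V) = base + amp\,e^{-((V-V_{peak})/width)^2}}, or
#'   `list(kind = "sigmoid", base, amp, v_half, slope)` with
#'   \eqn{\tau(V) = base + amp/(1 + \exp((V - V_{1/2})/k))}.
#'
#' @return An object of class `gatingSpec`.
#' @export
gatingSpec <- function(name, exponent = 1L, v_half, slope,
                       tau = list(kind = "constant", value = 0.01)) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  exponent <- as.integer(exponent)
  if (is.na(exponent) || exponent < 1L)
    stop("gating exponent must be an integer >= 1", call. = FALSE)
  if (!is.numeric(v_half) || !is.numeric(slope) || slope == 0)
    stop("v_half and nonzero slope are required", call. = FALSE)
  tau <- validateTau(tau)
  structure(list(name = name, exponent = exponent,
                 v_half = v_half, slope = slope, tau = tau),
            class = "gatingSpec")
}

validateTau <- function(tau) {
  if (!is.list(tau) || is.null(tau$kind))
    stop("tau must be a list with a 'kind' field", call. = FALSE)
  kind <- match.arg(tau$kind, c("constant", "bell", "sigmoid"))
  need <- switch(kind,
                 constant = "value",
                 bell     = c("base", "amp", "v_peak", "width"),
                 sigmoid  = c("base", "amp", "v_half", "slope"))
  miss <- setdiff(need, names(tau))
  if (length(miss))
    stop("tau (", kind, ") missing fields: ", paste(miss, collapse = ", "),
         call. = FALSE)
  tau$kind <- kind
  # positivity over the physiological voltage range
  v <- seq(-100, 60, by = 0.5)
  if (any(!is.finite(tauValue(tau, v))) || any(tauValue(tau, v) <= 0))
    stop("time constant must be positive on [-100, 60] mV", call. = FALSE)
  tau
}

gateInf <- function(gate, v) 1 / (1 + exp((v - gate$v_half) / gate$slope))

# d x_inf / dV
gateInfDeriv <- function(gate, v) {
  s <- gateInf(gate, v)
  -s * (1 - s) / gate$slope
}

tauValue <- function(tau, v) {
  switch(tau$kind,
         constant = rep(tau$value, length(v)),
         bell     = tau$base + tau$amp * exp(-((v - tau$v_peak) / tau$width)^2),
         sigmoid  = tau$base + tau$amp / (1 + exp((v - tau$v_half) / tau$slope)))
}

tauDeriv <- function(tau, v) {
  switch(tau$kind,
         constant = rep(0, length(v)),
         bell     = tau$amp * exp(-((v - tau$v_peak) / tau$width)^2) *
                      (-2 * (v - tau$v_peak) / tau$width^2),
         sigmoid  = {
           e <- exp((v - tau$v_half) / tau$slope)
           -tau$amp * e / (tau$slope * (1 + e)^2)
         })
}

#' Membrane-current specification
#'
#' One ionic current \eqn{I = \bar g\, a^{p_a} h^{p_h} (V - E)} with
#' optional activation and inactivation gates.  A current with no gates
#' is instantaneous (ohmic), as the leak current is.
#'
#' @param name current identifier (e.g. `"Na"`, `"leak"`).
#' @param reversal_potential reversal potential (mV).
#' @param max_conductance maximal conductance (nS, \eqn{\ge 0}).
#' @param activation,inactivation optional [gatingSpec()] objects.
#'
#' @return An object of class `currentSpec`.
#' @export
currentSpec <- function(name, reversal_potential, max_conductance,
                        activation = NULL, inactivation = NULL) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!is.numeric(max_conductance) || max_conductance < 0)
    stop("max_conductance must be >= 0", call. = FALSE)
  for (g in list(activation, inactivation))
    if (!is.null(g) && !inherits(g, "gatingSpec"))
      stop("activation/inactivation must be gatingSpec objects", call. = FALSE)
  structure(list(name = name,
                 reversal_potential = reversal_potential,
                 max_conductance = max_conductance,
                 activation = activation,
                 inactivation = inactivation,
                 instantaneous = is.null(activation) && is.null(inactivation)),
            class = "currentSpec")
}

#' Inhibitory synapse specification
#'
#' First-order synaptic kinetics driven by the presynaptic membrane
#' potential: \eqn{s' = (s_\infty(V_{pre}) - s)/\tau} with
#' \eqn{s_\infty(V) = 1/(1 + \exp(-(V - \theta)/\sigma))}, and
#' postsynaptic current \eqn{\bar g\, s\,(V_{post} - E_{syn})}.  Graded
#' synapses use a low threshold and slow kinetics; spike-mediated ones a
#' high threshold and fast kinetics.
#'
#' @param kind `"graded"` or `"spike_mediated"`.
#' @param max_conductance maximal conductance (nS, \eqn{\ge 0}).
#' @param reversal_potential synaptic reversal potential (mV).
#' @param v_threshold activation threshold \eqn{\theta} (mV).
#' @param v_slope activation slope \eqn{\sigma} (mV, > 0).
#' @param tau kinetic time constant (s, > 0).
#'
#' @return An object of class `synapseSpec`.
#' @export
synapseSpec <- function(kind = c("graded", "spike_mediated"),
                        max_conductance, reversal_potential,
                        v_threshold = if (kind == "graded") -40 else -20,
                        v_slope = 5, tau = if (kind == "graded") 0.2 else 0.01) {
  kind <- match.arg(kind)
  if (!is.numeric(max_conductance) || max_conductance < 0)
    stop("synaptic max_conductance must be >= 0", call. = FALSE)
  stopifnot(v_slope > 0, tau > 0)
  structure(list(kind = kind, max_conductance = max_conductance,
                 reversal_potential = reversal_potential,
                 v_threshold = v_threshold, v_slope = v_slope, tau = tau),
            class = "synapseSpec")
}

#' @export
print.gatingSpec <- function(x, ...) {
  cat(sprintf("<gatingSpec %s^%d>  V1/2 = %g mV, k = %g mV, tau: %s\n",
              x$name, x$exponent, x$v_half, x$slope, x$tau$kind))
  invisible(x)
}

#' @export
print.currentSpec <- function(x, ...) {
  gates <- c(if (!is.null(x$activation)) x$activation$name,
             if (!is.null(x$inactivation)) x$inactivation$name)
  cat(sprintf("<currentSpec %s>  E = %g mV, gmax = %g nS%s\n", x$name,
              x$reversal_potential, x$max_conductance,
              if (length(gates)) paste0(", gates: ", paste(gates, collapse = ", "))
              else " (instantaneous)"))
  invisible(x)
}
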