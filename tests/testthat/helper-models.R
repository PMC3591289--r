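# shared fixtures built in code

# leak-only declarative model (closed-form dynamics)
leakOnlyModel <- function(capacitance = 0.5) {
  modelSpec("leak_only", capacitance = capacitance,
            currents = list(currentSpec("leak", reversal_potential = -60,
                                        max_conductance = 8)))
}

# small two-current HH-type toy model with full gating structure
toyHHModel <- function() {
  modelSpec(
    "toy_hh", capacitance = 0.5,
    currents = list(
      currentSpec("leak", reversal_potential = -60, max_conductance = 8),
      currentSpec("P", reversal_potential = 45, max_conductance = 7,
                  activation = gatingSpec("m_P", 1, v_half = -39, slope = -5,
                                          tau = list(kind = "constant",
                                                     value = 0.01))),
      currentSpec("K2", reversal_potential = -70, max_conductance = 80,
                  activation = gatingSpec("m_K2", 2, v_half = -10, slope = -8,
                                          tau = list(kind = "bell", base = 0.05,
                                                     amp = 0.2, v_peak = -20,
                                                     width = 20)),
                  inactivation = gatingSpec("h_K2", 1, v_half = -30, slope = 6,
                                            tau = list(kind = "sigmoid",
                                                       base = 0.1, amp = 0.5,
                                                       v_half = -40,
                                                       slope = 10)))))
}

# 1-D linear relaxation toward v_rest, as an odeModel (closed form)
linearCell <- function(v_rest = -50, rate = 2) {
  odeModel(sprintf("linear(%g)", v_rest),
           rhs = function(t, y, p) p$rate * (p$v_rest - y[1]),
           jac = function(t, y, p) matrix(-p$rate, 1, 1),
           pars = list(rate = rate, v_rest = v_rest),
           state_names = "V")
}

# fixed-step classical RK4 integrator (independent oracle)
rk4Oracle <- function(f, y0, t_end, dt) {
  n <- ceiling(t_end / dt)
  y <- y0
  t <- 0
  for (i in seq_len(n)) {
    k1 <- f(t, y)
    k2 <- f(t + dt / 2, y + dt / 2 * k1)
    k3 <- f(t + dt / 2, y + dt / 2 * k2)
    k4 <- f(t + dt, y + dt * k3)
    y <- y + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    t <- t + dt
  }
  y
}

# plain stable-interval stub for interval-arithmetic tests
iv <- function(label, lo, hi) list(label = label, p_lo = lo, p_hi = hi)
rng <- function(lo, hi) list(g_min = lo, g_max = hi)

# the ten canonical coexistence arrangements, as interval fixtures
scenarioFixtures <- function() {
  list(
    A = list(iv = list(iv("hyp1", 6, 10)), b = rng(4, 8)),
    B = list(iv = list(iv("hyp1", 12, 20), iv("hyp2", 5, 6)), b = rng(4, 8)),
    C = list(iv = list(iv("hyp1", 7, 20), iv("dep1", 0, 2),
                       iv("dep2", 1, 1.5)), b = rng(4, 8)),
    D = list(iv = list(iv("hyp1", 7, 20), iv("dep1", 4.5, 5)), b = rng(4, 8)),
    E = list(iv = list(iv("hyp1", 8, 20), iv("dep1", 5, 9)), b = rng(4, 6)),
    F = list(iv = list(iv("hyp1", 7, 20), iv("dep1", 0, 5),
                       iv("dep2", 0.5, 1)), b = rng(4, 8)),
    G = list(iv = list(iv("hyp1", 5, 20), iv("dep1", 4.5, 7)), b = rng(4, 6)),
    H = list(iv = list(iv("hyp1", 5, 20), iv("dep1", 4.5, 6)), b = rng(4, 8)),
    I = list(iv = list(iv("hyp1", 5, 20), iv("dep1", 0, 7),
                       iv("dep2", 0.5, 1)), b = rng(4, 6)),
    J = list(iv = list(iv("hyp1", 5, 9), iv("dep1", 3, 12)), b = rng(6, 7)))
}

# analytic probe for scanner-algorithm tests: robust bursting on
# [lo, hi], with the stated regimes beyond each edge
analyticProbe <- function(lo, hi, below = "tonic_spiking", above = "silent") {
  function(g, state) {
    if (g < lo) list(robust = FALSE, label = below, state = state)
    else if (g > hi) list(robust = FALSE, label = above, state = state)
    else list(robust = TRUE, label = "bursting", state = state + 1)
  }
}
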