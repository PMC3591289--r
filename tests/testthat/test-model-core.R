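test_that("leak-only vector field and Jacobian match the closed form", {
  m <- leakOnlyModel(capacitance = 0.5)
  case <- caseParameters(0, E_leak = -60, g_leak = 10)
  vf <- buildVectorField(m, case)
  # dV/dt = -g (V - E) / C
  expect_equal(evalVectorField(vf, -50), -10 * (-50 + 60) / 0.5)
  expect_equal(evalVectorField(vf, -60), 0)
  expect_equal(modelJacobian(vf, -50), matrix(-10 / 0.5, 1, 1))
})

test_that("gating and synapse invariants are enforced", {
  expect_error(gatingSpec("m", exponent = 0, v_half = -40, slope = -5),
               "exponent")
  expect_error(gatingSpec("m", 1, v_half = -40, slope = -5,
                          tau = list(kind = "bell", base = -0.3, amp = 0.1,
                                     v_peak = -20, width = 10)),
               "positive")
  g <- gatingSpec("m", 2, v_half = -40, slope = -5)
  v <- seq(-100, 60, by = 1)
  si <- burstscan:::gateInf(g, v)
  expect_true(all(si >= 0 & si <= 1))
  expect_error(synapseSpec("graded", max_conductance = -1,
                           reversal_potential = -62.5), ">= 0")
  expect_error(currentSpec("Na", 45, max_conductance = -2), ">= 0")
})

test_that("scale factors must reference existing currents", {
  m <- leakOnlyModel()
  case <- caseParameters(1, -60, 8, scale_factors = c(CaF = 0.5))
  expect_error(buildVectorField(m, case), "unknown currents")
})

test_that("analytic Jacobian agrees with finite differences at random states", {
  m <- toyHHModel()
  case <- caseParameters(2, E_leak = -55, g_leak = 6,
                         scale_factors = c(P = 1.25, K2 = 0.75))
  vf <- buildVectorField(m, case)
  set.seed(11)
  for (i in 1:100) {
    y <- c(runif(1, -80, 20), runif(3, 0.05, 0.95))
    Ja <- modelJacobian(vf, y)
    Jn <- numJacobian(function(z) evalVectorField(vf, z), y)
    expect_lt(max(abs(Ja - Jn)) / max(1, max(abs(Jn))), 1e-5)
  }
})

test_that("surrogate burster Jacobian matches finite differences", {
  m <- makeMinimalBurster(g = 5)
  set.seed(7)
  for (i in 1:20) {
    y <- c(runif(1, -60, 15), runif(1, -5, 1), runif(1, 0.5, 2.5))
    Ja <- modelJacobian(m, y)
    Jn <- numJacobian(function(z) evalVectorField(m, z), y)
    expect_lt(max(abs(Ja - Jn)) / max(abs(Jn)), 1e-5)
  }
})

test_that("burster vector field reproduces an independent RK4 oracle", {
  m <- makeMinimalBurster(g = 3)
  y0 <- c(-45, 0, 1.2)
  oracle <- rk4Oracle(function(t, y) evalVectorField(m, y), y0,
                      t_end = 1, dt = 1e-5)
  tr <- integrateModel(m, y0, 1)
  got <- finalState(tr)
  expect_lt(max(abs(got - oracle) / pmax(1, abs(oracle))), 1e-6)
})

test_that("coupled cells decouple exactly at zero synaptic conductance", {
  m <- toyHHModel()
  ca <- caseParameters(0, -60, 5.9)
  cb <- caseParameters(1, -60, 6.0)
  syn <- list(synapseSpec("graded", 0, -62.5),
              synapseSpec("spike_mediated", 0, -62.5))
  hco <- assembleHCO(m, ca, cb, syn)
  va <- buildVectorField(m, ca)
  vb <- buildVectorField(m, cb)
  set.seed(3)
  n <- length(va$state_names)
  for (i in 1:25) {
    ya <- c(runif(1, -80, 20), runif(n - 1, 0.05, 0.95))
    yb <- c(runif(1, -80, 20), runif(n - 1, 0.05, 0.95))
    s <- runif(2, 0, 1)
    d <- evalVectorField(hco, c(ya, yb, s, s))
    expect_identical(d[seq_len(n)], evalVectorField(va, ya))
    expect_identical(d[n + seq_len(n)], evalVectorField(vb, yb))
  }
})

test_that("an asymmetric pair differing only in g_leak is accepted and integrable", {
  m <- toyHHModel()
  hco <- assembleHCO(m, caseParameters(0, -60, 5.9),
                     caseParameters(1, -60, 6.0),
                     list(synapseSpec("graded", 30, -62.5)))
  n <- length(hco$state_names)
  y0 <- c(-50, rep(0.1, 3), -55, rep(0.1, 3), 0, 0)
  tr <- integrateModel(hco, y0, 0.5)
  expect_true(all(is.finite(tr$states)))
  expect_equal(nrow(tr$states), 501L)
})

test_that("rejected synapse configurations raise configuration errors", {
  expect_error(assembleHCO(toyHHModel(), caseParameters(0, -60, 5),
                           caseParameters(1, -60, 5),
                           list(list(kind = "graded"))),
               "synapseSpec")
})
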