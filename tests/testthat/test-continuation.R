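test_that("Newton refinement finds both equilibria of the fold model", {
  m <- makeFoldModel(0)            # mu = 1
  eq1 <- findEquilibrium(m, 0.9)
  expect_equal(eq1$state, 1, tolerance = 1e-9)
  expect_equal(Re(eq1$eigenvalues), -2, tolerance = 1e-8)
  expect_true(eq1$stable)

  eq2 <- findEquilibrium(m, -0.9)
  expect_equal(eq2$state, -1, tolerance = 1e-9)
  expect_false(eq2$stable)

  # no real equilibria below the fold
  m_low <- setModelPar(makeFoldModel(0), -0.5)
  expect_error(findEquilibrium(m_low, 0.3), "converge|singular")
  expect_error(findEquilibrium(m, NaN), "finite")
})

test_that("continuation traverses the fold and recovers both half-branches", {
  m <- makeFoldModel(0)
  br <- continueBranch(m, findEquilibrium(m, 0.9))
  # closest sampled approach to the fold is limited by the step size
  expect_true(min(br$parameter) < 1e-3)
  x <- br$states[, 1]
  expect_true(any(x > 0.5) && any(x < -0.5))     # both halves present
  # every point sits on the analytic curve x^2 = mu, which is mirror
  # symmetric in x; the sampled halves match it on both signs
  expect_lt(max(abs(x^2 - br$parameter)), 1e-8)
  expect_lt(max(abs(abs(x) - sqrt(pmax(br$parameter, 0)))), 1e-8)
})

test_that("fold localization hits the analytic value within 1e-8", {
  for (mu_c in c(0, 3.5)) {
    m <- makeFoldModel(mu_c)
    br <- continueBranch(m, findEquilibrium(m, 0.9))
    bf <- detectBifurcations(br, m)
    lp <- Filter(function(b) b$kind == "LP", bf)
    expect_length(lp, 1L)
    expect_equal(lp[[1]]$label, "LP1")
    expect_lt(abs(lp[[1]]$parameter - mu_c), 1e-8)
  }
})

test_that("Hopf localization hits the analytic value within 1e-8", {
  for (mu_c in c(0, -2)) {
    m <- makeHopfModel(mu_c, omega = 1)
    eq <- findEquilibrium(m, c(1e-3, 0))
    br <- continueBranch(m, eq)
    bf <- detectBifurcations(br, m)
    ah <- Filter(function(b) b$kind == "AH", bf)
    expect_length(ah, 1L)
    expect_lt(abs(ah[[1]]$parameter - mu_c), 1e-8)
    expect_equal(max(abs(Im(ah[[1]]$eigenvalues))), 1, tolerance = 1e-6)
    # stability flips at the bifurcation
    expect_true(all(br$stable[br$parameter < mu_c - 1e-6]))
    expect_false(any(br$stable[br$parameter > mu_c + 1e-6]))
  }
})

test_that("relaxation-oscillator Hopf agrees with the eigenvalue-scan oracle", {
  m <- makeRelaxationModel(mu = 0)
  eq <- findEquilibrium(m, m$meta$equilibrium(0))
  br <- continueBranch(m, eq, direction = +1, p_outbound = 3)
  ah <- Filter(function(b) b$kind == "AH", detectBifurcations(br, m))
  expect_gte(length(ah), 1L)
  oracle <- equilibriumScanOracle(m, 0, 1)
  expect_lt(abs(ah[[1]]$parameter - oracle), 1e-5)
})

test_that("every branch point satisfies the equilibrium contract", {
  m <- makeMinimalBurster(g = 20)
  eq <- findEquilibrium(m, bursterEquilibrium(20))
  br <- continueBranch(m, eq)
  f <- burstscan:::parF(m)
  idx <- round(seq(1, length(br$parameter), length.out = 60))
  for (i in idx) {
    fv <- f(br$states[i, ], br$parameter[i])
    expect_lt(sqrt(sum(fv^2)), 1e-8)
    ev <- eigen(modelJacobian(setModelPar(m, br$parameter[i]),
                              br$states[i, ]), only.values = TRUE)$values
    expect_equal(br$stable[i], max(Re(ev)) < 0)
  }
})

test_that("equilibrium from settle endpoint matches the long integration", {
  m <- makeMinimalBurster(g = 20)
  tr <- settle(m, c(-10, 0, 2))
  eq <- findEquilibrium(m, finalState(tr))
  expect_lt(max(abs(eq$state - finalState(tr))), 1e-4)
  expect_true(eq$stable)
})

test_that("interval labels are invariant to the continuation step size", {
  m <- makeMinimalBurster(g = 20)
  eq <- findEquilibrium(m, bursterEquilibrium(20))
  labs <- lapply(c(0.02, 0.01), function(h) {
    br <- continueBranch(m, eq, step_max = h)
    bf <- detectBifurcations(br, m)
    iv <- stableIntervals(br, bf)
    list(labels = vapply(iv, `[[`, "", "label"),
         ah = Filter(function(b) b$kind == "AH", bf)[[1]]$parameter)
  })
  expect_equal(labs[[1]]$labels, labs[[2]]$labels)
  expect_lt(abs(labs[[1]]$ah - labs[[2]]$ah), 1e-6)
})

# synthetic branches exercise the labeling rules directly
syntheticBranch <- function(p, v, stable) {
  structure(list(parameter = p,
                 states = matrix(v, ncol = 1),
                 eigenvalues = lapply(stable, function(s)
                   if (s) -1 else 1),
                 stable = stable, par_name = "g", model_name = "synthetic",
                 start_parameter = p[1], termination = "floor"),
            class = "branch")
}

test_that("stable intervals split at -35 mV and clip to the physical domain", {
  # stable arc crossing -35 mV: split into hyp and dep parts
  p <- seq(20, -2, by = -0.5)
  v <- seq(-55, -11, length.out = length(p))
  br <- syntheticBranch(p, v, rep(TRUE, length(p)))
  iv <- stableIntervals(br)
  expect_equal(vapply(iv, `[[`, "", "label"), c("hyp1", "dep1"))
  expect_equal(iv[[1]]$p_hi, Inf)            # contains the branch start
  expect_equal(iv[[2]]$p_lo, 0)              # clipped to g >= 0
  expect_lt(iv[[1]]$v_rep, -35)
  expect_gt(iv[[2]]$v_rep, -35)

  # stable hyp arc, then unstable: hyp1 = [AH, Inf)
  p2 <- seq(20, 0, by = -0.5)
  st2 <- p2 >= 5
  br2 <- syntheticBranch(p2, rep(-55, length(p2)), st2)
  iv2 <- stableIntervals(br2)
  expect_equal(vapply(iv2, `[[`, "", "label"), "hyp1")
  expect_equal(iv2[[1]]$p_hi, Inf)
  # without a localized bifurcation the edge falls at the midpoint
  expect_equal(iv2[[1]]$p_lo, 4.75)

  # a depolarized interval entirely below 0 nS is dropped
  br3 <- syntheticBranch(c(-3, -2, -1), rep(-20, 3), rep(TRUE, 3))
  expect_length(stableIntervals(br3), 1L)    # clipped to [0, ...] via start
})
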