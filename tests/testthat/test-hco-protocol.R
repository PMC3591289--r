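trivialHCO <- function() {
  # two linear cells, inhibitory synapse: cheap but fully wired
  burstscan:::coupleCells(linearCell(-50), linearCell(-50),
                          list(synapseSpec("graded", 5, -62.5)),
                          capacitance = 0.5)
}

test_that("phase bookkeeping: 100 + 5 + 100 s with continuity except the reset", {
  hco <- trivialHCO()
  y0 <- c(-40, -55, 0, 0)
  out <- runPerturbation(hco, y0, reset_state = -50, which_cell = 1L,
                         t_pre = 2, t_block = 0.5, t_post = 2,
                         analyze_last = 1, keep_trajectories = TRUE,
                         sample_dt = 0.01)
  expect_equal(unname(out$timing), c(2, 0.5, 2, 4.5))
  p1 <- finalState(out$phases$pre)
  p2_0 <- out$phases$block$states[1, ]
  # only the reset cell's states change at the phase boundary
  expect_equal(unname(p2_0[1]), -50)                    # reset applied
  expect_equal(unname(p2_0[-1]), unname(p1[-1]), tolerance = 1e-12)
  # block -> post boundary is fully continuous
  expect_equal(unname(out$phases$post$states[1, ]),
               unname(finalState(out$phases$block)), tolerance = 1e-12)
  # default timing is the standard protocol
  fx_timing <- formals(runPerturbation)
  expect_equal(fx_timing$t_pre, 100)
  expect_equal(fx_timing$t_block, 5)
  expect_equal(fx_timing$t_post, 100)
})

test_that("two resting linear cells remain dysfunctional at rest", {
  hco <- trivialHCO()
  y0 <- c(-50, -50, 0, 0)
  out <- runPerturbation(hco, y0, reset_state = -50, which_cell = 2L,
                         t_pre = 2, t_block = 0.5, t_post = 2,
                         analyze_last = 1, sample_dt = 0.01)
  expect_equal(out$outcome, "dysfunctional")
  expect_equal(out$dysfunction_mode, "both_at_rest")
  # control variant: synapses never restored, same stationary outcome
  ctl <- runPerturbation(hco, y0, reset_state = -50, which_cell = 2L,
                         t_pre = 2, t_block = 0.5, t_post = 2,
                         analyze_last = 1, restore_synapses = FALSE,
                         sample_dt = 0.01)
  expect_equal(ctl$dysfunction_mode, "both_at_rest")
})

test_that("an unstable reset state violates the precondition", {
  unstable <- structure(list(parameter = 1, state = -50,
                             eigenvalues = 2 + 0i, stable = FALSE,
                             fnorm = 0),
                        class = "equilibriumPoint")
  expect_error(runPerturbation(trivialHCO(), c(-50, -50, 0, 0), unstable, 1L,
                               t_pre = 1, t_block = 0.5, t_post = 1),
               "stable stationary")
})

test_that("determinism: identical protocols give identical outcomes", {
  fx <- hcoFixture("recovered")
  warm <- integrateModel(fx$model, fx$y0, 10)
  a <- runPerturbation(fx$model, finalState(warm),
                       bursterEquilibrium(7.45), 1L,
                       t_pre = 10, t_block = 5, t_post = 10,
                       analyze_last = 8)
  b <- runPerturbation(fx$model, finalState(warm),
                       bursterEquilibrium(7.45), 1L,
                       t_pre = 10, t_block = 5, t_post = 10,
                       analyze_last = 8)
  expect_identical(a$outcome, b$outcome)
  expect_identical(a$post$functional$phase, b$post$functional$phase)
})

test_that("the frozen fixtures reproduce their manifest outcomes", {
  for (kind in c("recovered", "both_at_rest")) {
    fx <- hcoFixture(kind)
    warm <- integrateModel(fx$model, fx$y0, fx$warmup)
    g_reset <- fx$model$meta$cell_g[fx$reset_cell]
    cell <- makeMinimalBurster(g_reset)
    eq <- findEquilibrium(cell, bursterEquilibrium(g_reset))
    expect_true(eq$stable)
    out <- runPerturbation(fx$model, finalState(warm), eq, fx$reset_cell)
    if (kind == "recovered") {
      expect_equal(out$outcome, "recovered")
      expect_true(out$pre$functional$functional)
      expect_true(out$post$functional$functional)
    } else {
      expect_equal(out$outcome, "dysfunctional")
      expect_equal(out$dysfunction_mode, "both_at_rest")
      expect_equal(unname(out$post$labels), c("silent", "silent"))
    }
    expect_equal(unname(out$timing["total"]), 205)
  }
})
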