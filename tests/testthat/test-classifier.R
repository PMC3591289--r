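constantTrace <- function(v, duration = 10, dt = 1e-3) {
  t <- seq(0, duration, by = dt)
  trajectory(t, matrix(v, length(t), 1, dimnames = list(NULL, "V")))
}

test_that("spike detection applies the -10 mV local-maximum rule", {
  expect_length(detectSpikes(constantTrace(-50))$spike_times, 0)

  five <- makeSpikeTrace(list(kind = "tonic", isi = 1, n_spikes = 5))
  st <- detectSpikes(five$traj)
  expect_length(st$spike_times, 5)
  expect_equal(st$spike_times, five$spike_times, tolerance = 1.1e-3)

  # peaks below threshold are not spikes
  low <- makeSpikeTrace(list(kind = "tonic", isi = 1, n_spikes = 5),
                        peak = -20)
  expect_length(detectSpikes(low$traj)$spike_times, 0)
  # ... unless the threshold is lowered past them
  expect_length(detectSpikes(low$traj, threshold = -30)$spike_times, 5)
})

test_that("spike detection is invariant to disjoint concatenation", {
  a <- makeSpikeTrace(list(kind = "tonic", isi = 0.5, n_spikes = 4))
  n <- length(a$traj$times)
  shift <- max(a$traj$times) + 0.5
  joint <- trajectory(c(a$traj$times, a$traj$times + shift),
                      rbind(a$traj$states, a$traj$states))
  st <- detectSpikes(joint)$spike_times
  st1 <- detectSpikes(a$traj)$spike_times
  expect_equal(st, c(st1, st1 + shift), tolerance = 1e-9)
})

test_that("the 1 s ISI rule splits tonic spiking from bursting", {
  tonic <- makeSpikeTrace(list(kind = "tonic", isi = 0.5, n_spikes = 30))
  expect_equal(classifyRegime(tonic$traj)$label, "tonic_spiking")

  expect_equal(classifyRegime(constantTrace(-50))$label, "silent")
  # a depolarized rest state is still a silent regime
  expect_equal(classifyRegime(constantTrace(20))$label, "silent")

  # ISI exactly 1 s counts as a burst gap (complement of "smaller than 1 s")
  onesec <- makeSpikeTrace(list(kind = "tonic", isi = 1, n_spikes = 10))
  expect_equal(classifyRegime(onesec$traj)$label, "bursting")
})

test_that("burst statistics match hand arithmetic on a constructed train", {
  b <- makeSpikeTrace(list(kind = "burst", n_spikes = 5, isi = 0.1,
                           gap = 1.5, n_bursts = 8))
  reg <- classifyRegime(b$traj)
  expect_equal(reg$label, "bursting")
  s <- reg$stats
  expect_equal(mean(s$burst_durations), 0.4, tolerance = 1e-9)
  expect_equal(mean(s$interburst_intervals), 1.5, tolerance = 1e-9)
  expect_equal(mean(s$periods), 1.9, tolerance = 1e-9)
  expect_equal(s$cv_period, 0, tolerance = 1e-9)
  # period_i = duration_i + ibi_i exactly
  nb <- length(s$burst_onsets)
  expect_equal(s$periods, s$burst_durations[-nb] + s$interburst_intervals)
})

test_that("alternating periods beyond 5% CV classify as irregular", {
  # bursts of 2 spikes with alternating periods 1.9 s and 2.5 s
  onsets <- cumsum(c(1, rep(c(1.9, 2.5), 5)))
  st <- sort(c(onsets, onsets + 0.1))
  s <- burstStatistics(st)
  expect_equal(s$periods, rep(c(1.9, 2.5), 5), tolerance = 1e-9)
  expect_equal(s$cv_period, sd(rep(c(1.9, 2.5), 5)) / 2.2, tolerance = 1e-9)
  expect_gt(s$cv_period, 0.05)

  tr <- makeSpikeTrace(list(kind = "burst", n_spikes = 2, isi = 0.1,
                            gap = 1.5, n_bursts = 11))
  # rebuild the same trace with alternating gaps via direct times
  expect_equal(classifyRegime(tr$traj)$label, "bursting")
})

test_that("time shift changes no label or statistic", {
  b <- makeSpikeTrace(list(kind = "burst", n_spikes = 3, isi = 0.1,
                           gap = 2, n_bursts = 6))
  shifted <- trajectory(b$traj$times + 123.4, b$traj$states)
  r0 <- classifyRegime(b$traj)
  r1 <- classifyRegime(shifted)
  expect_equal(r1$label, r0$label)
  expect_equal(r1$stats$cv_period, r0$stats$cv_period)
  expect_equal(r1$stats$periods, r0$stats$periods, tolerance = 1e-9)
})

test_that("the robust-burster rules use strict 5% and 10% bounds", {
  mk <- function(cvp, cvi) structure(list(cv_period = cvp, cv_ibi = cvi),
                                     class = "burstStats")
  expect_true(isRobustBurster(mk(0, 0)))
  expect_true(isRobustBurster(mk(0.04, 0.09)))
  expect_false(isRobustBurster(mk(0.04, 0.12)))  # IBI rule fails
  expect_false(isRobustBurster(mk(0.06, 0.01)))  # period rule fails
  expect_false(isRobustBurster(mk(0.05, 0.01)))  # boundary: strict
  expect_false(isRobustBurster(mk(0.01, 0.10)))  # boundary: strict
  # plateau-like traces never qualify
  plat <- structure(list(label = "plateau_like", stats = NULL),
                    class = "regimeLabel")
  expect_false(isRobustBurster(plat))
})

test_that("plateau-like dwells are flagged only in spiking traces", {
  # two spikes, then a >1 s suprathreshold dome
  sp <- makeSpikeTrace(list(kind = "tonic", isi = 0.5, n_spikes = 2))
  t_dome <- seq(max(sp$traj$times) + 1e-3, max(sp$traj$times) + 2, by = 1e-3)
  dome <- -5 - 4 * ((t_dome - mean(t_dome)) / diff(range(t_dome)) * 2)^2
  tr <- trajectory(c(sp$traj$times, t_dome),
                   rbind(sp$traj$states, matrix(dome, ncol = 1)))
  expect_equal(classifyRegime(tr)$label, "plateau_like")
  # ordinary bursting has only brief suprathreshold dwells
  b <- makeSpikeTrace(list(kind = "burst", n_spikes = 4, isi = 0.2,
                           gap = 1.5, n_bursts = 5))
  expect_equal(classifyRegime(b$traj)$label, "bursting")
})

test_that("the functional-HCO criterion needs balanced regular antiphase", {
  onsets <- function(t0, period, n) t0 + period * (0:(n - 1))
  train <- function(on) sort(as.vector(outer(c(0, 0.1, 0.2), on, `+`)))
  a <- train(onsets(1, 4, 10))
  b_half <- train(onsets(3, 4, 10))      # offset half a period
  r <- hcoFunctional(a, b_half)
  expect_true(r$functional)
  expect_equal(r$phase, 0.5, tolerance = 1e-9)

  b_third <- train(onsets(1 + 0.3 * 4, 4, 10))  # offset 0.3 of a period
  r3 <- hcoFunctional(a, b_third)
  expect_false(r3$functional)
  expect_equal(r3$phase, 0.3, tolerance = 1e-9)

  # phase window boundaries are inclusive
  b_045 <- train(onsets(1 + 0.45 * 4, 4, 10))
  expect_true(hcoFunctional(a, b_045)$functional)

  # an irregular partner disqualifies the pair
  set.seed(5)
  jit <- onsets(3, 4, 10) + cumsum(rnorm(10, 0, 0.35))
  r_j <- hcoFunctional(a, train(sort(jit)))
  expect_gt(r_j$cv_b, 0.05)
  expect_false(r_j$functional)

  # non-bursting input violates the precondition
  expect_error(hcoFunctional(a, seq(0, 10, by = 0.5)), "bursting")
})

test_that("too few cycles raise an insufficient-cycles error", {
  expect_error(burstStatistics(c(1, 1.1, 1.2)), "fewer than 2 bursts")
  expect_error(burstStatistics(numeric(1)), "insufficient")
})
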