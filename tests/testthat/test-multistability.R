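test_that("coexistence ranges are exact interval intersections", {
  cx <- coexistenceRanges(list(iv("hyp1", 6, Inf)), rng(4, 8))
  expect_length(cx, 1L)
  expect_equal(c(cx[[1]]$p_lo, cx[[1]]$p_hi), c(6, 8))
  expect_equal(cx[[1]]$regimes, c("bursting", "hyp1"))

  cx2 <- coexistenceRanges(list(iv("dep1", 0, 5), iv("hyp1", 6, Inf)),
                           rng(4, 8))
  expect_length(cx2, 2L)
  expect_equal(lapply(cx2, function(r) c(r$p_lo, r$p_hi)),
               list(c(4, 5), c(6, 8)))
  expect_equal(cx2[[1]]$regimes, c("bursting", "dep1"))
  expect_equal(cx2[[2]]$regimes, c("bursting", "hyp1"))

  # a tristable window decomposes into its maximal constant-set ranges
  cx3 <- coexistenceRanges(list(iv("hyp1", 5, Inf), iv("dep1", 0, 6)),
                           rng(4, 8))
  sets <- lapply(cx3, `[[`, "regimes")
  expect_equal(sets, list(c("bursting", "dep1"),
                          c("bursting", "dep1", "hyp1"),
                          c("bursting", "hyp1")))
  expect_equal(vapply(cx3, function(r) c(r$p_lo, r$p_hi), c(0, 0)),
               matrix(c(4, 5, 5, 6, 6, 8), 2))
  expect_equal(vapply(cx3, `[[`, 0L, "order"), c(2L, 3L, 2L))
})

test_that("stationary-stationary overlaps and point contacts are handled", {
  cx <- coexistenceRanges(list(iv("dep1", 0, 2), iv("dep2", 1, 1.5)))
  expect_length(cx, 1L)
  expect_equal(cx[[1]]$regimes, c("dep1", "dep2"))

  # single-point contact: excluded by default, reported as diagnostics
  touch <- list(iv("hyp1", 5, 8), iv("dep1", 8, 10))
  expect_length(coexistenceRanges(touch), 0L)
  pts <- coexistenceRanges(touch, keep_points = TRUE)
  expect_length(pts, 1L)
  expect_equal(c(pts[[1]]$p_lo, pts[[1]]$p_hi), c(8, 8))
})

test_that("the scenario classifier realizes all ten arrangements", {
  fx <- scenarioFixtures()
  got <- vapply(names(fx), function(k) {
    cls <- classifyScenario(coexistenceRanges(fx[[k]]$iv, fx[[k]]$b))
    cls$class
  }, "")
  expect_equal(unname(got), names(fx))      # identity on {A..J}
  expect_length(unique(got), 10L)

  expect_equal(classifyScenario(list())$class, "none")
  odd <- coexistenceRanges(list(iv("hyp2", 4, 5)), rng(4, 8))
  expect_equal(classifyScenario(odd)$class, "B")
  unk <- coexistenceRanges(list(iv("hyp2", 4, 5), iv("hyp1", 4.5, 6)),
                           rng(4, 8))
  expect_equal(classifyScenario(unk)$class, "unclassified")
  expect_match(classifyScenario(unk)$signature, "hyp")
})

test_that("prevalence is the covered fraction of the bursting range", {
  b <- rng(2, 10)
  cx <- coexistenceRanges(list(iv("hyp1", 8, Inf)), b)
  expect_equal(prevalenceOfMultistability(b, cx), 0.25)

  full <- coexistenceRanges(list(iv("hyp1", 0, Inf)), b)
  expect_equal(prevalenceOfMultistability(b, full), 1.0)

  none <- coexistenceRanges(list(iv("dep1", 11, 12)), b)
  expect_equal(prevalenceOfMultistability(b, none), 0.0)

  # stationary-only overlaps never enter the numerator
  mix <- coexistenceRanges(list(iv("dep1", 0, 3), iv("dep2", 2.5, 3),
                                iv("hyp1", 9, Inf)), b)
  expect_equal(prevalenceOfMultistability(b, mix), (3 - 2) / 8 + 1 / 8)

  expect_error(prevalenceOfMultistability(rng(5, 5), list()), "zero width")
})

test_that("the outlier-adjusted prevalence summary matches arithmetic", {
  s1 <- summarizePrevalence(c(0.10, 0.20, 0.30))
  expect_equal(s1$mean, 0.2)
  expect_equal(s1$threshold, 0.4)
  expect_equal(s1$n_excluded, 0L)
  expect_equal(s1$adjusted_mean, 0.2)
  expect_equal(s1$sd, sd(c(0.1, 0.2, 0.3)))

  s2 <- summarizePrevalence(c(0.10, 0.10, 1.00))
  expect_equal(s2$mean, 0.4)
  expect_equal(s2$n_excluded, 1L)
  expect_equal(s2$adjusted_mean, 0.1)

  s3 <- summarizePrevalence(1.0)
  expect_equal(s3$mean, 1.0)
  expect_equal(s3$n_excluded, 0L)
  expect_equal(s3$adjusted_mean, 1.0)

  expect_error(summarizePrevalence(numeric()), "no prevalence")
})

test_that("point membership in coexistence ranges uses closed intervals", {
  cx <- coexistenceRanges(list(iv("hyp1", 6, Inf), iv("dep1", 0, 6)),
                          rng(4, 8))
  at7 <- multistableAt(7, cx)
  expect_length(at7, 1L)
  expect_equal(at7[[1]]$regimes, c("bursting", "hyp1"))
  expect_length(multistableAt(2, cx), 0L)
  # shared endpoint belongs to both adjacent ranges
  at6 <- multistableAt(6, cx)
  expect_length(at6, 2L)
  # membership consistency on rational endpoints
  for (g in c(4, 4.5, 5.99, 6, 8, 8.0001)) {
    inside <- length(multistableAt(g, cx)) > 0
    manual <- any(vapply(cx, function(r) r$p_lo <= g && g <= r$p_hi, TRUE))
    expect_identical(inside, manual)
  }
})
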