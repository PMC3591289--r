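demoStates <- function(case_id, pars = c(1, 2, 3), scen = "A") {
  data.frame(case_id = case_id, point_id = seq_along(pars),
             parameter = pars * pi,             # irrational: exercises round trip
             stable = c(TRUE, FALSE, TRUE)[seq_along(pars)],
             interval_label = c("hyp1", "", "dep2")[seq_along(pars)],
             scenario_class = scen,
             coexistence_at_original = "bursting+hyp1",
             state = vapply(pars, function(p)
               burstscan:::packState(c(-1 / 3, exp(p), p / 7)), ""))
}

demoBifs <- function(case_id) {
  data.frame(case_id = case_id, label = c("AH1", "LP1"),
             kind = c("AH", "LP"), parameter = c(7.2441895, 1 / 3),
             state = c(burstscan:::packState(c(-46.4, 0.1, 1.1)),
                       burstscan:::packState(c(0, 0, 0))))
}

test_that("numeric fields round-trip through the store exactly", {
  st <- resultsStore(tempfile("store"))
  writeCase(st, demoStates(7), demoBifs(7))
  back <- queryStore(st, "states")
  expect_identical(back$parameter, c(1, 2, 3) * pi)
  expect_identical(unpackState(back$state)[[2]], c(-1 / 3, exp(2), 2 / 7))
  bb <- queryStore(st, "bifurcations")
  expect_identical(bb$parameter, c(7.2441895, 1 / 3))
})

test_that("writes are idempotent and integrity-checked", {
  st <- resultsStore(tempfile("store"))
  writeCase(st, demoStates(1), demoBifs(1))
  writeCase(st, demoStates(1), demoBifs(1))            # identical re-run
  expect_equal(nrow(queryStore(st, "states")), 3L)
  expect_equal(nrow(queryStore(st, "bifurcations")), 2L)

  altered <- demoStates(1)
  altered$parameter[2] <- 99
  expect_error(writeCase(st, altered), "integrity")

  expect_error(writeCase(st, rbind(demoStates(2), demoStates(2))),
               "duplicate")
  bad_bifs <- demoBifs(99)
  expect_error(writeCase(st, demoStates(3), bad_bifs), "unknown case")
})

test_that("queries filter exactly and order stably", {
  st <- resultsStore(tempfile("store"))
  writeCase(st, demoStates(2, scen = "G"))
  writeCase(st, demoStates(1, scen = "A"))
  dep2 <- queryStore(st, "states", function(df)
    df$stable & df$interval_label == "dep2")
  expect_equal(nrow(dep2), 2L)
  expect_equal(dep2$case_id, c(1L, 2L))               # stable key order
  expect_true(all(dep2$interval_label == "dep2"))

  gcase <- queryStore(st, "states", function(df) df$scenario_class == "G")
  expect_equal(unique(gcase$case_id), 2L)

  empty <- resultsStore(tempfile("store"))
  expect_equal(nrow(queryStore(empty, "states")), 0L)
  expect_error(queryStore(st, "states", function(df) 1:3), "query error")
})

test_that("stored bifurcation counts match detection on a surrogate", {
  m <- makeFoldModel(0)
  br <- continueBranch(m, findEquilibrium(m, 0.9))
  bf <- detectBifurcations(br, m)
  ivs <- stableIntervals(br)
  st <- resultsStore(tempfile("store"))
  writeCase(st, stationaryStateRecords(5, br, ivs), bifurcationRecords(5, bf))
  stored <- queryStore(st, "bifurcations", function(df) df$case_id == 5)
  expect_equal(nrow(stored), length(bf))
  expect_equal(stored$kind, "LP")
  # referential integrity: every bifurcation's case exists
  expect_true(all(stored$case_id %in% queryStore(st, "states")$case_id))
  # stability flags agree with the stored interval labels
  ss <- queryStore(st, "states")
  expect_true(all(ss$interval_label == "" | ss$stable))
})
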