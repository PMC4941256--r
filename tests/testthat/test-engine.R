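test_that("balanced-growth init is normalized and transient-free", {
  p <- fastParams()
  g <- simulationGrid(dt = 1, horizon = 72)
  init <- steadyStateInit(p, 1000, g)
  expect_equal(totalCellNumber(init), 1000, tolerance = 1e-9)
  expect_true(all(tlGenerationCounts(init)[-1] == 0))
  tr <- simulatePopulation(p, grid = g, init = init)
  td <- tr@doublingTime
  pred <- 1000 * 2^(tr@observables$time_h / td)
  expect_lt(max(abs(tr@observables$n_total / pred - 1)), 1e-9)
  # phase mix stays at the stationary composition
  expect_lt(max(abs(tr@observables$pct_G1 - tr@observables$pct_G1[1])), 1e-6)
})

test_that("init raises on non-positive population and matches eigen fractions", {
  expect_error(steadyStateInit(fastParams(), 0), "n0 > 0")
  p <- fastParams()
  gr <- growthRate(p, 1)
  init <- steadyStateInit(p, 500, simulationGrid(dt = 1, horizon = 24))
  expect_equal(unname(fcPercentages(init)) / 100, gr$phaseFractions,
               tolerance = 1e-9)
})

test_that("an absorbing G1 checkpoint empties S and G2M and stops growth", {
  p <- fastParams(maxGen = 3L)
  g <- coarseGrid(96)
  sch <- treatmentSchedule("drugX", 0, 96)
  dm <- drugModel("drugX", modules = list(
    perturbationModule("b", "block", "G1", NULL, 1, window = "during")))
  tr <- simulatePopulation(p, list(dm), sch, g)
  last <- atTime(tr, 96)
  expect_gt(last$pct_G1, 99.9)
  # once in-transit S/G2M cells clear, the population is constant
  obs <- tr@observables
  lateN <- obs$n_total[obs$time_h >= 48]
  expect_lt(diff(range(lateN)) / lateN[1], 1e-9)
})

test_that("death-free trajectories never lose cells and respect generation bookkeeping", {
  p <- fastParams()
  g <- coarseGrid(96)
  e1 <- shippedModel("bxpc3_erlotinib_1uM")
  e1@modules <- Filter(function(m) m@effect != "death", e1@modules)
  tr <- simulatePopulation(p, list(e1), shippedSchedule("erlotinib"), g)
  obs <- tr@observables
  expect_true(all(diff(obs$n_total) > -1e-9))
  expect_true(all(obs$n_dead == 0))
  expect_true(all(diff(obs$n_gen0) < 1e-9))  # generation 0 only drains
  genCols <- grep("^n_gen", names(obs), value = TRUE)
  expect_equal(rowSums(obs[, genCols]), obs$n_total, tolerance = 1e-9)
})

test_that("first division of a deterministic-limit cohort occurs at the cycle time", {
  p <- cellCycleParameters(10, 8, 6, 0.02, 0.02, 0.02)
  g <- simulationGrid(dt = 0.5, horizon = 30)
  tr <- simulatePopulation(p, grid = g, init = pulseState(p))
  obs <- tr@observables
  # essentially no divisions one bin before Tc = 24 h, most done 1.5 h after
  expect_lt(obs$n_gen1[obs$time_h == 22.5], 0.05)
  expect_gt(obs$n_gen1[obs$time_h == 26], 1.8)
})

test_that("snapshots are kept at requested times and retrievable", {
  p <- fastParams()
  g <- coarseGrid(48)
  tr <- simulatePopulation(p, grid = g, keepTimes = c(24, 48))
  st <- stateAt(tr, 24)
  expect_s4_class(st, "PopulationState")
  expect_equal(st@time, 24)
  expect_equal(totalCellNumber(st),
               tr@observables$n_total[tr@observables$time_h == 24],
               tolerance = 1e-12)
  expect_error(stateAt(tr, 12), "no snapshot")
})

test_that("a schedule reaching beyond the horizon warns", {
  p <- fastParams()
  expect_warning(
    simulatePopulation(p, list(delayDrug(0.3)),
                       treatmentSchedule("drugX", 0, 100), coarseGrid(48)),
    "horizon")
})
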