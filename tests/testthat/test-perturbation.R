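test_that("delay composition scales exit hazard multiplicatively", {
  expect_equal(effectiveExitHazard(0.2), 0.2)
  expect_equal(effectiveExitHazard(0.2, 0), 0.2)
  expect_equal(effectiveExitHazard(1, c(0.5, 0.5)), 0.25)
  expect_equal(effectiveExitHazard(0.3, 1), 0)
  # an 88% DNA-synthesis inhibition reduces S transit speed to 12%
  expect_equal(effectiveExitHazard(1, 0.88), 0.12)
})

test_that("checkpoint split conserves flux and honours the block probability", {
  s <- applyCheckpointBlock(100, 0.23)
  expect_equal(s$passing, 77)
  expect_equal(s$blocked, 23)
  expect_equal(s$passing + s$blocked, 100)
  expect_equal(applyCheckpointBlock(50, 1)$passing, 0)
  # a 0.98 block probability lets 2% of each arriving cohort into S
  expect_equal(applyCheckpointBlock(100, 0.98)$passing, 2)
})

test_that("recycling and death follow first-order kinetics", {
  expect_equal(recycleFlux(100, 0), 0)
  expect_equal(recycleFlux(100, 0.24), 24)
  expect_equal(applyDeath(1000, 0.010), 10)
  expect_equal(applyDeath(0, 0.5), 0)
})

test_that("module and model validity enforce the grammar", {
  expect_error(perturbationModule("x", "delay", "S", 0, magnitude = 1.2),
               "magnitude")
  expect_error(perturbationModule("x", "death", "S", 0, magnitude = -0.1),
               "rate")
  expect_error(perturbationModule("x", "teleport", "S", 0, 0.1), "effect")
  m1 <- perturbationModule("b1", "block", "G1", 1, 0.5)
  m2 <- perturbationModule("b2", "block", "G1", 1, 0.3)
  expect_error(drugModel("d", modules = list(m1, m2)), "one block module")
  # same phase, different generation set is allowed
  m3 <- perturbationModule("b3", "block", "G1", 0, 0.3)
  expect_s4_class(drugModel("d", modules = list(m1, m3)), "DrugModel")
})

test_that("generation shorthand '0/1' expands to both generations", {
  m <- perturbationModule("x", "delay", "S", "0/1", 0.5)
  expect_identical(m@generations, c(0L, 1L))
})

test_that("rate tables honour windows, generation scope and composition", {
  times <- seq(0, 96, by = 2)
  sch <- treatmentSchedule("drugX", 0, 48)
  dm <- drugModel("drugX", modules = list(
    perturbationModule("d1", "delay", "S", 0, 0.5, window = "during"),
    perturbationModule("d2", "delay", "S", 0, 0.5, window = "during"),
    perturbationModule("post", "delay", "G2M", 1, 0.3, window = "post"),
    perturbationModule("k", "block", "G1", 1, 0.8, window = "during"),
    perturbationModule("mu", "death", "S", "0/1", 0.02, window = "during")))
  tab <- cytokinetics:::.buildRateTables(list(dm), sch, 4L, times)
  iDuring <- which(times == 24); iPost <- which(times == 72)
  expect_equal(tab$speed[2, 1, iDuring], 0.25)  # two 0.5 delays compose
  expect_equal(tab$speed[2, 1, iPost], 1)       # off after washout
  expect_equal(tab$speed[3, 2, iPost], 0.7)     # post module on after washout
  expect_equal(tab$speed[3, 2, iDuring], 1)
  expect_equal(tab$block[1, 2, iDuring], 0.8)
  expect_equal(tab$death[2, 1, iDuring], 0.02)
  expect_equal(tab$death[2, 3, iDuring], 0)     # generation 2 untargeted
})

test_that("a zero-magnitude drug reproduces the untreated trajectory bit for bit", {
  p <- fastParams()
  g <- coarseGrid(48)
  sch <- treatmentSchedule("drugX", 0, 24)
  nil <- drugModel("drugX", modules = list(
    perturbationModule("d", "delay", "S", 0, 0, window = "during"),
    perturbationModule("b", "block", "G1", 1, 0, window = "during"),
    perturbationModule("k", "death", "S", 0, 0, window = "during")))
  init <- steadyStateInit(p, 1000, g)
  t0 <- simulatePopulation(p, list(), NULL, g, init = init)
  t1 <- simulatePopulation(p, list(nil), sch, g, init = init)
  expect_identical(t0@observables, t1@observables)
})
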