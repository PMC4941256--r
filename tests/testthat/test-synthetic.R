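test_that("zero noise reproduces the noiseless simulation exactly", {
  p <- fastParams(3L)
  g <- coarseGrid(48)
  des <- experimentDesign(fcTimes = c(0, 24, 48), tlTimes = seq(0, 48, 12),
                          countTimes = c(0, 48))
  ds <- generateDataset(p, design = des, noise = noiseModel(0, 0, 0, 0),
                        grid = g, seed = 3)
  truth <- attr(ds, "truth")
  key <- function(d) paste(d$stream, d$time_h, d$variable, d$generation)
  m <- match(key(ds), key(truth))
  expect_equal(ds$value, truth$value[m], tolerance = 1e-12)
})

test_that("datasets are reproducible given the seed", {
  p <- fastParams(3L)
  g <- coarseGrid(48)
  des <- experimentDesign(fcTimes = c(0, 24), tlTimes = c(0, 24),
                          countTimes = c(0, 24))
  a <- generateDataset(p, design = des, grid = g, seed = 9)
  b <- generateDataset(p, design = des, grid = g, seed = 9)
  expect_identical(a, b)
})

test_that("FC replicate means scatter as predicted by the renormalized noise law", {
  p <- fastParams(3L)
  g <- simulationGrid(dt = 2, horizon = 2)
  des <- experimentDesign(fcTimes = 0, tlTimes = 0, countTimes = 0,
                          fcReplicates = 3L)
  tr <- simulatePopulation(p, grid = g)
  p1 <- tr@observables$pct_G1[1] / 100
  sigma <- 2
  nDatasets <- 1500
  means <- vapply(seq_len(nDatasets), function(s) {
    ds <- generateDataset(p, design = des, grid = g, seed = s,
                          noise = noiseModel(fcSd = sigma, tlCv = 0,
                                             countCv = 0))
    mean(ds$value[ds$stream == "fc" & ds$variable == "pct_G1"])
  }, numeric(1))
  # renormalizing to 100 shrinks the per-replicate SD: for percentage p,
  # Var = sigma^2 [(1-p)^2 + 2 p^2] (independent oracle: delta method on
  # x_i' = 100 (x_i + e_i)/sum(x_j + e_j))
  predicted <- sigma * sqrt((1 - p1)^2 + 2 * p1^2) / sqrt(3)
  expect_equal(stats::sd(means), predicted, tolerance = 0.08)
})

test_that("SRB grids honour the truth surface, its monotonicity and the zero dose", {
  f <- loeweAdditiveSurface(ic50A = 2, ic50B = 40, hill = 1.5)
  dosesA <- c(0, 0.5, 1, 2, 4, 8)
  dosesB <- c(0, 10, 20, 40, 80)
  g0 <- generateSrbGrid(f, dosesA, dosesB, noise = noiseModel(srbCv = 0),
                        nReps = 1, seed = 1)
  truth <- attr(g0, "truth")
  expect_equal(g0$inhibition, truth$inhibition, tolerance = 1e-12)
  expect_equal(g0$inhibition[g0$dose_A == 0 & g0$dose_B == 0], 0)
  # noiseless grid is monotone along every ray
  for (b in dosesB) {
    ray <- g0$inhibition[g0$dose_B == b][order(dosesA)]
    expect_true(all(diff(ray) >= -1e-12))
  }
  gN <- generateSrbGrid(f, dosesA, dosesB, noise = noiseModel(srbCv = 0.07),
                        nReps = 4, seed = 1)
  z <- gN$inhibition[gN$dose_A == 0 & gN$dose_B == 0]
  expect_lt(abs(mean(z)), 0.15)
  expect_gt(stats::sd(z), 0)
})

test_that("model-based growth inhibition increases with cytostatic strength", {
  p <- fastParams(3L)
  g <- coarseGrid(72)
  sch <- treatmentSchedule("drugX", 0, 48)
  weak <- srbInhibition(p, list(delayDrug(0.3)), sch, g, readoutTime = 72)
  strong <- srbInhibition(p, list(delayDrug(0.9)), sch, g, readoutTime = 72)
  expect_gt(weak, 0)
  expect_gt(strong, weak)
  expect_lt(strong, 1)
})
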