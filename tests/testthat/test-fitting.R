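makeFitFixture <- function(noise = noiseModel(0, 0, 0, 0), seed = 1,
                           magnitude = 0.6) {
  p <- fastParams(3L)
  g <- coarseGrid(48)
  sch <- treatmentSchedule("drugX", 0, 48)
  truth <- delayDrug(magnitude)
  des <- experimentDesign(fcTimes = c(0, 24, 48), tlTimes = seq(0, 48, 6),
                          countTimes = c(0, 24, 48))
  ds <- generateDataset(p, list(truth), sch, des, noise, g, seed = seed)
  list(p = p, g = g, sch = sch, truth = truth, ds = ds)
}

test_that("the objective vanishes on noiseless self-generated data", {
  fx <- makeFitFixture()
  expect_lt(objectiveValue(fx$ds, fx$p, list(fx$truth), fx$sch, fx$g), 1e-12)
  wrong <- delayDrug(0.3)
  expect_gt(objectiveValue(fx$ds, fx$p, list(wrong), fx$sch, fx$g), 1)
})

test_that("objective is invariant to dataset row order and count rescaling", {
  fx <- makeFitFixture(noise = noiseModel())
  base <- objectiveValue(fx$ds, fx$p, list(fx$truth), fx$sch, fx$g)
  shuf <- fx$ds[sample(nrow(fx$ds)), ]
  expect_equal(objectiveValue(shuf, fx$p, list(fx$truth), fx$sch, fx$g), base)
})

test_that("inverse-variance weighting responds to the stated SEMs", {
  fx <- makeFitFixture(noise = noiseModel())
  s <- summarizeDataset(fx$ds)
  base <- objectiveValue(s, fx$p, list(delayDrug(0.5)), fx$sch, fx$g)
  s2 <- s
  fcRows <- s2$stream == "fc"
  s2$sem[fcRows] <- 2 * s2$sem[fcRows]
  infl <- objectiveValue(s2, fx$p, list(delayDrug(0.5)), fx$sch, fx$g)
  fcPart <- base - objectiveValue(s[!fcRows, ], fx$p, list(delayDrug(0.5)),
                                  fx$sch, fx$g)
  # doubling FC SEMs divides the FC contribution by 4
  expect_equal(base - infl, fcPart * 3 / 4, tolerance = 1e-9)
})

test_that("summaries pool dispersions when asked and apply the detection floor", {
  fx <- makeFitFixture(noise = noiseModel())
  s <- summarizeDataset(fx$ds, weighting = "pooled")
  for (str in unique(s$stream))
    expect_equal(length(unique(s$sd[s$stream == str])), 1L)
  sf <- summarizeDataset(fx$ds, minCount = 5)
  expect_true(all(expm1(sf$mean[sf$stream == "tl"]) >= 5))
  expect_true(any(s$stream == "tl" & expm1(s$mean) < 5))
})

test_that("an all-fixed specification evaluates without searching", {
  fx <- makeFitFixture()
  sp <- list(parameterSpec("d1", "drugX", "d1", free = FALSE))
  fit <- fitModel(fx$ds, fx$p, list(fx$truth), fx$sch, sp, fx$g)
  expect_equal(fit@nFree, 0L)
  expect_lt(fit@objective, 1e-12)
})

test_that("a single free delay is recovered from noiseless data", {
  fx <- makeFitFixture()
  sp <- list(parameterSpec("d1", "drugX", "d1", lower = 0, upper = 1))
  fit <- fitModel(fx$ds, fx$p, list(delayDrug(0.2)), fx$sch, sp, fx$g,
                  nStarts = 3, seed = 1)
  expect_equal(unname(fit@estimates["d1"]), 0.6, tolerance = 1e-3)
})

test_that("parameters inactive over the observation window are auto-fixed", {
  fx <- makeFitFixture()
  late <- drugModel("drugX", modules = c(fx$truth@modules, list(
    perturbationModule("ghost", "delay", "G2M", 0, 0.5,
                       profile = timeProfile("step_window", onset = 90,
                                             offset = 96),
                       window = "all"))))
  sp <- list(parameterSpec("d1", "drugX", "d1"),
             parameterSpec("ghost", "drugX", "ghost"))
  expect_warning(
    fit <- fitModel(fx$ds, fx$p, list(late), fx$sch, sp, fx$g, nStarts = 2),
    "inactive")
  expect_false("ghost" %in% names(fit@estimates))
})

test_that("bootstrap intervals cover and widen with noise", {
  quiet <- makeFitFixture(noise = noiseModel(1, 0.03, 0.02, 0), seed = 4)
  loud <- makeFitFixture(noise = noiseModel(4, 0.15, 0.1, 0), seed = 4)
  sp <- list(parameterSpec("d1", "drugX", "d1", lower = 0, upper = 1))
  width <- function(fx) {
    fit <- fitModel(fx$ds, fx$p, list(delayDrug(0.4)), fx$sch, sp, fx$g,
                    nStarts = 2, seed = 1)
    fit <- uncertaintyIntervals(fit, fx$ds, fx$p, list(delayDrug(0.4)),
                                fx$sch, fx$g, nBoot = 14, seed = 2)
    iv <- intervals(fit)
    c(width = iv[1, 2] - iv[1, 1],
      covers = iv[1, 1] <= 0.6 && iv[1, 2] >= 0.6)
  }
  wq <- width(quiet)
  wl <- width(loud)
  expect_gt(wl["width"], wq["width"])
  expect_true(as.logical(wq["covers"]) || as.logical(wl["covers"]))
})

test_that("bootstrap on noiseless data warns about degeneracy and collapses", {
  fx <- makeFitFixture()
  sp <- list(parameterSpec("d1", "drugX", "d1", lower = 0, upper = 1))
  fit <- fitModel(fx$ds, fx$p, list(fx$truth), fx$sch, sp, fx$g, nStarts = 1)
  expect_warning(
    fit <- uncertaintyIntervals(fit, fx$ds, fx$p, list(fx$truth), fx$sch,
                                fx$g, nBoot = 6, seed = 1),
    "degenerate")
  iv <- intervals(fit)
  expect_lt(iv[1, 2] - iv[1, 1], 1e-3)
})

test_that("model comparison rejects never on identical fits and demands nesting", {
  fx <- makeFitFixture(noise = noiseModel())
  spR <- list(parameterSpec("d1", "drugX", "d1"))
  fR <- fitModel(fx$ds, fx$p, list(fx$truth), fx$sch, spR, fx$g, nStarts = 2)
  same <- new("FitResult", estimates = c(fR@estimates, extra = 0.1),
              objective = fR@objective, intervals = fR@intervals,
              nObs = fR@nObs, nFree = 2L, converged = TRUE, details = list())
  cmp <- compareModels(fR, same)
  expect_false(cmp$rejectReduced)
  expect_equal(cmp$statistic, 0)
  other <- new("FitResult", estimates = c(zz = 1), objective = 1,
               intervals = fR@intervals, nObs = fR@nObs, nFree = 1L,
               converged = TRUE, details = list())
  expect_error(compareModels(fR, other), "not nested")
  expect_error(compareModels(same, fR), "not nested")
})
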