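test_that("an empty second model leaves the first-drug trajectory untouched", {
  p <- fastParams()
  g <- coarseGrid(96)
  gm <- shippedModel("bxpc3_gemcitabine_20nM")
  emptyB <- drugModel("erlotinib")
  sch <- shippedSchedule("GE")
  seq1 <- simulateSequential(p, gm, emptyB, sch, g)
  alone <- simulatePopulation(p, list(gm), shippedSchedule("gemcitabine"), g)
  expect_equal(seq1@observables, alone@observables, tolerance = 1e-12)
})

test_that("switching at t = 0 reproduces the second drug alone", {
  p <- fastParams()
  g <- coarseGrid(96)
  e1 <- shippedModel("bxpc3_erlotinib_1uM")
  emptyA <- drugModel("gemcitabine")
  sch <- treatmentSchedule(c("gemcitabine", "erlotinib"), c(0, 0), c(1e-9 + 0, 48))
  # zero-length interval contributes nothing; drug B runs from t = 0
  sch@intervals$end[1] <- 2
  seq1 <- simulateSequential(p, emptyA, e1, sch, g)
  alone <- simulatePopulation(p, list(e1), shippedSchedule("erlotinib"), g)
  expect_equal(seq1@observables, alone@observables, tolerance = 1e-12)
})

test_that("gemcitabine pre-treatment hands over a semi-synchronized S-phase wave", {
  p <- fastParams()
  g <- coarseGrid(96)
  gm <- shippedModel("bxpc3_gemcitabine_20nM")
  e1 <- shippedModel("bxpc3_erlotinib_1uM")
  tr <- simulateSequential(p, gm, e1, shippedSchedule("GE"), g,
                           keepTimes = 24)
  untreated <- simulatePopulation(p, grid = g)
  sAt24 <- atTime(tr, 24)$pct_S
  expect_gt(sAt24, atTime(untreated, 24)$pct_S)
  # the full population state carries across the switch: cell number is
  # continuous there
  obs <- tr@observables
  i <- which(obs$time_h == 24)
  step <- abs(obs$n_total[i + 1] - obs$n_total[i]) / obs$n_total[i]
  expect_lt(step, 0.05)
})

test_that("the no-interaction prediction emits the comparison axes", {
  p <- fastParams()
  pred <- noInteractionPrediction(p, shippedModel("bxpc3_gemcitabine_20nM"),
                                  shippedModel("bxpc3_erlotinib_1uM"),
                                  shippedSchedule("GE"), coarseGrid(96))
  expect_equal(pred$fc$time_h, c(72, 96))
  expect_true(all(abs(rowSums(pred$fc[, -1]) - 100) < 1e-9))
  expect_gt(pred$countIncrease, 1)
  pred2 <- noInteractionPrediction(p, shippedModel("bxpc3_gemcitabine_20nM"),
                                   shippedModel("bxpc3_erlotinib_1uM"),
                                   shippedSchedule("GE"), coarseGrid(96))
  expect_identical(pred$fc, pred2$fc)
})

test_that("overlap policies supersede, error or compose as configured", {
  p <- fastParams(3L)
  g <- coarseGrid(72)
  a <- drugModel("A", modules = list(
    perturbationModule("dSa", "delay", "S", 1, 0.5, window = "post")))
  b <- drugModel("B", modules = list(
    perturbationModule("dSb", "delay", "S", 1, 0.4, window = "during")))
  sch <- treatmentSchedule(c("A", "B"), c(0, 24), c(6, 72))
  expect_error(simulateSequential(p, a, b, sch, g, policy = "error"),
               "overlapping")
  sup <- simulateSequential(p, a, b, sch, g, policy = "supersede")
  comp <- simulateSequential(p, a, b, sch, g, policy = "compose")
  # composed delays slow S further than the superseded model
  expect_lt(tail(comp@observables$n_total, 1),
            tail(sup@observables$n_total, 1))
})

test_that("refitting null-interaction data does not flag the freed parameter", {
  p <- fastParams()
  g <- coarseGrid(96)
  gm <- shippedModel("bxpc3_gemcitabine_20nM")
  e1 <- shippedModel("bxpc3_erlotinib_1uM")
  sch <- shippedSchedule("GE")
  drugsGen <- cytokinetics:::.resolveSequential(gm, e1, sch)
  ds <- generateDataset(p, drugsGen, sch, experimentDesign(), noiseModel(),
                        g, seed = 21)
  ref <- shippedIntervals("bxpc3_erlotinib_1uM")
  ref <- data.frame(parameter = ref$parameter, value = ref$value,
                    lower = ref$lower, upper = ref$upper)
  sp <- list(parameterSpec("delayS.post.g1", "erlotinib", "delayS.post.g1"))
  res <- refitInteraction(ds, p, gm, e1, sch, sp, ref, g, nBoot = 6,
                          seed = 1, nStarts = 2)
  expect_false(res$delta$changed)
  expect_error(refitInteraction(ds, p, gm, e1, sch, list(), ref, g),
               "at least one")
})
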