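hill <- function(d, ic50, h, top = 1, bottom = 0) {
  bottom + (top - bottom) / (1 + (ic50 / pmax(d, 1e-300))^h)
}

test_that("exact four-parameter logistic data are recovered to high precision", {
  d <- c(0, 0.25, 0.5, 1, 2, 4, 8, 16)
  y <- hill(d, ic50 = 2, h = 1.8, top = 0.9, bottom = 0.05)
  fit <- fitRay(d, y)
  co <- fit$coefficients
  expect_equal(unname(co["ec50"]), 2, tolerance = 1e-5)
  expect_equal(unname(co["hill"]), 1.8, tolerance = 1e-4)
  expect_equal(unname(co["top"]), 0.9, tolerance = 1e-5)
  expect_equal(unname(co["bottom"]), 0.05, tolerance = 1e-5)
  expect_false(fit$nonMonotone)
})

test_that("IC50 of a symmetric curve equals its midpoint and inversion round-trips", {
  d <- c(0, 0.5, 1, 2, 4, 8, 16)
  fit <- fitRay(d, hill(d, 3, 1.5))
  expect_equal(as.numeric(icLevel(fit, 0.5)), 3, tolerance = 1e-4)
  ic30 <- icLevel(fit, 0.30)
  expect_equal(hill(as.numeric(ic30), 3, 1.5), 0.30, tolerance = 1e-4)
  # unreachable level is reported as such
  lowtop <- fitRay(d, hill(d, 3, 1.5, top = 0.4))
  expect_true(is.na(icLevel(lowtop, 0.5)))
  expect_true(isTRUE(attr(icLevel(lowtop, 0.5), "unreachable")))
})

test_that("the Combination Index obeys the Loewe identities", {
  expect_equal(combinationIndex(2, 0, 2, 37), 1)
  expect_equal(combinationIndex(0, 37, 2, 37), 1)
  # sham self-combination: any split of the iso-effective dose gives CI 1
  ic <- 5
  for (f in c(0.2, 0.5, 0.8))
    expect_equal(combinationIndex(f * ic, (1 - f) * ic, ic, ic), 1,
                 tolerance = 1e-12)
  # relabeling invariance
  expect_equal(combinationIndex(1, 10, 2, 40), combinationIndex(10, 1, 40, 2))
  expect_true(is.na(combinationIndex(1, 1, NA, 40)))
})

test_that("a Loewe-additive surface yields CI near 1 across the pipeline", {
  f <- loeweAdditiveSurface(ic50A = 2, ic50B = 40, hill = 1.6)
  dosesA <- c(0, 0.5, 1, 2, 4, 8)
  dosesB <- c(0, 10, 20, 40, 80, 160)
  g0 <- generateSrbGrid(f, dosesA, dosesB, noise = noiseModel(srbCv = 0),
                        nReps = 2, seed = 1)
  res <- isoboleAnalysis(g0, levels = c(0.3, 0.5))
  expect_true(all(res$ci > 0))
  expect_lt(max(abs(res$ci[!res$extrapolated] - 1)), 0.12)
  ics <- attr(res, "singleAgentIC")
  expect_equal(unname(ics$ic_0.5["A"]), 2, tolerance = 0.02)
  expect_equal(unname(ics$ic_0.5["B"]), 40, tolerance = 0.02)
})

test_that("bootstrap CI intervals bracket the point estimates", {
  f <- loeweAdditiveSurface(2, 40, 1.6)
  g1 <- generateSrbGrid(f, c(0, 0.5, 1, 2, 4, 8), c(0, 10, 20, 40, 80),
                        noise = noiseModel(srbCv = 0.07), nReps = 8, seed = 2)
  res <- isoboleAnalysis(g1, levels = 0.5, nBoot = 20, seed = 3)
  ok <- is.finite(res$ciLower) & is.finite(res$ciUpper)
  expect_gt(mean(ok), 0.8)
  expect_true(all(res$ciLower[ok] <= res$ciUpper[ok]))
})
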