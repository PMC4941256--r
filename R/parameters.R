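#' Construct unperturbed cell-cycle parameters
#'
#' @param meanG1,meanS,meanG2M mean phase durations, hours.
#' @param cvG1,cvS,cvG2M coefficients of variation of the gamma-distributed
#'   phase transit times, each in (0, 1].
#' @param maxGeneration highest tracked generation; later divisions are
#'   lumped into a self-renewing compartment.
#' @return a \code{\linkS4class{CellCycleParameters}} object.
#' @examples
#' p <- cellCycleParameters(9, 8, 5, 0.2, 0.15, 0.2)
#' cycleTime(p)
#' @export
cellCycleParameters <- function(meanG1, meanS, meanG2M,
                                cvG1 = 0.2, cvS = 0.15, cvG2M = 0.2,
                                maxGeneration = 5L) {
  new("CellCycleParameters", meanG1 = meanG1, meanS = meanS, meanG2M = meanG2M,
      cvG1 = cvG1, cvS = cvS, cvG2M = cvG2M,
      maxGeneration = as.integer(maxGeneration))
}

#' Mean cell-cycle time (sum of mean phase durations), hours
#' @param params a \code{CellCycleParameters} object.
#' @export
cycleTime <- function(params) params@meanG1 + params@meanS + params@meanG2M

.phaseMeans <- function(params) c(params@meanG1, params@meanS, params@meanG2M)
.phaseCvs <- function(params) c(params@cvG1, params@cvS, params@cvG2M)

# gamma (shape, rate) matching a given mean and CV
.gammaShapeRate <- function(mean, cv) {
  shape <- 1 / cv^2
  list(shape = shape, rate = shape / mean)
}

#' Per-phase transit-time law on the discrete age grid
#'
#' Discretizes the gamma transit-time distribution of one phase on age bins
#' of width \code{dt}: survival at bin edges and the per-bin conditional
#' exit probability (discrete hazard). The final bin absorbs the residual
#' tail so every cohort eventually exits.
#'
#' @param mean,cv gamma mean (hours) and coefficient of variation.
#' @param dt age-bin width, hours.
#' @param tail tail mass beyond which the grid is truncated.
#' @return list with elements \code{edges}, \code{surv}, \code{exitProb}
#'   (unconditional P(exit in bin i)), \code{hazard} (conditional) and
#'   \code{nBins}.
#' @export
phaseStepDistribution <- function(mean, cv, dt, tail = 1e-12) {
  gp <- .gammaShapeRate(mean, cv)
  aMax <- stats::qgamma(1 - tail, gp$shape, gp$rate)
  nBins <- max(2L, ceiling(aMax / dt))
  edges <- (0:nBins) * dt
  surv <- stats::pgamma(edges, gp$shape, gp$rate, lower.tail = FALSE)
  p <- surv[-length(surv)] - surv[-1]
  p[nBins] <- p[nBins] + surv[nBins + 1L]
  hazard <- ifelse(surv[1:nBins] > 0, p / surv[1:nBins], 1)
  list(edges = edges, surv = surv[1:nBins], exitProb = p,
       hazard = pmin(hazard, 1), nBins = nBins)
}

#' Balanced exponential growth of the unperturbed population
#'
#' Solves the discrete renewal equation of the age-structured chain,
#' \eqn{2\,G_{G1}(z)\,G_S(z)\,G_{G2M}(z) = 1}, where \eqn{G_p(z)} is the
#' probability generating function of the number of steps spent in phase
#' \eqn{p} and \eqn{z} the per-step discount. The root gives the exact
#' per-step growth factor of the discrete engine, the Malthusian rate and
#' the doubling time; also returns the stationary phase-entry fluxes and
#' phase occupancy fractions.
#'
#' @param params a \code{CellCycleParameters} object.
#' @param dt discretization step, hours.
#' @return list with \code{z}, \code{growthFactor} (per step), \code{lambda}
#'   (per hour), \code{doublingTime} (hours), \code{entryFlux} (per phase),
#'   \code{phaseFractions}, and the per-phase discretized distributions.
#' @export
growthRate <- function(params, dt = 0.5) {
  means <- .phaseMeans(params)
  cvs <- .phaseCvs(params)
  dists <- lapply(1:3, function(p) phaseStepDistribution(means[p], cvs[p], dt))
  G <- function(z, d) sum(d$exitProb * z^(seq_len(d$nBins)))
  f <- function(z) 2 * G(z, dists[[1]]) * G(z, dists[[2]]) * G(z, dists[[3]]) - 1
  root <- tryCatch(
    stats::uniroot(f, interval = c(1e-8, 1 - 1e-12), tol = 1e-14),
    error = function(e) stop("growth-rate eigenproblem did not converge: ",
                             conditionMessage(e))
  )
  z <- root$root
  lambda <- -log(z) / dt
  flux <- numeric(3)
  flux[1] <- 1
  flux[2] <- flux[1] * G(z, dists[[1]])
  flux[3] <- flux[2] * G(z, dists[[2]])
  occ <- vapply(1:3, function(p) {
    d <- dists[[p]]
    sum(flux[p] * z^(0:(d$nBins - 1L)) * d$surv)
  }, numeric(1))
  list(z = z, growthFactor = 1 / z, lambda = lambda,
       doublingTime = log(2) / lambda, entryFlux = flux,
       phaseFractions = occ / sum(occ), dists = dists, dt = dt)
}

setMethod("show", "CellCycleParameters", function(object) {
  cat("CellCycleParameters\n")
  cat(sprintf("  mean durations (h): G1 %.3g | S %.3g | G2M %.3g  (Tc %.3g)\n",
              object@meanG1, object@meanS, object@meanG2M, cycleTime(object)))
  cat(sprintf("  CVs: %.3g / %.3g / %.3g; generations tracked: 0..%d (lumped above)\n",
              object@cvG1, object@cvS, object@cvG2M, object@maxGeneration))
})
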