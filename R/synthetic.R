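#' Construct a replicate-noise model
#'
#' Defaults emulate the replicate scatter of triplicate flow-cytometry
#' experiments, five-well time-lapse counts, triplicate Coulter counts and
#' replicate-plate SRB growth-inhibition readouts.
#'
#' @param fcSd additive Gaussian SD on phase percentages, points.
#' @param tlCv,countCv,srbCv lognormal (multiplicative, mean-1) CVs.
#' @export
noiseModel <- function(fcSd = 2.5, tlCv = 0.08, countCv = 0.05,
                       srbCv = 0.07) {
  new("NoiseModel", fcSd = fcSd, tlCv = tlCv, countCv = countCv, srbCv = srbCv)
}

# mean-1 lognormal multipliers with coefficient of variation cv
.lnormNoise <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  s2 <- log(1 + cv^2)
  exp(stats::rnorm(n, -s2 / 2, sqrt(s2)))
}

#' Generate a noisy synthetic FC/TL/count dataset from a ground truth
#'
#' Simulates the ground-truth model and draws replicates: Gaussian noise on
#' phase percentages (clamped at 0 and renormalized to 100), lognormal
#' multiplicative noise on per-generation time-lapse counts and on absolute
#' cell counts. With all dispersions 0 the dataset equals the noiseless
#' simulation; output is reproducible given the seed.
#'
#' @inheritParams simulatePopulation
#' @param design an \code{ExperimentDesign}.
#' @param noise a \code{NoiseModel}.
#' @param seed RNG seed.
#' @return a tidy data.frame (time_h, stream, variable, generation,
#'   replicate, value) with attribute \code{truth} holding the noiseless
#'   tidy series.
#' @export
generateDataset <- function(params, drugs = list(), schedule = NULL,
                            design = experimentDesign(),
                            noise = noiseModel(), grid = simulationGrid(),
                            n0 = 1000, seed = 1) {
  set.seed(seed)
  horizon <- max(design@fcTimes, design@tlTimes, design@countTimes)
  if (grid@horizon < horizon)
    stop("simulation horizon shorter than the latest observation time")
  tr <- simulatePopulation(params, drugs, schedule, grid, n0 = n0)
  obs <- tr@observables
  rows <- list()

  fc <- obs[obs$time_h %in% design@fcTimes, , drop = FALSE]
  for (r in if (nrow(fc)) seq_len(design@fcReplicates) else integer()) {
    pct <- as.matrix(fc[, c("pct_G1", "pct_S", "pct_G2M")])
    pct <- pct + matrix(stats::rnorm(length(pct), 0, noise@fcSd),
                        nrow = nrow(pct))
    pct <- pmax(pct, 0)
    pct <- 100 * pct / rowSums(pct)
    for (j in 1:3)
      rows[[length(rows) + 1L]] <- data.frame(
        time_h = fc$time_h, stream = "fc",
        variable = c("pct_G1", "pct_S", "pct_G2M")[j],
        generation = NA_integer_, replicate = r, value = pct[, j])
  }

  tl <- obs[obs$time_h %in% design@tlTimes, , drop = FALSE]
  genCols <- grep("^n_gen", names(obs), value = TRUE)
  for (r in seq_len(design@tlWells)) {
    for (col in genCols) {
      g <- as.integer(sub("n_gen", "", col))
      v <- tl[[col]] * .lnormNoise(nrow(tl), noise@tlCv)
      rows[[length(rows) + 1L]] <- data.frame(
        time_h = tl$time_h, stream = "tl", variable = "n", generation = g,
        replicate = r, value = v)
    }
  }

  ct <- obs[obs$time_h %in% design@countTimes, , drop = FALSE]
  for (r in seq_len(design@countReplicates)) {
    v <- ct$n_total * .lnormNoise(nrow(ct), noise@countCv)
    rows[[length(rows) + 1L]] <- data.frame(
      time_h = ct$time_h, stream = "count", variable = "n_total",
      generation = NA_integer_, replicate = r, value = v)
  }

  ds <- do.call(rbind, rows)
  rownames(ds) <- NULL
  attr(ds, "truth") <- tidyObservables(obs, design)
  ds
}

#' Growth inhibition of one treated model relative to control
#'
#' Simulates treated and untreated populations and returns
#' \eqn{1 - N_{treated}(t_r)/N_{control}(t_r)} at the readout time.
#'
#' @inheritParams simulatePopulation
#' @param readoutTime assay readout, hours (must lie on the grid).
#' @export
srbInhibition <- function(params, drugs, schedule, grid = simulationGrid(),
                          readoutTime = grid@horizon, n0 = 1000) {
  init <- steadyStateInit(params, n0, grid)
  trt <- simulatePopulation(params, drugs, schedule, grid, init = init)
  ctl <- simulatePopulation(params, list(), NULL, grid, init = init)
  at <- function(tr) {
    i <- which.min(abs(tr@observables$time_h - readoutTime))
    tr@observables$n_total[i]
  }
  1 - at(trt) / at(ctl)
}

#' Generate a noisy SRB dose-response grid from a truth surface
#'
#' @param inhibition function(a, b) returning the true growth-inhibition
#'   fraction for dose pair (a, b); evaluated on the full factorial grid.
#' @param dosesA,dosesB dose vectors (including 0).
#' @param noise a \code{NoiseModel}; its \code{srbCv} is applied as
#'   lognormal noise on the survival fraction, so zero-dose wells scatter
#'   around inhibition 0 (small negative values can occur, as in real
#'   assays).
#' @param nReps replicate plates per pair (default 8: two experiments of
#'   four plates).
#' @param seed RNG seed.
#' @return tidy data.frame (dose_A, dose_B, replicate, inhibition).
#' @export
generateSrbGrid <- function(inhibition, dosesA, dosesB,
                            noise = noiseModel(), nReps = 8L, seed = 1) {
  set.seed(seed)
  grd <- expand.grid(dose_A = dosesA, dose_B = dosesB)
  truth <- mapply(inhibition, grd$dose_A, grd$dose_B)
  rows <- lapply(seq_len(nReps), function(r) {
    surv <- pmax(1 - truth, 0) * .lnormNoise(nrow(grd), noise@srbCv)
    data.frame(dose_A = grd$dose_A, dose_B = grd$dose_B, replicate = r,
               inhibition = 1 - surv)
  })
  out <- do.call(rbind, rows)
  attr(out, "truth") <- cbind(grd, inhibition = truth)
  out
}

#' Loewe-additive two-drug inhibition surface
#'
#' Builds the unique surface that satisfies Loewe additivity for two
#' single-agent Hill curves with a common slope: the effect E(a, b) solves
#' \eqn{a/\mathrm{IC}_E^A + b/\mathrm{IC}_E^B = 1} with
#' \eqn{\mathrm{IC}_E = \mathrm{IC}_{50} (E/(1-E))^{1/h}}. Useful as a
#' synthetic truth for testing the Combination-Index pipeline under the
#' additivity null (CI = 1 everywhere).
#'
#' @param ic50A,ic50B single-agent IC50s.
#' @param hill common Hill slope (> 0).
#' @return function(a, b) returning the inhibition fraction.
#' @export
loeweAdditiveSurface <- function(ic50A, ic50B, hill = 1.5) {
  icE <- function(ic50, E) ic50 * (E / (1 - E))^(1 / hill)
  function(a, b) {
    if (a <= 0 && b <= 0) return(0)
    f <- function(E) a / icE(ic50A, E) + b / icE(ic50B, E) - 1
    stats::uniroot(f, c(1e-9, 1 - 1e-9), tol = 1e-12)$root
  }
}

setMethod("show", "NoiseModel", function(object) {
  cat(sprintf("NoiseModel: fcSd %g pts | tlCv %g | countCv %g | srbCv %g\n",
              object@fcSd, object@tlCv, object@countCv, object@srbCv))
})

setMethod("show", "ExperimentDesign", function(object) {
  cat(sprintf("ExperimentDesign: FC %d times x%d | TL %d times x%d wells | counts %d times x%d\n",
              length(object@fcTimes), object@fcReplicates,
              length(object@tlTimes), object@tlWells,
              length(object@countTimes), object@countReplicates))
})
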