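#' Construct a simulation grid
#' @param dt time step and age-bin width, hours.
#' @param horizon simulated duration, hours.
#' @export
simulationGrid <- function(dt = 0.5, horizon = 96) {
  new("SimulationGrid", dt = dt, horizon = horizon)
}

.nGen <- function(params) params@maxGeneration + 1L

.emptyCompartments <- function(nGen) {
  lapply(1:3, function(p) lapply(seq_len(nGen), function(g) numeric(0)))
}

#' Balanced-exponential-growth initial state
#'
#' Computes the stationary age/phase distribution of the unperturbed
#' discrete-time population chain (the dominant eigenvector of its renewal
#' operator, obtained from the generating-function root found by
#' \code{\link{growthRate}}) and loads it, normalized to \code{n0} cells,
#' into generation 0. A subsequent drug-free simulation grows exponentially
#' from t = 0 with no transient beyond numerical tolerance.
#'
#' @param params a \code{CellCycleParameters} object.
#' @param n0 initial total cell number (> 0).
#' @param grid a \code{SimulationGrid}.
#' @return a \code{\linkS4class{PopulationState}} at time 0, with attributes
#'   \code{doublingTime} (h) and \code{growth} (the \code{growthRate} list).
#' @export
steadyStateInit <- function(params, n0 = 1000, grid = simulationGrid()) {
  stopifnot(n0 > 0)
  gr <- growthRate(params, grid@dt)
  nGen <- .nGen(params)
  density <- .emptyCompartments(nGen)
  ages <- .emptyCompartments(nGen)
  for (p in 1:3) {
    d <- gr$dists[[p]]
    i <- 0:(d$nBins - 1L)
    density[[p]][[1L]] <- gr$entryFlux[p] * gr$z^i * d$surv
    ages[[p]][[1L]] <- i * grid@dt
  }
  tot <- sum(unlist(density, use.names = FALSE))
  for (p in 1:3) density[[p]][[1L]] <- density[[p]][[1L]] * (n0 / tot)
  st <- new("PopulationState", time = 0, density = density, ages = ages,
            blocked = matrix(0, 3, nGen), dead = matrix(0, 3, nGen))
  attr(st, "doublingTime") <- gr$doublingTime
  attr(st, "growth") <- gr
  st
}

#' Simulate a treated or untreated cell population
#'
#' Deterministic age-structured transport of cell cohorts through
#' G1 -> S -> G2M -> division across generations. Each step, every age bin
#' of every (phase, generation) compartment ages by \code{speed * dt}
#' (speed < 1 under delay/synthesis-inhibition modules) and exits with the
#' conditional probability implied by the gamma transit-time law; the exit
#' flux is split at the checkpoint (arrest vs passage), blocked pools drain
#' at their recycling rate, death rates remove cells to a cumulative dead
#' count, and the G2M exit flux is doubled and injected at age 0 of G1 in
#' the next generation (lumped at \code{maxGeneration}). The scheme is the
#' exact mean-field of the single-cell chain simulated by
#' \code{\link{microsimulate}}.
#'
#' @param params a \code{CellCycleParameters} object.
#' @param drugs list of \code{DrugModel} objects (empty for control growth).
#' @param schedule a \code{TreatmentSchedule} (NULL for untreated).
#' @param grid a \code{SimulationGrid}.
#' @param init a \code{PopulationState}; default
#'   \code{steadyStateInit(params, n0, grid)}.
#' @param n0 initial cell number when \code{init} is NULL.
#' @param keepTimes times (h) at which full \code{PopulationState} snapshots
#'   are retained (the final state always is).
#' @return a \code{\linkS4class{PopulationTrajectory}}.
#' @examples
#' p <- cellCycleParameters(9, 8, 5)
#' tr <- simulatePopulation(p, grid = simulationGrid(dt = 1, horizon = 48))
#' head(tr@observables)
#' @export
simulatePopulation <- function(params, drugs = list(), schedule = NULL,
                               grid = simulationGrid(), init = NULL,
                               n0 = 1000, keepTimes = numeric()) {
  dt <- grid@dt
  nSteps <- round(grid@horizon / dt)
  times <- seq(0, by = dt, length.out = nSteps + 1L)
  if (!is.null(schedule) && nrow(schedule@intervals) &&
      max(schedule@intervals$end) > grid@horizon + 1e-9)
    warning("schedule extends beyond the simulation horizon")
  if (is.null(init)) init <- steadyStateInit(params, n0, grid)
  nGen <- .nGen(params)
  gp <- lapply(1:3, function(p)
    .gammaShapeRate(.phaseMeans(params)[p], .phaseCvs(params)[p]))
  tab <- .buildRateTables(drugs, schedule, nGen, times)

  n <- init@density
  age <- init@ages
  blocked <- init@blocked
  dead <- init@dead

  obsPct <- matrix(NA_real_, nSteps + 1L, 3L)
  obsGen <- matrix(0, nSteps + 1L, nGen)
  obsTot <- numeric(nSteps + 1L)
  obsDead <- numeric(nSteps + 1L)
  obsBlocked <- numeric(nSteps + 1L)
  states <- list()

  record <- function(s) {
    phaseTot <- numeric(3)
    for (p in 1:3) {
      for (g in seq_len(nGen)) {
        v <- sum(n[[p]][[g]]) + blocked[p, g]
        phaseTot[p] <- phaseTot[p] + v
        obsGen[s, g] <<- obsGen[s, g] + v
      }
    }
    live <- sum(phaseTot)
    obsTot[s] <<- live
    obsDead[s] <<- sum(dead)
    obsBlocked[s] <<- sum(blocked)
    if (live > 0) obsPct[s, ] <<- 100 * phaseTot / live
  }
  snapshot <- function(tNow) {
    new("PopulationState", time = tNow, density = n, ages = age,
        blocked = blocked, dead = dead)
  }

  record(1L)
  for (s in seq_len(nSteps)) {
    outPass <- matrix(0, 3, nGen)
    for (p in 1:3) {
      sh <- gp[[p]]$shape; ra <- gp[[p]]$rate
      for (g in seq_len(nGen)) {
        nd <- n[[p]][[g]]; ag <- age[[p]][[g]]; pool <- blocked[p, g]
        mu <- tab$death[p, g, s]
        if (mu > 0 && (length(nd) || pool > 0)) {
          fd <- -expm1(-mu * dt)
          dead[p, g] <- dead[p, g] + fd * (sum(nd) + pool)
          nd <- nd * (1 - fd)
          pool <- pool * (1 - fd)
        }
        exitF <- 0
        v <- tab$speed[p, g, s]
        if (length(nd) && v > 0) {
          sOld <- stats::pgamma(ag, sh, ra, lower.tail = FALSE)
          sNew <- stats::pgamma(ag + v * dt, sh, ra, lower.tail = FALSE)
          h <- ifelse(sOld > 1e-300, pmin(pmax(1 - sNew / sOld, 0), 1), 1)
          exitF <- sum(nd * h)
          nd <- nd * (1 - h)
          ag <- ag + v * dt
        }
        pb <- tab$block[p, g, s]
        blockedIn <- pb * exitF
        rr <- tab$recycle[p, g, s]
        recOut <- if (rr > 0 && pool > 0) pool * (-expm1(-rr * dt)) else 0
        blocked[p, g] <- pool - recOut + blockedIn
        outPass[p, g] <- (exitF - blockedIn) + recOut
        # trim numerically empty tail bins
        len <- length(nd)
        if (len && nd[len] <= 0) {
          keep <- which(nd > 0)
          len <- if (length(keep)) max(keep) else 0L
          nd <- nd[seq_len(len)]; ag <- ag[seq_len(len)]
        }
        n[[p]][[g]] <- nd; age[[p]][[g]] <- ag
      }
    }
    if (any(outPass < 0) || any(blocked < -1e-12))
      stop("negative density at t = ", times[s],
           " h; reduce the step size (dt = ", dt, ")")
    for (g in seq_len(nGen)) {
      inS <- outPass[1, g]
      if (inS > 0) {
        n[[2]][[g]] <- c(inS, n[[2]][[g]]); age[[2]][[g]] <- c(0, age[[2]][[g]])
      }
      inM <- outPass[2, g]
      if (inM > 0) {
        n[[3]][[g]] <- c(inM, n[[3]][[g]]); age[[3]][[g]] <- c(0, age[[3]][[g]])
      }
      born <- 2 * outPass[3, g]
      if (born > 0) {
        gd <- min(g + 1L, nGen)
        n[[1]][[gd]] <- c(born, n[[1]][[gd]])
        age[[1]][[gd]] <- c(0, age[[1]][[gd]])
      }
    }
    record(s + 1L)
    if (length(keepTimes)) {
      hit <- keepTimes[abs(keepTimes - times[s + 1L]) < dt / 2]
      for (kt in hit) states[[sprintf("t%g", kt)]] <- snapshot(times[s + 1L])
    }
  }
  states[["final"]] <- snapshot(times[nSteps + 1L])

  obs <- data.frame(time_h = times, pct_G1 = obsPct[, 1], pct_S = obsPct[, 2],
                    pct_G2M = obsPct[, 3], n_total = obsTot, n_dead = obsDead,
                    n_blocked = obsBlocked, check.names = FALSE)
  for (g in seq_len(nGen)) obs[[sprintf("n_gen%d", g - 1L)]] <- obsGen[, g]
  td <- attr(init, "doublingTime")
  new("PopulationTrajectory", times = times, observables = obs,
      states = states, params = params, grid = grid,
      doublingTime = if (is.null(td)) NA_real_ else td)
}

#' Final state of a trajectory
#' @param trajectory a \code{PopulationTrajectory}.
#' @export
finalState <- function(trajectory) trajectory@states[["final"]]

#' State snapshot nearest a requested time
#' @param trajectory a \code{PopulationTrajectory} simulated with matching
#'   \code{keepTimes}.
#' @param time requested time, h.
#' @export
stateAt <- function(trajectory, time) {
  st <- trajectory@states[[sprintf("t%g", time)]]
  if (is.null(st)) stop("no snapshot kept at t = ", time,
                        " h; pass it in keepTimes when simulating")
  st
}

setMethod("show", "PopulationState", function(object) {
  live <- totalCellNumber(object)
  cat(sprintf("PopulationState at t = %g h: %.4g live cells (%.4g blocked, %.4g dead)\n",
              object@time, live, sum(object@blocked), sum(object@dead)))
  if (live > 0) {
    pct <- fcPercentages(object)
    cat(sprintf("  %%G1 %.1f | %%S %.1f | %%G2M %.1f\n", pct[1], pct[2], pct[3]))
  }
})

setMethod("show", "PopulationTrajectory", function(object) {
  cat(sprintf("PopulationTrajectory: %g-%g h, dt %g h, %d generations\n",
              min(object@times), max(object@times), object@grid@dt,
              ncol(object@observables) - 6L))
  last <- object@observables[nrow(object@observables), ]
  cat(sprintf("  final: %.4g live cells; %%G1/%%S/%%G2M = %.1f/%.1f/%.1f\n",
              last$n_total, last$pct_G1, last$pct_S, last$pct_G2M))
})
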