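#' Stochastic single-cell microsimulation (brute-force oracle)
#'
#' Simulates individual cells: each draws a gamma phase duration, ages at
#' the (possibly delay-reduced) speed of its compartment, faces Bernoulli
#' checkpoint-block decisions at phase exits, and exponential death and
#' recycling waiting times discretized to the step. Observable definitions
#' match the deterministic engine exactly; the engine is the mean field of
#' this chain, so the two agree within Monte-Carlo error.
#'
#' @inheritParams simulatePopulation
#' @param nCells initial number of simulated cells (>= 1), sampled from the
#'   balanced-growth age/phase distribution, all in generation 0.
#' @param seed RNG seed; runs are reproducible given the seed.
#' @return a wide observables data.frame with the same columns as the
#'   \code{observables} slot of a \code{PopulationTrajectory}, with
#'   attributes \code{seed} and \code{nCells}.
#' @export
microsimulate <- function(params, drugs = list(), schedule = NULL,
                          nCells = 1000, seed = 1,
                          grid = simulationGrid()) {
  stopifnot(nCells >= 1)
  set.seed(seed)
  dt <- grid@dt
  nSteps <- round(grid@horizon / dt)
  times <- seq(0, by = dt, length.out = nSteps + 1L)
  nGen <- .nGen(params)
  sh <- numeric(3); ra <- numeric(3)
  for (p in 1:3) {
    g <- .gammaShapeRate(.phaseMeans(params)[p], .phaseCvs(params)[p])
    sh[p] <- g$shape; ra[p] <- g$rate
  }
  tab <- .buildRateTables(drugs, schedule, nGen, times)
  gr <- growthRate(params, dt)

  # sample the balanced-growth (phase, age) law; duration conditional on
  # survival to the sampled age
  wPhase <- integer(0); wAge <- numeric(0); wProb <- numeric(0)
  for (p in 1:3) {
    d <- gr$dists[[p]]
    i <- 0:(d$nBins - 1L)
    wPhase <- c(wPhase, rep.int(p, d$nBins))
    wAge <- c(wAge, i * dt)
    wProb <- c(wProb, gr$entryFlux[p] * gr$z^i * d$surv)
  }
  pick <- sample.int(length(wProb), nCells, replace = TRUE, prob = wProb)

  cap <- ceiling(nCells * 2^(grid@horizon / gr$doublingTime) * 1.4) + 1024L
  phase <- integer(cap); gen <- integer(cap)
  age <- numeric(cap); tau <- numeric(cap)
  isBlocked <- logical(cap); alive <- logical(cap)
  m <- nCells
  phase[1:m] <- wPhase[pick]
  gen[1:m] <- 1L
  age[1:m] <- wAge[pick]
  lo <- stats::pgamma(age[1:m], sh[phase[1:m]], ra[phase[1:m]])
  tau[1:m] <- stats::qgamma(stats::runif(m, lo, 1), sh[phase[1:m]],
                            ra[phase[1:m]])
  alive[1:m] <- TRUE
  deadTotal <- 0

  ensure <- function(k) {
    if (m + k <= length(phase)) return(invisible(NULL))
    grow <- max(k, length(phase))
    phase <<- c(phase, integer(grow)); gen <<- c(gen, integer(grow))
    age <<- c(age, numeric(grow)); tau <<- c(tau, numeric(grow))
    isBlocked <<- c(isBlocked, logical(grow)); alive <<- c(alive, logical(grow))
  }
  divide <- function(idx) {
    k <- length(idx)
    if (!k) return(invisible(NULL))
    gen[idx] <<- pmin(gen[idx] + 1L, nGen)
    phase[idx] <<- 1L
    age[idx] <<- 0
    tau[idx] <<- stats::rgamma(k, sh[1], ra[1])
    ensure(k)
    dst <- m + seq_len(k)
    phase[dst] <<- 1L; gen[dst] <<- gen[idx]
    age[dst] <<- 0; tau[dst] <<- stats::rgamma(k, sh[1], ra[1])
    isBlocked[dst] <<- FALSE; alive[dst] <<- TRUE
    m <<- m + k
  }
  advance <- function(idx) {
    # phase exit after a passed checkpoint; G2M exit is a division
    div <- idx[phase[idx] == 3L]
    mov <- idx[phase[idx] != 3L]
    if (length(mov)) {
      phase[mov] <<- phase[mov] + 1L
      age[mov] <<- 0
      tau[mov] <<- stats::rgamma(length(mov), sh[phase[mov]], ra[phase[mov]])
    }
    divide(div)
  }

  obsPct <- matrix(NA_real_, nSteps + 1L, 3L)
  obsGen <- matrix(0, nSteps + 1L, nGen)
  obsTot <- numeric(nSteps + 1L); obsDead <- numeric(nSteps + 1L)
  obsBlocked <- numeric(nSteps + 1L)
  record <- function(s) {
    liveIdx <- which(alive[1:m])
    obsTot[s] <<- length(liveIdx)
    obsDead[s] <<- deadTotal
    obsBlocked[s] <<- sum(isBlocked[liveIdx])
    obsGen[s, ] <<- tabulate(gen[liveIdx], nGen)
    ph <- tabulate(phase[liveIdx], 3L)
    if (length(liveIdx)) obsPct[s, ] <<- 100 * ph / length(liveIdx)
  }

  record(1L)
  for (s in seq_len(nSteps)) {
    liveIdx <- which(alive[1:m])
    if (!length(liveIdx)) { record(s + 1L); next }
    mu <- tab$death[cbind(phase[liveIdx], gen[liveIdx], s)]
    anyMu <- any(mu > 0)
    if (anyMu) {
      die <- stats::runif(length(liveIdx)) < -expm1(-mu * dt)
      if (any(die)) {
        alive[liveIdx[die]] <- FALSE
        deadTotal <- deadTotal + sum(die)
        liveIdx <- liveIdx[!die]
      }
    }
    wasBlocked <- isBlocked[liveIdx]
    blk <- liveIdx[wasBlocked]
    if (length(blk)) {
      rr <- tab$recycle[cbind(phase[blk], gen[blk], s)]
      rec <- blk[stats::runif(length(blk)) < -expm1(-rr * dt)]
      if (length(rec)) {
        isBlocked[rec] <- FALSE
        advance(rec)
      }
    }
    # cells recycled this step enter the downstream phase at age 0 and
    # begin aging next step, matching the engine's inflow timing
    trn <- liveIdx[!wasBlocked]
    if (length(trn)) {
      v <- tab$speed[cbind(phase[trn], gen[trn], s)]
      age[trn] <- age[trn] + v * dt
      cross <- trn[age[trn] >= tau[trn] - 1e-12]
      if (length(cross)) {
        pb <- tab$block[cbind(phase[cross], gen[cross], s)]
        arr <- stats::runif(length(cross)) < pb
        isBlocked[cross[arr]] <- TRUE
        advance(cross[!arr])
      }
    }
    record(s + 1L)
  }

  obs <- data.frame(time_h = times, pct_G1 = obsPct[, 1], pct_S = obsPct[, 2],
                    pct_G2M = obsPct[, 3], n_total = obsTot, n_dead = obsDead,
                    n_blocked = obsBlocked, check.names = FALSE)
  for (g in seq_len(nGen)) obs[[sprintf("n_gen%d", g - 1L)]] <- obsGen[, g]
  attr(obs, "seed") <- seed
  attr(obs, "nCells") <- nCells
  obs
}
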