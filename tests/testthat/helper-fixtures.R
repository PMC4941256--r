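# shared fixtures: small parameter sets and grids keep unit tests fast;
# heavier simulation studies live in test-acceptance.R

fastParams <- function(maxGen = 5L) {
  cellCycleParameters(9, 8, 5, 0.2, 0.15, 0.2, maxGeneration = maxGen)
}

coarseGrid <- function(horizon = 96, dt = 2) simulationGrid(dt = dt, horizon = horizon)

# all cells at age 0 of one phase, generation 0
pulseState <- function(params, phase = 1L, n0 = 1) {
  nGen <- params@maxGeneration + 1L
  den <- lapply(1:3, function(p) lapply(seq_len(nGen), function(g) numeric(0)))
  ag <- den
  den[[phase]][[1L]] <- n0
  ag[[phase]][[1L]] <- 0
  new("PopulationState", time = 0, density = den, ages = ag,
      blocked = matrix(0, 3, nGen), dead = matrix(0, 3, nGen))
}

# single-delay test drug
delayDrug <- function(magnitude = 0.5, phase = "S", gens = 0L,
                      window = "during") {
  drugModel("drugX", modules = list(
    perturbationModule("d1", "delay", phase, gens, magnitude,
                       window = window)))
}

atTime <- function(traj, t) {
  obs <- traj@observables
  obs[which.min(abs(obs$time_h - t)), , drop = FALSE]
}
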