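#' Construct an experiment design
#'
#' Observation times and replicate structure of the three measured data
#' streams: flow-cytometric phase percentages (FC), time-lapse live-cell
#' counts per generation (TL), and absolute cell counts.
#'
#' @param fcTimes,tlTimes,countTimes observation times, hours.
#' @param fcReplicates independent FC experiments (>= 1; default 3).
#' @param tlWells replicate TL culture wells (>= 1; default 5).
#' @param countReplicates replicate flasks for absolute counts (default 3).
#' @export
experimentDesign <- function(fcTimes = seq(0, 96, by = 24),
                             tlTimes = seq(0, 96, by = 6),
                             countTimes = seq(0, 96, by = 24),
                             fcReplicates = 3L, tlWells = 5L,
                             countReplicates = 3L) {
  new("ExperimentDesign", fcTimes = fcTimes, tlTimes = tlTimes,
      countTimes = countTimes, fcReplicates = as.integer(fcReplicates),
      tlWells = as.integer(tlWells),
      countReplicates = as.integer(countReplicates))
}

.phaseSums <- function(state) {
  vapply(1:3, function(p)
    sum(unlist(state@density[[p]], use.names = FALSE)) +
      sum(state@blocked[p, ]), numeric(1))
}

#' @describeIn fcPercentages percentages of one state; raises on an empty
#'   population.
#' @export
setMethod("fcPercentages", "PopulationState", function(object) {
  tot <- .phaseSums(object)
  live <- sum(tot)
  if (live <= 0) stop("flow-cytometric percentages are undefined: no live cells")
  stats::setNames(100 * tot / live, .PHASES)
})

#' @describeIn fcPercentages time course of percentages.
#' @export
setMethod("fcPercentages", "PopulationTrajectory", function(object) {
  object@observables[, c("time_h", "pct_G1", "pct_S", "pct_G2M")]
})

#' @describeIn tlGenerationCounts live cells per generation of one state
#'   (in transit plus blocked; dead excluded).
#' @export
setMethod("tlGenerationCounts", "PopulationState", function(object) {
  nGen <- ncol(object@blocked)
  cnt <- vapply(seq_len(nGen), function(g)
    sum(unlist(lapply(1:3, function(p) object@density[[p]][[g]]),
               use.names = FALSE)) + sum(object@blocked[, g]), numeric(1))
  stats::setNames(cnt, sprintf("gen%d", seq_len(nGen) - 1L))
})

#' @describeIn tlGenerationCounts time course of per-generation counts.
#' @export
setMethod("tlGenerationCounts", "PopulationTrajectory", function(object) {
  cols <- grep("^n_gen", names(object@observables), value = TRUE)
  object@observables[, c("time_h", cols)]
})

#' @describeIn totalCellNumber live cells of one state.
#' @export
setMethod("totalCellNumber", "PopulationState", function(object) {
  sum(.phaseSums(object))
})

#' @describeIn totalCellNumber time course of total live cells.
#' @export
setMethod("totalCellNumber", "PopulationTrajectory", function(object) {
  object@observables[, c("time_h", "n_total")]
})

#' Tidy long-format view of simulated observables
#'
#' Shared CSV schema of the simulation, synthetic-data and fitting layers:
#' columns time_h, stream ("fc", "tl", "count"), variable, generation
#' (NA except for TL), replicate (NA for noiseless series) and value.
#'
#' @param observables the wide observables data.frame of a
#'   \code{PopulationTrajectory} (slot \code{observables}), or the
#'   trajectory itself.
#' @param design optional \code{ExperimentDesign}; when given, only the
#'   design's observation times are emitted per stream.
#' @return a tidy data.frame.
#' @export
tidyObservables <- function(observables, design = NULL) {
  if (is(observables, "PopulationTrajectory"))
    observables <- observables@observables
  obs <- observables
  pick <- function(tms) {
    if (is.null(tms)) obs
    else obs[obs$time_h %in% tms, , drop = FALSE]
  }
  row <- function(times, stream, variable, generation, value) {
    k <- length(times)
    data.frame(time_h = times, stream = rep(stream, k),
               variable = rep(variable, k),
               generation = rep(generation, k),
               replicate = rep(NA_integer_, k), value = value)
  }
  out <- list()
  fc <- pick(if (is.null(design)) NULL else design@fcTimes)
  for (v in c("pct_G1", "pct_S", "pct_G2M"))
    out[[v]] <- row(fc$time_h, "fc", v, NA_integer_, fc[[v]])
  tl <- pick(if (is.null(design)) NULL else design@tlTimes)
  for (col in grep("^n_gen", names(obs), value = TRUE)) {
    g <- as.integer(sub("n_gen", "", col))
    out[[col]] <- row(tl$time_h, "tl", "n", g, tl[[col]])
  }
  ct <- pick(if (is.null(design)) NULL else design@countTimes)
  out[["n_total"]] <- row(ct$time_h, "count", "n_total", NA_integer_,
                          ct$n_total)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
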