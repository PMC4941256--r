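#' @import methods
NULL

.PHASES <- c("G1", "S", "G2M")
.EFFECTS <- c("delay", "block", "death", "recycle", "synthesis_inhibition")
.WINDOWS <- c("during", "post", "all")
.PROFILE_KINDS <- c("constant", "step_window", "sigmoid", "recovery")

#' Unperturbed cell-cycle parameters
#'
#' Phase transit times are gamma distributed, parameterized by mean duration
#' (hours) and coefficient of variation per phase. Generations beyond
#' \code{maxGeneration} are lumped into a self-renewing compartment.
#'
#' @slot meanG1,meanS,meanG2M mean phase durations in hours.
#' @slot cvG1,cvS,cvG2M coefficients of variation, in (0, 1].
#' @slot maxGeneration highest explicitly tracked division generation (>= 2).
#' @export
setClass("CellCycleParameters",
  representation(
    meanG1 = "numeric", meanS = "numeric", meanG2M = "numeric",
    cvG1 = "numeric", cvS = "numeric", cvG2M = "numeric",
    maxGeneration = "integer"
  )
)

setValidity("CellCycleParameters", function(object) {
  msgs <- character()
  means <- c(object@meanG1, object@meanS, object@meanG2M)
  cvs <- c(object@cvG1, object@cvS, object@cvG2M)
  if (any(!is.finite(means)) || any(means <= 0))
    msgs <- c(msgs, "mean phase durations must be positive and finite")
  if (any(!is.finite(cvs)) || any(cvs <= 0) || any(cvs > 1))
    msgs <- c(msgs, "coefficients of variation must lie in (0, 1]")
  if (length(object@maxGeneration) != 1L || object@maxGeneration < 2L)
    msgs <- c(msgs, "maxGeneration must be a single integer >= 2")
  if (length(msgs)) msgs else TRUE
})

#' Time-activation profile of a perturbation module
#'
#' Profiles take values in [0, 1] as a function of time measured from the
#' module's clock origin (treatment start for \code{during}/\code{all}
#' modules, washout for \code{post} modules). Kinds:
#' \describe{
#'   \item{constant}{1 from \code{onset} onward.}
#'   \item{step_window}{1 on [\code{onset}, \code{offset}), else 0.}
#'   \item{sigmoid}{logistic rise, value 1/2 at \code{halfMax}; the default
#'     steepness makes the rise from 10\% to 90\% take 6 h.}
#'   \item{recovery}{logistic decline from 1 toward \code{floor}, value
#'     (1 + floor)/2 at \code{halfMax}; models gradual release of
#'     DNA-synthesis inhibition with a possible residual plateau.}
#' }
#' @export
setClass("TimeProfile",
  representation(
    kind = "character", onset = "numeric", offset = "numeric",
    halfMax = "numeric", steepness = "numeric", floor = "numeric"
  ),
  prototype(kind = "constant", onset = 0, offset = Inf,
            halfMax = 0, steepness = 1.366, floor = 0)
)

setValidity("TimeProfile", function(object) {
  msgs <- character()
  if (!(object@kind %in% .PROFILE_KINDS))
    msgs <- c(msgs, sprintf("kind must be one of %s",
                            paste(.PROFILE_KINDS, collapse = ", ")))
  if (object@kind == "step_window" && object@offset <= object@onset)
    msgs <- c(msgs, "step_window requires offset > onset")
  if (object@steepness <= 0) msgs <- c(msgs, "steepness must be positive")
  if (object@floor < 0 || object@floor > 1)
    msgs <- c(msgs, "floor must lie in [0, 1]")
  if (length(msgs)) msgs else TRUE
})

#' One drug effect on cell-cycle progression
#'
#' @slot label identifier used to address the module from parameter specs.
#' @slot effect one of delay, block, death, recycle, synthesis_inhibition.
#' @slot phase target phase ("G1", "S", "G2M"); for block, the checkpoint at
#'   that phase's exit; for recycle, the blocked pool it drains.
#' @slot generations integer generation indices (0-based); empty = all.
#' @slot magnitude probability/fraction in [0, 1] for delay, block and
#'   synthesis_inhibition; per-hour rate (>= 0) for death and recycle.
#' @slot profile a \code{TimeProfile}.
#' @slot window "during" (active while the drug is applied), "post" (after
#'   washout) or "all" (from drug start onward).
#' @slot activeUntil absolute time after which the module is forced off
#'   (used when a later drug supersedes it); default Inf.
#' @export
setClass("PerturbationModule",
  representation(
    label = "character", effect = "character", phase = "character",
    generations = "integer", magnitude = "numeric",
    profile = "TimeProfile", window = "character", activeUntil = "numeric"
  ),
  prototype(window = "during", activeUntil = Inf, generations = integer())
)

setValidity("PerturbationModule", function(object) {
  msgs <- character()
  if (!(object@effect %in% .EFFECTS))
    msgs <- c(msgs, sprintf("effect must be one of %s",
                            paste(.EFFECTS, collapse = ", ")))
  if (!(object@phase %in% .PHASES))
    msgs <- c(msgs, "phase must be G1, S or G2M")
  if (!(object@window %in% .WINDOWS))
    msgs <- c(msgs, "window must be during, post or all")
  m <- object@magnitude
  if (length(m) != 1L || !is.finite(m)) {
    msgs <- c(msgs, "magnitude must be a single finite number")
  } else if (object@effect %in% c("delay", "block", "synthesis_inhibition")) {
    if (m < 0 || m > 1)
      msgs <- c(msgs, sprintf("%s magnitude must lie in [0, 1]", object@effect))
  } else if (m < 0) {
    msgs <- c(msgs, sprintf("%s magnitude (a rate) must be >= 0", object@effect))
  }
  if (any(object@generations < 0))
    msgs <- c(msgs, "generation indices must be >= 0")
  if (length(msgs)) msgs else TRUE
})

#' A drug model: named, concentration-labelled set of perturbation modules
#'
#' Concentration is a label selecting a parameter set, not a dynamic
#' quantity (no pharmacokinetics).
#' @export
setClass("DrugModel",
  representation(name = "character", concentration = "character",
                 modules = "list")
)

setValidity("DrugModel", function(object) {
  msgs <- character()
  ok <- vapply(object@modules, is, logical(1), class2 = "PerturbationModule")
  if (!all(ok)) msgs <- c(msgs, "modules must all be PerturbationModule objects")
  if (all(ok) && length(object@modules)) {
    labs <- vapply(object@modules, slot, character(1), name = "label")
    if (anyDuplicated(labs))
      msgs <- c(msgs, "module labels must be unique within a drug model")
    key <- vapply(object@modules, function(m) {
      if (m@effect != "block") return(NA_character_)
      paste(m@phase, paste(sort(m@generations), collapse = ","), m@window)
    }, character(1))
    if (anyDuplicated(stats::na.omit(key)))
      msgs <- c(msgs, "at most one block module per (phase, generations, window)")
  }
  if (length(msgs)) msgs else TRUE
})

#' Treatment schedule: per-drug exposure intervals
#'
#' @slot intervals data.frame with columns drug, start, end (hours).
#' @export
setClass("TreatmentSchedule", representation(intervals = "data.frame"))

setValidity("TreatmentSchedule", function(object) {
  iv <- object@intervals
  msgs <- character()
  if (!all(c("drug", "start", "end") %in% names(iv)))
    msgs <- c(msgs, "intervals needs columns drug, start, end")
  else {
    if (any(iv$end <= iv$start)) msgs <- c(msgs, "interval end must exceed start")
    for (d in unique(iv$drug)) {
      sub <- iv[iv$drug == d, , drop = FALSE]
      sub <- sub[order(sub$start), , drop = FALSE]
      if (nrow(sub) > 1 && any(sub$start[-1] < sub$end[-nrow(sub)]))
        msgs <- c(msgs, sprintf("overlapping intervals for drug '%s'", d))
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' Simulation grid
#'
#' The transport scheme uses an age bin equal to the time step, so cohorts
#' advance exactly one bin per step under unit aging speed.
#' @slot dt time step and age-bin width, hours.
#' @slot horizon simulated duration, hours.
#' @export
setClass("SimulationGrid", representation(dt = "numeric", horizon = "numeric"),
         prototype(dt = 0.5, horizon = 96))

setValidity("SimulationGrid", function(object) {
  if (object@dt <= 0 || object@horizon <= 0) return("dt and horizon must be positive")
  if (object@horizon < object@dt) return("horizon must be at least one step")
  TRUE
})

#' Age-binned population state
#'
#' Live cell densities per (phase, generation, age bin), blocked pools per
#' (phase, generation), and cumulative dead cells.
#'
#' @slot time hours.
#' @slot density list indexed [[phase]][[generation]] of per-age-bin counts.
#' @slot ages matching list of bin ages (hours since phase entry).
#' @slot blocked 3 x nGenerations matrix of arrested cells.
#' @slot dead 3 x nGenerations matrix of cumulative dead cells.
#' @export
setClass("PopulationState",
  representation(time = "numeric", density = "list", ages = "list",
                 blocked = "matrix", dead = "matrix")
)

setValidity("PopulationState", function(object) {
  msgs <- character()
  if (length(object@density) != 3L || length(object@ages) != 3L)
    msgs <- c(msgs, "density and ages must have one entry per phase")
  neg <- any(unlist(object@density, use.names = FALSE) < 0) ||
    any(object@blocked < 0) || any(object@dead < 0)
  if (isTRUE(neg)) msgs <- c(msgs, "cell counts must be non-negative")
  if (length(msgs)) msgs else TRUE
})

#' Simulated population trajectory
#'
#' @slot times step times, hours.
#' @slot observables wide data.frame: time_h, pct_G1, pct_S, pct_G2M,
#'   n_total, n_dead and one n_gen<g> column per generation.
#' @slot states named list of PopulationState snapshots (requested times and
#'   the final state).
#' @slot doublingTime unperturbed doubling time of the initial condition, h.
#' @export
setClass("PopulationTrajectory",
  representation(times = "numeric", observables = "data.frame",
                 states = "list", params = "CellCycleParameters",
                 grid = "SimulationGrid", doublingTime = "numeric")
)

#' Experiment design: observation times and replicate structure
#' @export
setClass("ExperimentDesign",
  representation(fcTimes = "numeric", tlTimes = "numeric",
                 countTimes = "numeric", fcReplicates = "integer",
                 tlWells = "integer", countReplicates = "integer")
)

setValidity("ExperimentDesign", function(object) {
  if (object@fcReplicates < 1L || object@tlWells < 1L || object@countReplicates < 1L)
    return("replicate counts must be >= 1")
  TRUE
})

#' Replicate-noise model for synthetic datasets
#'
#' @slot fcSd additive SD on phase percentages, points.
#' @slot tlCv,countCv,srbCv multiplicative (lognormal) CVs.
#' @export
setClass("NoiseModel",
  representation(fcSd = "numeric", tlCv = "numeric", countCv = "numeric",
                 srbCv = "numeric"),
  prototype(fcSd = 2.5, tlCv = 0.08, countCv = 0.05, srbCv = 0.07)
)

setValidity("NoiseModel", function(object) {
  if (any(c(object@fcSd, object@tlCv, object@countCv, object@srbCv) < 0))
    return("noise dispersions must be >= 0")
  TRUE
})

#' Free/fixed parameter declaration for fitting
#'
#' A spec addresses one scalar estimand: a field shared by one or more
#' modules (addressed by label) of one drug model. Multiple labels make the
#' parameter shared across those modules (e.g. a recycling rate set equal in
#' generations 0 and 1).
#' @export
setClass("ParameterSpec",
  representation(name = "character", drug = "character", labels = "character",
                 field = "character", lower = "numeric", upper = "numeric",
                 free = "logical"),
  prototype(field = "magnitude", free = TRUE)
)

setValidity("ParameterSpec", function(object) {
  msgs <- character()
  if (!(object@field %in% c("magnitude", "halfMax", "onset", "offset")))
    msgs <- c(msgs, "field must be magnitude, halfMax, onset or offset")
  if (!is.finite(object@lower) || !is.finite(object@upper) ||
      object@upper <= object@lower)
    msgs <- c(msgs, "bounds must be finite with upper > lower")
  if (length(msgs)) msgs else TRUE
})

#' Result of a model fit
#'
#' @slot estimates named numeric vector of fitted parameter values.
#' @slot objective minimized weighted sum of squared residuals.
#' @slot intervals matrix with columns lower, upper (filled by
#'   \code{\link{uncertaintyIntervals}}; NA until then).
#' @export
setClass("FitResult",
  representation(estimates = "numeric", objective = "numeric",
                 intervals = "matrix", nObs = "integer", nFree = "integer",
                 converged = "logical", details = "list")
)

setValidity("FitResult", function(object) {
  if (length(object@objective) != 1L || object@objective < 0)
    return("objective must be a single non-negative number")
  TRUE
})
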