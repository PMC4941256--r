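#' Construct a perturbation module
#'
#' The drug-effect grammar: a module targets one effect in one phase for a
#' set of generations, with a magnitude and a time-activation profile.
#' Delay and synthesis_inhibition magnitudes are fractional slow-downs of
#' phase transit speed (an S-phase delay is equivalent to the same
#' fractional reduction of the DNA synthesis rate); block magnitudes are
#' per-cohort arrest probabilities at the phase-exit checkpoint; death and
#' recycle magnitudes are first-order per-hour rates.
#'
#' @param label unique identifier within a drug model.
#' @param effect "delay", "block", "death", "recycle" or
#'   "synthesis_inhibition".
#' @param phase "G1", "S" or "G2M".
#' @param generations integer vector of generation indices (0 = undivided);
#'   the string "0/1" is accepted as shorthand; NULL means all generations.
#' @param magnitude probability in [0, 1] or rate per hour (see above).
#' @param profile a \code{TimeProfile} (default: constant 1).
#' @param window "during", "post" or "all" relative to the drug's exposure
#'   interval.
#' @return a \code{\linkS4class{PerturbationModule}}.
#' @export
perturbationModule <- function(label, effect, phase, generations = NULL,
                               magnitude = 0, profile = timeProfile(),
                               window = "during") {
  if (is.character(generations))
    generations <- as.integer(unlist(strsplit(generations, "/", fixed = TRUE)))
  if (is.null(generations)) generations <- integer()
  new("PerturbationModule", label = label, effect = effect, phase = phase,
      generations = as.integer(generations), magnitude = magnitude,
      profile = profile, window = window, activeUntil = Inf)
}

#' Construct a drug model
#' @param name drug name used to match schedule intervals.
#' @param concentration concentration label (e.g. "1 uM"); informational.
#' @param modules list of \code{PerturbationModule} objects.
#' @export
drugModel <- function(name, concentration = "", modules = list()) {
  new("DrugModel", name = name, concentration = concentration,
      modules = modules)
}

#' @describeIn modules modules of a DrugModel
#' @export
setMethod("modules", "DrugModel", function(object) object@modules)

#' Replace one module field in a drug model
#'
#' @param drug a \code{DrugModel}.
#' @param labels labels of the modules to modify.
#' @param field "magnitude" or a \code{TimeProfile} time field ("halfMax",
#'   "onset", "offset").
#' @param value new value, applied to every addressed module.
#' @export
setModuleField <- function(drug, labels, field, value) {
  hit <- FALSE
  drug@modules <- lapply(drug@modules, function(m) {
    if (!(m@label %in% labels)) return(m)
    hit <<- TRUE
    if (field == "magnitude") m@magnitude <- value
    else slot(m@profile, field) <- value
    m
  })
  if (!hit) stop("no module with label(s) ", paste(labels, collapse = ", "),
                 " in drug '", drug@name, "'")
  validObject(drug)
  drug
}

#' Effective phase-exit hazard under active delay modules
#'
#' Active delays compose multiplicatively on transit speed: the hazard (and
#' the aging speed) is scaled by \eqn{\prod_i (1 - d_i\,\pi_i(t))} over the
#' active delay/synthesis-inhibition modules, where \eqn{\pi_i} is the
#' module's profile value. A magnitude of 1 gives full arrest.
#'
#' @param baseHazard per-hour exit hazard without perturbation.
#' @param delays numeric vector of effective delay values
#'   \eqn{d_i \pi_i(t)} of the active modules (each in [0, 1]).
#' @return the scaled hazard.
#' @export
effectiveExitHazard <- function(baseHazard, delays = numeric()) {
  stopifnot(all(baseHazard >= 0))
  baseHazard * prod(1 - delays)
}

#' Split an arriving cohort at a checkpoint
#'
#' The fraction of the cohort given by the block probability is arrested
#' into the blocked pool; the remainder passes to the next phase. The split
#' conserves flux exactly.
#'
#' @param arrivingFlux cells/h reaching the checkpoint.
#' @param blockProb effective block probability \eqn{p\,\pi(t)} in [0, 1].
#' @return list with \code{passing} and \code{blocked} fluxes.
#' @export
applyCheckpointBlock <- function(arrivingFlux, blockProb) {
  stopifnot(arrivingFlux >= 0, blockProb >= 0, blockProb <= 1)
  blocked <- blockProb * arrivingFlux
  list(passing = arrivingFlux - blocked, blocked = blocked)
}

#' First-order outflow from a blocked pool
#'
#' Blocked cells re-enter the cycle at rate \eqn{r\,\pi(t)} per hour,
#' resuming at age 0 of the phase downstream of the checkpoint where they
#' were arrested (G1-blocked cells enter S; G2M-blocked cells divide).
#'
#' @param blockedPool cells currently arrested.
#' @param rate effective recycling rate \eqn{r\,\pi(t)}, per hour.
#' @return instantaneous outflow, cells/h.
#' @export
recycleFlux <- function(blockedPool, rate) {
  stopifnot(blockedPool >= 0, rate >= 0)
  rate * blockedPool
}

#' Instantaneous death removal from a compartment
#'
#' @param compartment live cells in the targeted compartment.
#' @param rate effective death rate \eqn{\mu\,\pi(t)}, per hour; commitment
#'   windows (e.g. death only after 48 h for undivided cells) are expressed
#'   through the module's step-window profile.
#' @return removal flux, cells/h.
#' @export
applyDeath <- function(compartment, rate) {
  stopifnot(compartment >= 0, rate >= 0)
  rate * compartment
}

setMethod("show", "PerturbationModule", function(object) {
  gens <- if (length(object@generations))
    paste(object@generations, collapse = ",") else "all"
  cat(sprintf("PerturbationModule '%s': %s %s gen{%s} magnitude %g [%s, %s]\n",
              object@label, object@effect, object@phase, gens,
              object@magnitude, object@window, object@profile@kind))
})

setMethod("show", "DrugModel", function(object) {
  cat(sprintf("DrugModel '%s' (%s), %d modules\n", object@name,
              object@concentration, length(object@modules)))
  for (m in object@modules) show(m)
})
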