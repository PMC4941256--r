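#' Flow-cytometric phase percentages of a state
#'
#' Percentages of live cells (in transit plus blocked, all generations
#' pooled) in G1, S and G2M. Blocked cells count in their phase of arrest;
#' dead cells are excluded.
#' @param object a \code{PopulationState} or \code{PopulationTrajectory}.
#' @return named numeric of length 3 (state) or a data.frame over time
#'   (trajectory).
#' @export
setGeneric("fcPercentages", function(object) standardGeneric("fcPercentages"))

#' Live cells per division generation (time-lapse observable)
#' @param object a \code{PopulationState} or \code{PopulationTrajectory}.
#' @export
setGeneric("tlGenerationCounts",
           function(object) standardGeneric("tlGenerationCounts"))

#' Total live cell number
#' @param object a \code{PopulationState} or \code{PopulationTrajectory}.
#' @export
setGeneric("totalCellNumber",
           function(object) standardGeneric("totalCellNumber"))

#' Perturbation modules of a drug model
#' @param object a \code{DrugModel}.
#' @export
setGeneric("modules", function(object) standardGeneric("modules"))

#' Parameter estimates of a fit
#' @param object a \code{FitResult}.
#' @export
setGeneric("estimates", function(object) standardGeneric("estimates"))

#' Uncertainty intervals of a fit
#' @param object a \code{FitResult}.
#' @export
setGeneric("intervals", function(object) standardGeneric("intervals"))
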