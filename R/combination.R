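#' Simulate a sequential two-drug treatment
#'
#' Runs a single continuous simulation in which the first drug's model acts
#' until the second drug is applied; the full population state (age-binned
#' densities, blocked pools, generation structure) carries across the
#' switch exactly. By default (policy "supersede") the first drug's
#' post-treatment modules that target the same (effect, phase, generation)
#' as some module of the second drug are switched off at the second drug's
#' start, and all others persist; policy "error" raises on such overlaps,
#' policy "compose" lets them act together (delays multiply).
#'
#' @inheritParams simulatePopulation
#' @param drugA,drugB \code{DrugModel}s for the first and second treatment.
#' @param schedule \code{TreatmentSchedule} containing intervals for both
#'   drug names (e.g. gemcitabine 0-6 h, erlotinib 24-72 h).
#' @param policy overlap policy, see above.
#' @return a \code{\linkS4class{PopulationTrajectory}}.
#' @export
simulateSequential <- function(params, drugA, drugB, schedule,
                               grid = simulationGrid(), init = NULL,
                               n0 = 1000, keepTimes = numeric(),
                               policy = c("supersede", "error", "compose")) {
  policy <- match.arg(policy)
  iv <- schedule@intervals
  ivB <- iv[iv$drug == drugB@name, , drop = FALSE]
  switchTime <- if (nrow(ivB)) min(ivB$start) else Inf
  if (length(drugB@modules) && !nrow(ivB))
    stop("schedule has no interval for the second drug '", drugB@name, "'")
  overlapKey <- function(m) paste(m@effect, m@phase,
                                  paste(sort(m@generations), collapse = ","))
  keysB <- vapply(drugB@modules, overlapKey, character(1))
  clash <- vapply(drugA@modules, function(m) overlapKey(m) %in% keysB,
                  logical(1))
  if (any(clash)) {
    if (policy == "error")
      stop("drug models have overlapping modules for the same ",
           "(effect, phase, generations); choose a policy to resolve")
    if (policy == "supersede")
      drugA@modules <- lapply(drugA@modules, function(m) {
        if (overlapKey(m) %in% keysB) m@activeUntil <- switchTime
        m
      })
  }
  simulatePopulation(params, list(drugA, drugB), schedule, grid, init, n0,
                     keepTimes)
}

#' Expected combination outcome in the absence of drug interaction
#'
#' Wraps \code{\link{simulateSequential}} with the unmodified single-drug
#' models and returns the observables used to compare prediction and
#' combination data: phase percentages at the comparison times and the
#' relative cell-number increase between them.
#'
#' @inheritParams simulateSequential
#' @param compareTimes two times (h), by default the end of the second
#'   treatment window available on the grid and 24 h later (72 and 96 h).
#' @return list with \code{trajectory}, \code{fc} (percentages at the
#'   comparison times) and \code{countIncrease} (ratio of total cells
#'   between the two times).
#' @export
noInteractionPrediction <- function(params, drugA, drugB, schedule,
                                    grid = simulationGrid(), n0 = 1000,
                                    compareTimes = c(72, 96)) {
  tr <- simulateSequential(params, drugA, drugB, schedule, grid, n0 = n0)
  obs <- tr@observables
  idx <- vapply(compareTimes, function(t) which.min(abs(obs$time_h - t)),
                integer(1))
  fc <- obs[idx, c("time_h", "pct_G1", "pct_S", "pct_G2M")]
  rownames(fc) <- NULL
  list(trajectory = tr, fc = fc,
       countIncrease = obs$n_total[idx[2]] / obs$n_total[idx[1]])
}

#' Refit selected parameters against combination data
#'
#' Frees the named parameters (normally parameters of the second drug's
#' model, optionally the first drug's post-treatment modules) and refits
#' them against combination time courses, keeping everything else at the
#' single-treatment values. The delta report compares each freed parameter
#' with its single-drug reference: it is flagged "changed" when the
#' combination interval and the reference interval are disjoint.
#'
#' @param dataset tidy combination dataset.
#' @inheritParams simulateSequential
#' @param specs non-empty list of \code{\link{parameterSpec}}s naming the
#'   freed parameters.
#' @param reference data.frame with columns parameter, value, lower, upper:
#'   the single-drug estimates and their uncertainty intervals.
#' @param nBoot bootstrap replicates for the combination intervals (0
#'   disables interval estimation; parameters are then flagged only if the
#'   point estimate leaves the reference interval).
#' @param ... passed to \code{\link{fitModel}}.
#' @return list with \code{fit} (a \code{FitResult}) and \code{delta} (the
#'   report data.frame).
#' @export
refitInteraction <- function(dataset, params, drugA, drugB, schedule,
                             specs, reference, grid = simulationGrid(),
                             n0 = 1000, policy = "supersede", nBoot = 0L,
                             seed = 1, ...) {
  if (!length(specs)) stop("specs must name at least one freed parameter")
  drugsEff <- .resolveSequential(drugA, drugB, schedule, policy)
  fit <- fitModel(dataset, params, drugsEff, schedule, specs, grid, n0,
                  seed = seed, ...)
  if (nBoot > 0)
    fit <- uncertaintyIntervals(fit, dataset, params, drugsEff, schedule,
                                grid, n0, nBoot = nBoot, seed = seed)
  est <- fit@estimates
  delta <- do.call(rbind, lapply(names(est), function(nm) {
    ref <- reference[reference$parameter == nm, , drop = FALSE]
    if (!nrow(ref))
      ref <- data.frame(value = NA_real_, lower = -Inf, upper = Inf)
    cl <- fit@intervals[nm, "lower"]
    cu <- fit@intervals[nm, "upper"]
    if (!is.finite(cl)) cl <- est[[nm]]
    if (!is.finite(cu)) cu <- est[[nm]]
    data.frame(parameter = nm, single = ref$value[1],
               singleLower = ref$lower[1], singleUpper = ref$upper[1],
               combination = est[[nm]], comboLower = cl, comboUpper = cu,
               changed = (cu < ref$lower[1]) | (cl > ref$upper[1]))
  }))
  rownames(delta) <- NULL
  list(fit = fit, delta = delta)
}

# apply the supersession policy and return the effective two-model list
.resolveSequential <- function(drugA, drugB, schedule, policy = "supersede") {
  iv <- schedule@intervals
  ivB <- iv[iv$drug == drugB@name, , drop = FALSE]
  switchTime <- if (nrow(ivB)) min(ivB$start) else Inf
  overlapKey <- function(m) paste(m@effect, m@phase,
                                  paste(sort(m@generations), collapse = ","))
  keysB <- vapply(drugB@modules, overlapKey, character(1))
  if (policy == "supersede")
    drugA@modules <- lapply(drugA@modules, function(m) {
      if (overlapKey(m) %in% keysB) m@activeUntil <- switchTime
      m
    })
  list(drugA, drugB)
}
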