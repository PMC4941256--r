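#' Declare a fitting parameter
#'
#' @param name parameter name reported in fit results.
#' @param drug name of the \code{DrugModel} the parameter lives in.
#' @param labels labels of the module(s) sharing this parameter (several
#'   labels tie the value across modules, e.g. a recycling rate set equal
#'   in generations 0 and 1).
#' @param field "magnitude" (default) or a profile time field ("halfMax",
#'   "onset", "offset"). Time fields are optimized on a 3 h grid.
#' @param lower,upper finite box bounds respecting the field's semantics
#'   (probabilities in [0, 1], rates >= 0).
#' @param free logical; fixed parameters keep the model's current value.
#' @export
parameterSpec <- function(name, drug, labels, field = "magnitude",
                          lower = 0, upper = 1, free = TRUE) {
  new("ParameterSpec", name = name, drug = drug, labels = labels,
      field = field, lower = lower, upper = upper, free = free)
}

.TIME_GRID_H <- 3

#' Summarize a tidy dataset into per-observation means and errors
#'
#' FC percentages are summarized on their natural scale; TL and count
#' streams on log(count + 1), so the objective is invariant to a
#' unit-preserving rescaling of counts. Standard errors are the replicate
#' SD over sqrt(replicates); missing or zero SDs fall back to the pooled
#' per-stream SD.
#'
#' @param dataset tidy data.frame (time_h, stream, variable, generation,
#'   replicate, value).
#' @param weighting "replicate" (default) weights every observation by its
#'   own replicate SD; "pooled" uses the root-mean-square SD of the stream
#'   for every observation. Pooled weights make the standardized residuals
#'   homoscedastic Gaussian within a stream (counts are on the log scale,
#'   where the multiplicative noise is homoscedastic), which is what the
#'   nested-model F test assumes; per-observation weights estimated from
#'   few replicates are noisy and inflate the test's size.
#' @param minCount detection floor, cells: TL/count observations whose
#'   replicate-mean count falls below it are dropped (a time-lapse field
#'   cannot score a generation that holds no cells; near-empty
#'   observations carry almost no noise on the log scale yet would count
#'   toward the residual degrees of freedom).
#' @return data.frame with columns stream, time_h, variable, generation,
#'   mean, sem, n.
#' @export
summarizeDataset <- function(dataset, weighting = c("replicate", "pooled"),
                             minCount = 0) {
  weighting <- match.arg(weighting)
  ds <- dataset
  ds$value <- ifelse(ds$stream == "fc", ds$value, log(ds$value + 1))
  key <- interaction(ds$stream, ds$time_h, ds$variable,
                     ifelse(is.na(ds$generation), -1L, ds$generation),
                     drop = TRUE)
  agg <- function(f) tapply(ds$value, key, f)
  first <- !duplicated(key)
  out <- data.frame(stream = ds$stream[first], time_h = ds$time_h[first],
                    variable = ds$variable[first],
                    generation = ds$generation[first],
                    mean = as.numeric(agg(mean)[as.character(key[first])]),
                    sd = as.numeric(agg(stats::sd)[as.character(key[first])]),
                    n = as.numeric(agg(length)[as.character(key[first])]))
  for (s in unique(out$stream)) {
    i <- out$stream == s
    ok <- i & is.finite(out$sd) & out$sd > 0
    pooled <- if (any(ok)) sqrt(mean(out$sd[ok]^2))
      else if (s == "fc") 1 else 0.1
    if (weighting == "pooled") out$sd[i] <- pooled
    else out$sd[i & !ok] <- pooled
  }
  out$sem <- out$sd / sqrt(out$n)
  if (minCount > 0)
    out <- out[out$stream == "fc" | expm1(out$mean) >= minCount, ,
               drop = FALSE]
  out <- out[order(out$stream, out$time_h, out$variable, out$generation,
                   na.last = TRUE), ]
  rownames(out) <- NULL
  out
}

# model predictions matched to the rows of a dataset summary
.simPredictions <- function(summary, params, drugs, schedule, grid, n0) {
  tr <- simulatePopulation(params, drugs, schedule, grid, n0 = n0)
  obs <- tr@observables
  idx <- match(round(summary$time_h, 9), round(obs$time_h, 9))
  if (anyNA(idx))
    stop("observation times must lie on the simulation grid (dt = ",
         grid@dt, " h)")
  val <- numeric(nrow(summary))
  for (r in seq_len(nrow(summary))) {
    s <- summary$stream[r]
    val[r] <- if (s == "fc") {
      obs[[summary$variable[r]]][idx[r]]
    } else if (s == "tl") {
      log(obs[[sprintf("n_gen%d", summary$generation[r])]][idx[r]] + 1)
    } else {
      log(obs$n_total[idx[r]] + 1)
    }
  }
  val
}

#' Joint weighted least-squares objective
#'
#' Weighted sum of squared residuals over the FC, TL and count streams:
#' FC residuals in percentage points, TL/count residuals on log counts,
#' each divided by its replicate standard error (inverse-variance
#' weighting), so no stream dominates by units.
#'
#' @param dataset tidy dataset or a \code{\link{summarizeDataset}} result.
#' @inheritParams simulatePopulation
#' @inheritParams summarizeDataset
#' @return the scalar objective.
#' @export
objectiveValue <- function(dataset, params, drugs = list(), schedule = NULL,
                           grid = simulationGrid(), n0 = 1000,
                           weighting = "replicate", minCount = 0) {
  summary <- if (!is.null(dataset$sem)) dataset
    else summarizeDataset(dataset, weighting, minCount)
  pred <- .simPredictions(summary, params, drugs, schedule, grid, n0)
  sum(((pred - summary$mean) / summary$sem)^2)
}

# write spec values (natural scale) into the drug-model list
.applySpecs <- function(drugs, specs, values) {
  byName <- vapply(drugs, function(d) d@name, character(1))
  for (sp in specs) {
    if (!(sp@name %in% names(values))) next
    v <- values[[sp@name]]
    if (sp@field != "magnitude")
      v <- round(v / .TIME_GRID_H) * .TIME_GRID_H
    i <- match(sp@drug, byName)
    if (is.na(i)) stop("spec '", sp@name, "' names unknown drug '", sp@drug, "'")
    drugs[[i]] <- setModuleField(drugs[[i]], sp@labels, sp@field, v)
  }
  drugs
}

# current value of a spec'd parameter in the model list
.specValue <- function(drugs, sp) {
  byName <- vapply(drugs, function(d) d@name, character(1))
  d <- drugs[[match(sp@drug, byName)]]
  for (m in d@modules)
    if (m@label %in% sp@labels)
      return(if (sp@field == "magnitude") m@magnitude else slot(m@profile, sp@field))
  stop("spec '", sp@name, "' addresses no module")
}

.toUnit <- function(x, sp) pmin(pmax((x - sp@lower) / (sp@upper - sp@lower),
                                     1e-6), 1 - 1e-6)
.fromUnit <- function(u, sp) sp@lower + (sp@upper - sp@lower) * u

# modules influencing no observation time are unidentifiable: auto-fix
.guardIdentifiability <- function(specs, drugs, schedule, maxTime) {
  byName <- vapply(drugs, function(d) d@name, character(1))
  tt <- seq(0, maxTime, by = 0.5)
  keepFree <- vapply(specs, function(sp) {
    if (!sp@free) return(FALSE)
    d <- drugs[[match(sp@drug, byName)]]
    probe <- drugModel(d@name, modules = Filter(function(m)
      m@label %in% sp@labels, d@modules))
    for (m in probe@modules) if (m@magnitude == 0) probe <-
        setModuleField(probe, m@label, "magnitude", 1)
    schedOne <- if (is.null(schedule)) NULL else {
      iv <- schedule@intervals[schedule@intervals$drug == sp@drug, ,
                               drop = FALSE]
      if (nrow(iv)) treatmentSchedule(iv$drug, iv$start, iv$end) else NULL
    }
    tab <- .buildRateTables(list(probe), schedOne, 8L, tt)
    act <- max(1 - tab$speed, tab$block, tab$death, tab$recycle)
    if (act < 1e-8) {
      warning("parameter '", sp@name,
              "' is inactive over the observation window; fixing it",
              call. = FALSE)
      return(FALSE)
    }
    TRUE
  }, logical(1))
  for (i in seq_along(specs)) specs[[i]]@free <- keepFree[i]
  specs
}

#' Fit perturbation-module parameters to FC/TL/count time courses
#'
#' Multi-start bounded search: Latin-hypercube starts within the spec
#' bounds (plus the model's current values and any user-supplied starts),
#' the best \code{refineTop} of which are polished by Nelder-Mead on a
#' logit-transformed scale. Reproducible given \code{seed}.
#'
#' @param dataset tidy dataset (see \code{\link{generateDataset}}).
#' @inheritParams simulatePopulation
#' @param specs list of \code{\link{parameterSpec}} declarations.
#' @param nStarts Latin-hypercube starts (>= 1).
#' @param refineTop how many best starts receive full local refinement.
#' @param maxit Nelder-Mead iteration budget per refinement.
#' @param extraStarts optional list of named vectors used as additional
#'   starts (e.g. the estimate of a nested reduced model).
#' @param seed RNG seed for the start design.
#' @inheritParams summarizeDataset
#' @return a \code{\linkS4class{FitResult}}; with no free parameters, the
#'   evaluated objective is returned without any search.
#' @export
fitModel <- function(dataset, params, drugs, schedule = NULL, specs = list(),
                     grid = simulationGrid(), n0 = 1000, nStarts = 8L,
                     refineTop = 3L, maxit = 150L, extraStarts = NULL,
                     seed = 1, weighting = "replicate", minCount = 0) {
  summary <- summarizeDataset(dataset, weighting, minCount)
  if (length(unique(summary$time_h)) < 2)
    stop("dataset must cover at least two time points")
  specs <- .guardIdentifiability(specs, drugs, schedule, max(summary$time_h))
  free <- Filter(function(sp) sp@free, specs)
  nm <- vapply(free, function(sp) sp@name, character(1))
  k <- length(free)
  evalAt <- function(values) {
    objectiveValue(summary, params, .applySpecs(drugs, specs, values),
                   schedule, grid, n0)
  }
  if (k == 0L) {
    return(new("FitResult", estimates = numeric(0), objective = evalAt(list()),
               intervals = matrix(numeric(0), 0, 2), nObs = nrow(summary),
               nFree = 0L, converged = TRUE, details = list(specs = specs)))
  }
  if (k > nrow(summary))
    warning("more free parameters (", k, ") than observations (",
            nrow(summary), "); the fit is unidentifiable")

  toValues <- function(u) {
    v <- as.list(mapply(function(ui, sp) .fromUnit(ui, sp), u, free))
    names(v) <- nm
    v
  }
  objU <- function(uLogit) {
    u <- stats::plogis(uLogit)
    val <- tryCatch(evalAt(toValues(u)), error = function(e) Inf)
    if (!is.finite(val)) 1e12 else val
  }

  set.seed(seed)
  starts <- lhs::randomLHS(max(1L, nStarts), k)
  cur <- vapply(free, function(sp) .specValue(drugs, sp), numeric(1))
  starts <- rbind(starts, mapply(.toUnit, cur, free))
  if (!is.null(extraStarts))
    for (es in extraStarts)
      starts <- rbind(starts, mapply(function(n, sp)
        .toUnit(es[[n]], sp), nm, free))
  sObj <- apply(starts, 1, function(u) objU(stats::qlogis(u)))
  ord <- order(sObj)
  best <- list(value = Inf, par = stats::qlogis(starts[ord[1], ]))
  trace <- sObj[ord]
  for (i in ord[seq_len(min(refineTop, length(ord)))]) {
    p0 <- stats::qlogis(starts[i, ])
    opt <- if (k == 1L) {
      stats::optim(p0, objU, method = "Brent", lower = -12, upper = 12)
    } else {
      stats::optim(p0, objU, method = "Nelder-Mead",
                   control = list(maxit = maxit, reltol = 1e-10))
    }
    if (opt$value < best$value) best <- opt
  }
  if (!is.finite(best$value))
    stop("all starts failed; objective trace: ",
         paste(signif(trace, 4), collapse = ", "))
  est <- unlist(toValues(stats::plogis(best$par)))
  iv <- matrix(NA_real_, k, 2, dimnames = list(nm, c("lower", "upper")))
  new("FitResult", estimates = est, objective = best$value, intervals = iv,
      nObs = nrow(summary), nFree = as.integer(k), converged = TRUE,
      details = list(specs = specs, startObjectives = trace, seed = seed))
}

#' @describeIn estimates estimates of a FitResult
#' @export
setMethod("estimates", "FitResult", function(object) object@estimates)

#' @describeIn intervals interval matrix of a FitResult
#' @export
setMethod("intervals", "FitResult", function(object) object@intervals)

#' Residual-bootstrap uncertainty intervals
#'
#' Resamples standardized residuals within each data stream, rebuilds
#' perturbed observation means around the fitted predictions, refits
#' locally from the point estimate, and reports percentile (2.5-97.5)
#' intervals per free parameter. Reproducible given \code{seed}.
#'
#' @param fit a converged \code{FitResult} from \code{\link{fitModel}}.
#' @inheritParams fitModel
#' @param nBoot bootstrap replicates.
#' @return the \code{FitResult} with its \code{intervals} slot filled and a
#'   \code{bootstrap} matrix in \code{details}.
#' @export
uncertaintyIntervals <- function(fit, dataset, params, drugs, schedule = NULL,
                                 grid = simulationGrid(), n0 = 1000,
                                 nBoot = 50L, maxit = 60L, seed = 1,
                                 weighting = "replicate") {
  specs <- fit@details$specs
  free <- Filter(function(sp) sp@free, specs)
  nm <- vapply(free, function(sp) sp@name, character(1))
  if (!length(nm)) return(fit)
  summary <- summarizeDataset(dataset, weighting)
  fittedDrugs <- .applySpecs(drugs, specs, as.list(fit@estimates))
  yhat <- .simPredictions(summary, params, fittedDrugs, schedule, grid, n0)
  z <- (summary$mean - yhat) / summary$sem
  if (all(abs(z) < 1e-4))
    warning("degenerate residuals: bootstrap intervals will be near-zero width")
  set.seed(seed)
  boots <- matrix(NA_real_, nBoot, length(nm), dimnames = list(NULL, nm))
  for (b in seq_len(nBoot)) {
    zb <- z
    for (s in unique(summary$stream)) {
      i <- which(summary$stream == s)
      zb[i] <- sample(z[i], length(i), replace = TRUE)
    }
    sb <- summary
    sb$mean <- yhat + zb * summary$sem
    objB <- function(uLogit) {
      u <- stats::plogis(uLogit)
      v <- as.list(mapply(function(ui, sp) .fromUnit(ui, sp), u, free))
      names(v) <- nm
      val <- tryCatch(objectiveValue(sb, params,
                                     .applySpecs(drugs, specs, v),
                                     schedule, grid, n0),
                      error = function(e) Inf)
      if (!is.finite(val)) 1e12 else val
    }
    p0 <- stats::qlogis(mapply(.toUnit, fit@estimates[nm], free))
    opt <- if (length(nm) == 1L) {
      stats::optim(p0, objB, method = "Brent", lower = -12, upper = 12)
    } else {
      stats::optim(p0, objB, method = "Nelder-Mead",
                   control = list(maxit = maxit))
    }
    u <- stats::plogis(opt$par)
    boots[b, ] <- mapply(function(ui, sp) .fromUnit(ui, sp), u, free)
  }
  qs <- apply(boots, 2, stats::quantile, probs = c(0.025, 0.975), names = FALSE)
  iv <- cbind(lower = pmin(qs[1, ], fit@estimates[nm]),
              upper = pmax(qs[2, ], fit@estimates[nm]))
  rownames(iv) <- nm
  fit@intervals <- iv
  fit@details$bootstrap <- boots
  fit
}

#' Nested-model comparison by F test
#'
#' Compares a reduced model against a full model containing extra
#' perturbation modules, using the weighted residual sums of squares:
#' \eqn{F = [(SSE_r - SSE_f)/\Delta k] / [SSE_f/(n - k_f)]}, rejecting the
#' reduced model at level \code{alpha}. Supports the incremental
#' model-building workflow (add a module only when it significantly
#' improves the joint fit).
#'
#' @param fitReduced,fitFull \code{FitResult}s on the same dataset; the
#'   reduced model's free parameters must be a subset of the full model's.
#' @param alpha test level.
#' @return list with statistic, df, p.value and \code{rejectReduced}.
#' @export
compareModels <- function(fitReduced, fitFull, alpha = 0.05) {
  if (fitReduced@nObs != fitFull@nObs)
    stop("fits use different numbers of observations; not comparable")
  nmR <- names(fitReduced@estimates)
  nmF <- names(fitFull@estimates)
  if (fitReduced@nFree >= fitFull@nFree || !all(nmR %in% nmF))
    stop("models are not nested (reduced free parameters must be a strict subset)")
  n <- fitFull@nObs
  dk <- fitFull@nFree - fitReduced@nFree
  df2 <- n - fitFull@nFree
  sseR <- fitReduced@objective
  sseF <- fitFull@objective
  stat <- if (sseF <= 0) {
    if (sseR <= sseF + 1e-12) 0 else Inf
  } else {
    max(0, (sseR - sseF) / dk) / (sseF / df2)
  }
  p <- stats::pf(stat, dk, df2, lower.tail = FALSE)
  list(statistic = stat, df = c(dk, df2), p.value = p,
       rejectReduced = is.finite(stat) && p < alpha)
}

setMethod("show", "FitResult", function(object) {
  cat(sprintf("FitResult: objective %.4g over %d observations, %d free\n",
              object@objective, object@nObs, object@nFree))
  if (length(object@estimates)) {
    for (nm in names(object@estimates)) {
      iv <- object@intervals[nm, ]
      ivs <- if (all(is.finite(iv)))
        sprintf(" [%.3g-%.3g]", iv[1], iv[2]) else ""
      cat(sprintf("  %s = %.4g%s\n", nm, object@estimates[[nm]], ivs))
    }
  }
})
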