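#' Constrained four-parameter logistic dose-response fit
#'
#' Fits \eqn{y = b + (T - b) / (1 + (\mathrm{EC}_{50}/d)^h)} to one
#' dose-response ray with bottom >= 0, top <= 1 and slope > 0, by
#' Levenberg-Marquardt (falling back to bounded quasi-Newton least squares
#' if that fails). Dose 0 contributes the bottom asymptote.
#'
#' @param dose dose vector (>= 4 levels recommended).
#' @param inhibition observed growth-inhibition fractions.
#' @param sd optional replicate SDs used as weights (1/sd^2).
#' @return object of class \code{rayFit}: list with \code{coefficients}
#'   (bottom, top, ec50, hill), \code{fitted}, \code{nonMonotone} flag and
#'   the dose range.
#' @export
fitRay <- function(dose, inhibition, sd = NULL) {
  stopifnot(length(dose) == length(inhibition))
  ord <- order(dose)
  dose <- dose[ord]; inhibition <- inhibition[ord]
  sd <- if (is.null(sd)) rep(1, length(dose)) else pmax(sd[ord], 1e-6)
  pos <- dose > 0
  if (sum(pos) < 3) stop("need at least 3 positive dose levels on a ray")
  f4pl <- function(d, b, T, e, h) b + (T - b) / (1 + (e / pmax(d, 1e-300))^h)
  start <- list(b = max(min(inhibition), 0),
                T = min(max(inhibition), 1),
                e = stats::median(dose[pos]), h = 1.5)
  lowerB <- c(0, 0, min(dose[pos]) / 100, 0.1)
  upperB <- c(1, 1, max(dose) * 100, 20)
  co <- tryCatch({
    fit <- minpack.lm::nlsLM(
      inhibition ~ f4pl(dose, b, T, e, h), start = start,
      lower = lowerB, upper = upperB, weights = 1 / sd^2,
      control = minpack.lm::nls.lm.control(maxiter = 200))
    stats::coef(fit)
  }, error = function(err) {
    sse <- function(p) sum(((f4pl(dose, p[1], p[2], exp(p[3]), p[4]) -
                               inhibition) / sd)^2)
    p0 <- c(start$b, start$T, log(start$e), start$h)
    opt <- stats::optim(p0, sse, method = "L-BFGS-B",
                        lower = c(0, 0, log(lowerB[3]), 0.1),
                        upper = c(1, 1, log(upperB[3]), 20))
    c(b = opt$par[1], T = opt$par[2], e = exp(opt$par[3]), h = opt$par[4])
  })
  co <- stats::setNames(as.numeric(co), c("bottom", "top", "ec50", "hill"))
  fitted <- f4pl(dose, co["bottom"], co["top"], co["ec50"], co["hill"])
  runs <- diff(inhibition[pos])
  nonMono <- length(runs) > 0 &&
    sum(runs < -3 * stats::median(sd)) > length(runs) / 2
  structure(list(coefficients = co, fitted = fitted, dose = dose,
                 inhibition = inhibition, nonMonotone = nonMono),
            class = "rayFit")
}

#' Invert a fitted ray at a target effect level
#'
#' @param fit a \code{rayFit} object.
#' @param level target inhibition fraction (e.g. 0.30 or 0.50).
#' @return the interpolated dose (ICx), with attribute
#'   \code{extrapolated} when it lies outside the tested dose range, or NA
#'   (attribute \code{unreachable}) when the level is outside the fitted
#'   asymptotes.
#' @export
icLevel <- function(fit, level) {
  co <- fit$coefficients
  if (level <= co["bottom"] || level >= co["top"]) {
    out <- NA_real_
    attr(out, "unreachable") <- TRUE
    return(out)
  }
  d <- unname(co["ec50"] * ((co["top"] - level) /
                              (level - co["bottom"]))^(-1 / co["hill"]))
  rng <- range(fit$dose[fit$dose > 0])
  attr(d, "extrapolated") <- d < rng[1] || d > rng[2]
  d
}

#' Loewe Combination Index of one iso-effective dose pair
#'
#' \eqn{\mathrm{CI} = a/\mathrm{IC}_x^A + b/\mathrm{IC}_x^B} for a pair
#' (a, b) producing effect level x; CI < 1 indicates synergy, about 1
#' additivity, > 1 antagonism. Invariant to relabeling the drugs.
#'
#' @param a,b doses of the two agents in the combination.
#' @param icxA,icxB single-agent doses producing the same effect level.
#' @return the CI; NA if either single-agent ICx is NA (level unreachable
#'   by that agent alone).
#' @export
combinationIndex <- function(a, b, icxA, icxB) {
  if (is.na(icxA) || is.na(icxB)) return(NA_real_)
  stopifnot(a >= 0, b >= 0, icxA > 0, icxB > 0)
  a / icxA + b / icxB
}

#' Isobologram and Combination-Index analysis of a factorial grid
#'
#' For each effect level: fits dose-response rays of drug A at each fixed
#' drug-B dose and vice versa (constrained 4PL), inverts them at the target
#' level to obtain iso-effective dose pairs, and computes the Loewe
#' Combination Index of every pair against the single-agent ICx values.
#'
#' @param grid tidy grid data.frame (dose_A, dose_B, replicate, inhibition)
#'   as produced by \code{\link{generateSrbGrid}}.
#' @param levels effect levels (default IC30 and IC50).
#' @param nBoot optional bootstrap replicates over plates for CI intervals.
#' @param seed RNG seed for the bootstrap.
#' @return data.frame: level, dose_A, dose_B, axis ("A" when drug A's dose
#'   was solved for at fixed B), ci, extrapolated; when \code{nBoot > 0},
#'   ciLower/ciUpper columns. The attribute \code{singleAgentIC} gives the
#'   single-agent ICx values per level.
#' @export
isoboleAnalysis <- function(grid, levels = c(0.30, 0.50), nBoot = 0L,
                            seed = 1) {
  run <- function(g) {
    agg <- stats::aggregate(inhibition ~ dose_A + dose_B, data = g, mean)
    sds <- stats::aggregate(inhibition ~ dose_A + dose_B, data = g,
                            stats::sd)
    names(sds)[3] <- "sd"
    agg <- merge(agg, sds, all.x = TRUE)
    dosesA <- sort(unique(agg$dose_A)); dosesB <- sort(unique(agg$dose_B))
    out <- list()
    ics <- list()
    for (lv in levels) {
      fA <- fitRay(agg$dose_A[agg$dose_B == 0], agg$inhibition[agg$dose_B == 0],
                   agg$sd[agg$dose_B == 0])
      fB <- fitRay(agg$dose_B[agg$dose_A == 0], agg$inhibition[agg$dose_A == 0],
                   agg$sd[agg$dose_A == 0])
      icA <- icLevel(fA, lv); icB <- icLevel(fB, lv)
      for (b in dosesB[dosesB > 0]) {
        sub <- agg[agg$dose_B == b, ]
        fr <- tryCatch(fitRay(sub$dose_A, sub$inhibition, sub$sd),
                       error = function(e) NULL)
        if (is.null(fr)) next
        aStar <- icLevel(fr, lv)
        if (is.na(aStar)) next
        out[[length(out) + 1L]] <- data.frame(
          level = lv, dose_A = as.numeric(aStar), dose_B = b, axis = "A",
          ci = combinationIndex(as.numeric(aStar), b, icA, icB),
          extrapolated = isTRUE(attr(aStar, "extrapolated")))
      }
      for (a in dosesA[dosesA > 0]) {
        sub <- agg[agg$dose_A == a, ]
        fr <- tryCatch(fitRay(sub$dose_B, sub$inhibition, sub$sd),
                       error = function(e) NULL)
        if (is.null(fr)) next
        bStar <- icLevel(fr, lv)
        if (is.na(bStar)) next
        out[[length(out) + 1L]] <- data.frame(
          level = lv, dose_A = a, dose_B = as.numeric(bStar), axis = "B",
          ci = combinationIndex(a, as.numeric(bStar), icA, icB),
          extrapolated = isTRUE(attr(bStar, "extrapolated")))
      }
      ics[[sprintf("ic_%g", lv)]] <- c(A = as.numeric(icA),
                                       B = as.numeric(icB))
    }
    res <- if (length(out)) do.call(rbind, out) else
      data.frame(level = numeric(), dose_A = numeric(), dose_B = numeric(),
                 axis = character(), ci = numeric(), extrapolated = logical())
    attr(res, "singleAgentIC") <- ics
    res
  }
  res <- run(grid)
  if (nBoot > 0) {
    set.seed(seed)
    reps <- sort(unique(grid$replicate))
    bootCi <- replicate(nBoot, {
      pickR <- sample(reps, length(reps), replace = TRUE)
      gb <- do.call(rbind, lapply(seq_along(pickR), function(i) {
        gi <- grid[grid$replicate == pickR[i], ]
        gi$replicate <- i
        gi
      }))
      rb <- tryCatch(run(gb), error = function(e) NULL)
      if (is.null(rb)) return(rep(NA_real_, nrow(res)))
      key <- paste(res$level, res$dose_B, res$axis,
                   ifelse(res$axis == "A", res$dose_B, res$dose_A))
      keyB <- paste(rb$level, rb$dose_B, rb$axis,
                    ifelse(rb$axis == "A", rb$dose_B, rb$dose_A))
      rb$ci[match(key, keyB)]
    })
    if (is.null(dim(bootCi))) bootCi <- matrix(bootCi, nrow = nrow(res))
    res$ciLower <- apply(bootCi, 1, stats::quantile, 0.025, na.rm = TRUE)
    res$ciUpper <- apply(bootCi, 1, stats::quantile, 0.975, na.rm = TRUE)
  }
  res
}
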