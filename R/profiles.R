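#' Construct a time-activation profile
#'
#' @param kind "constant", "step_window", "sigmoid" or "recovery".
#' @param onset activation time (h, module clock); used by constant and
#'   step_window.
#' @param offset deactivation time for step_window (h); Inf for open windows.
#' @param halfMax time at which a sigmoid reaches 1/2 (or a recovery profile
#'   the midpoint between 1 and its floor), h.
#' @param steepness logistic time scale, h. The default 1.366 makes the
#'   10\%-to-90\% rise span 6 h.
#' @param floor residual plateau of a recovery profile, in [0, 1].
#' @return a \code{\linkS4class{TimeProfile}}.
#' @examples
#' pr <- timeProfile("sigmoid", halfMax = 6)
#' profileValue(pr, 6) # 0.5
#' @export
timeProfile <- function(kind = "constant", onset = 0, offset = Inf,
                        halfMax = 0, steepness = 1.366, floor = 0) {
  new("TimeProfile", kind = kind, onset = onset, offset = offset,
      halfMax = halfMax, steepness = steepness, floor = floor)
}

#' Evaluate a time profile
#'
#' @param profile a \code{TimeProfile}.
#' @param t numeric vector of times on the module clock, h.
#' @return numeric vector of values in [0, 1].
#' @export
profileValue <- function(profile, t) {
  v <- switch(profile@kind,
    constant = as.numeric(t >= profile@onset),
    step_window = as.numeric(t >= profile@onset & t < profile@offset),
    sigmoid = stats::plogis((t - profile@halfMax) / profile@steepness),
    recovery = profile@floor + (1 - profile@floor) *
      stats::plogis(-(t - profile@halfMax) / profile@steepness),
    stop("unknown profile kind: ", profile@kind)
  )
  pmin(pmax(v, 0), 1)
}

setMethod("show", "TimeProfile", function(object) {
  cat(sprintf("TimeProfile <%s>", object@kind))
  if (object@kind == "step_window")
    cat(sprintf(" [%g, %g) h", object@onset, object@offset))
  if (object@kind %in% c("sigmoid", "recovery"))
    cat(sprintf(" half-max %g h, steepness %g h", object@halfMax,
                object@steepness))
  if (object@kind == "recovery") cat(sprintf(", floor %g", object@floor))
  cat("\n")
})
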