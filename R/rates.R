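# Precomputed per-step effect tables shared by the deterministic engine and
# the single-cell microsimulator.
#
# For every (phase, generation, step) the tables hold:
#   speed   - aging-speed factor, prod(1 - d_i * profile_i) over delays and
#             synthesis inhibition (1 = unperturbed)
#   block   - arrest probability at the phase-exit checkpoint, combined as
#             1 - prod(1 - p_i * profile_i)
#   death   - summed per-hour death rate (applied to transit and blocked
#             cells of that phase/generation)
#   recycle - summed per-hour exit rate of the blocked pool of that phase
.buildRateTables <- function(drugs, schedule, nGen, times) {
  nt <- length(times)
  dims <- c(3L, nGen, nt)
  tab <- list(speed = array(1, dims), block = array(0, dims),
              death = array(0, dims), recycle = array(0, dims))
  if (!length(drugs)) return(tab)
  iv <- if (is.null(schedule)) data.frame(drug = character(), start = numeric(),
                                          end = numeric()) else schedule@intervals
  byName <- stats::setNames(drugs, vapply(drugs, function(d) d@name, character(1)))
  for (i in seq_len(nrow(iv))) {
    d <- byName[[iv$drug[i]]]
    if (is.null(d)) stop("schedule names drug '", iv$drug[i],
                         "' absent from the model list")
    for (m in d@modules) {
      base <- if (m@window == "post") iv$end[i] else iv$start[i]
      gate <- switch(m@window,
        during = times >= iv$start[i] & times < iv$end[i],
        post = times >= iv$end[i],
        all = times >= iv$start[i])
      gate <- gate & times < m@activeUntil
      if (!any(gate)) next
      val <- m@magnitude * profileValue(m@profile, times - base) * gate
      gens <- if (length(m@generations)) m@generations + 1L else seq_len(nGen)
      gens <- gens[gens >= 1L & gens <= nGen]
      p <- match(m@phase, .PHASES)
      for (g in gens) {
        if (m@effect %in% c("delay", "synthesis_inhibition")) {
          tab$speed[p, g, ] <- tab$speed[p, g, ] * (1 - val)
        } else if (m@effect == "block") {
          tab$block[p, g, ] <- 1 - (1 - tab$block[p, g, ]) * (1 - val)
        } else if (m@effect == "death") {
          tab$death[p, g, ] <- tab$death[p, g, ] + val
        } else if (m@effect == "recycle") {
          tab$recycle[p, g, ] <- tab$recycle[p, g, ] + val
        }
      }
    }
  }
  tab
}
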