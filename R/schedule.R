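#' Construct a treatment schedule
#'
#' @param drug character vector of drug names.
#' @param start,end exposure interval bounds, hours. Washout is implied by
#'   the interval end.
#' @return a \code{\linkS4class{TreatmentSchedule}}.
#' @examples
#' # gemcitabine 0-6 h followed, after an 18 h gap, by 48 h erlotinib
#' treatmentSchedule(c("gemcitabine", "erlotinib"), c(0, 24), c(6, 72))
#' @export
treatmentSchedule <- function(drug = character(), start = numeric(),
                              end = numeric()) {
  new("TreatmentSchedule",
      intervals = data.frame(drug = as.character(drug), start = start,
                             end = end, stringsAsFactors = FALSE))
}

#' Exposure intervals of a schedule
#' @param schedule a \code{TreatmentSchedule}.
#' @export
scheduleIntervals <- function(schedule) schedule@intervals

setMethod("show", "TreatmentSchedule", function(object) {
  cat("TreatmentSchedule\n")
  iv <- object@intervals
  if (!nrow(iv)) { cat("  (untreated)\n"); return(invisible(NULL)) }
  for (i in seq_len(nrow(iv)))
    cat(sprintf("  %s: %g-%g h\n", iv$drug[i], iv$start[i], iv$end[i]))
})
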