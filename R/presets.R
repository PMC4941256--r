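#' Shipped parameter sets
#'
#' The package ships YAML encodings of the published best-fit single-drug
#' models for the BxPC-3 pancreatic cancer cell line (erlotinib 1 and 10 uM
#' over 0-48 h; gemcitabine 20 and 40 nM over 0-6 h) and nominal Capan-1
#' counterparts; files whose values are nominal rather than published carry
#' the suffix \code{_nominal}. Cell-line cycling parameters are nominal
#' throughout (the originals are not printed in the main text).
#'
#' @param name base name of a file under \code{extdata/models} (without
#'   extension), e.g. "bxpc3_erlotinib_1uM".
#' @return a \code{DrugModel}.
#' @export
shippedModel <- function(name) {
  path <- system.file("extdata", "models", paste0(name, ".yaml"),
                      package = "cytokinetics")
  if (path == "") stop("no shipped model '", name, "'; see shippedModelNames()")
  readDrugModel(path)
}

#' @rdname shippedModel
#' @export
shippedModelNames <- function() {
  sub("\\.yaml$", "",
      list.files(system.file("extdata", "models", package = "cytokinetics"),
                 pattern = "\\.yaml$"))
}

#' @rdname shippedModel
#' @param line "bxpc3" or "capan1".
#' @export
shippedCellCycleParameters <- function(line = "bxpc3") {
  path <- system.file("extdata", "params", paste0(line, "_nominal.yaml"),
                      package = "cytokinetics")
  if (path == "") stop("no shipped parameters for '", line, "'")
  readCellCycleParameters(path)
}

#' Published single-treatment schedules
#'
#' Single treatments: erlotinib 0-48 h, gemcitabine 0-6 h. Sequential
#' schedules with an 18 h gap: gemcitabine-then-erlotinib ("GE",
#' gemcitabine 0-6 h, erlotinib 24-72 h) and erlotinib-then-gemcitabine
#' ("EG", erlotinib 0-48 h, gemcitabine 66-72 h).
#'
#' @param which "erlotinib", "gemcitabine", "GE" or "EG".
#' @export
shippedSchedule <- function(which = c("erlotinib", "gemcitabine", "GE", "EG")) {
  which <- match.arg(which)
  switch(which,
    erlotinib = treatmentSchedule("erlotinib", 0, 48),
    gemcitabine = treatmentSchedule("gemcitabine", 0, 6),
    GE = treatmentSchedule(c("gemcitabine", "erlotinib"), c(0, 24), c(6, 72)),
    EG = treatmentSchedule(c("erlotinib", "gemcitabine"), c(0, 66), c(48, 72)))
}

#' Published uncertainty brackets for shipped model parameters
#'
#' Interval table (parameter, value, lower, upper) for the parameters of
#' the shipped BxPC-3 single-drug models, as printed with the best-fit
#' estimates; parameter names follow the module labels.
#'
#' @param model a shipped model name, e.g. "bxpc3_erlotinib_1uM".
#' @export
shippedIntervals <- function(model) {
  tab <- list(
    bxpc3_erlotinib_1uM = data.frame(
      parameter = c("delayS.g0", "blockG2M.g0", "blockG1.g1", "delayS.g1",
                    "deathS.g01", "delayS.post.g1", "delayG2M.post.g1",
                    "recycleG1.g01"),
      value = c(0.33, 0.11, 0.23, 0.33, 0.010, 0.41, 0.19, 0.03),
      lower = c(0.30, 0.08, 0.21, 0.30, 0.008, 0.36, 0.04, 0.02),
      upper = c(0.35, 0.14, 0.25, 0.35, 0.011, 0.45, 0.30, 0.04)),
    bxpc3_erlotinib_10uM = data.frame(
      parameter = c("delayS.g0", "blockG2M.g0", "blockG1.g1", "delayS.g1",
                    "deathS.g01", "delayS.post.g1", "delayG2M.post.g1",
                    "recycleG1.g01"),
      value = c(0.93, 0.23, 0.98, 0, 0.014, 0.41, 0.28, 0.24),
      lower = c(0.91, 0.19, 0.97, 0, 0.012, 0.39, 0.18, 0.21),
      upper = c(0.96, 0.27, 0.996, 0.09, 0.016, 0.44, 0.36, 0.26)),
    bxpc3_gemcitabine_20nM = data.frame(
      parameter = c("delayG1.g0", "synthS.g01", "blockG2M.g0"),
      value = c(0.75, 0.88, 0.10),
      lower = c(0.56, 0.85, 0.07),
      upper = c(0.93, 0.91, 0.13)),
    bxpc3_gemcitabine_40nM = data.frame(
      parameter = c("delayG1.g0", "synthS.g01", "ltDelayS.g0",
                    "blockG2M.g0", "ltDelayS.g1"),
      value = c(0.87, 1, 0.37, 0.15, 0.18),
      lower = c(0.75, 0.97, 0.33, 0.12, 0.13),
      upper = c(0.98, 1, 0.40, 0.17, 0.22))
  )
  out <- tab[[model]]
  if (is.null(out)) stop("no interval table for '", model, "'")
  out
}
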