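.profileToList <- function(pr) {
  out <- list(kind = pr@kind)
  if (pr@kind %in% c("constant", "step_window")) out$onset <- pr@onset
  if (pr@kind == "step_window" && is.finite(pr@offset)) out$offset <- pr@offset
  if (pr@kind %in% c("sigmoid", "recovery")) {
    out$half_max <- pr@halfMax
    out$steepness <- pr@steepness
  }
  if (pr@kind == "recovery") out$floor <- pr@floor
  out
}

.profileFromList <- function(x) {
  timeProfile(kind = x$kind %||% "constant",
              onset = x$onset %||% 0,
              offset = x$offset %||% Inf,
              halfMax = x$half_max %||% 0,
              steepness = x$steepness %||% 1.366,
              floor = x$floor %||% 0)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a drug model to YAML
#'
#' The serialization round-trips: \code{readDrugModel(writeDrugModel(m))}
#' reproduces the model.
#' @param drug a \code{DrugModel}.
#' @param path output file.
#' @export
writeDrugModel <- function(drug, path) {
  x <- list(name = drug@name, concentration = drug@concentration,
            modules = lapply(drug@modules, function(m) {
              list(label = m@label, effect = m@effect, phase = m@phase,
                   generations = as.list(m@generations),
                   magnitude = m@magnitude, window = m@window,
                   profile = .profileToList(m@profile))
            }))
  yaml::write_yaml(x, path)
  invisible(path)
}

#' Read a drug model from YAML
#' @param path YAML file written by \code{\link{writeDrugModel}} (or by
#'   hand; generations accept the "0/1" shorthand).
#' @export
readDrugModel <- function(path) {
  x <- yaml::read_yaml(path)
  mods <- lapply(x$modules, function(m) {
    perturbationModule(label = m$label, effect = m$effect, phase = m$phase,
                       generations = if (is.character(m$generations))
                         m$generations else unlist(m$generations),
                       magnitude = m$magnitude,
                       profile = .profileFromList(m$profile %||% list()),
                       window = m$window %||% "during")
  })
  drugModel(x$name, x$concentration %||% "", mods)
}

#' Read cell-cycle parameters from YAML
#' @param path YAML file with fields mean_G1, mean_S, mean_G2M, cv_G1,
#'   cv_S, cv_G2M and optional max_generation.
#' @export
readCellCycleParameters <- function(path) {
  x <- yaml::read_yaml(path)
  cellCycleParameters(x$mean_G1, x$mean_S, x$mean_G2M, x$cv_G1, x$cv_S,
                      x$cv_G2M, x$max_generation %||% 5L)
}

#' Write a tidy observables/dataset table to CSV with a provenance header
#'
#' @param df a tidy data.frame.
#' @param path output file.
#' @param seed,config optional seed and configuration description recorded
#'   in comment lines.
#' @export
writeObservablesCsv <- function(df, path, seed = NULL, config = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# cytokinetics %s",
                     as.character(utils::packageVersion("cytokinetics"))), con)
  if (!is.null(seed)) writeLines(sprintf("# seed: %s", seed), con)
  if (!is.null(config)) writeLines(sprintf("# config: %s", config), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Read a tidy CSV written by \code{\link{writeObservablesCsv}}
#' @param path input file; leading comment lines are skipped.
#' @export
readObservablesCsv <- function(path) {
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}
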