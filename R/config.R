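# Structured pipeline configuration: one YAML file with optional sections
# `sim`, `splice`, `classify` and `events`, whose keys are the arguments of
# simConfig(), spliceConfig(), classifyConfig() and assignEvents()
# respectively (named maps such as lossTypeProbs become named vectors).

#' Read a pipeline configuration file
#'
#' @param path YAML file with optional sections \code{sim}, \code{splice},
#'   \code{classify}, \code{events} (\code{overrides}, \code{maxGainSpan}).
#'   Missing sections fall back to defaults.
#' @return list with elements \code{sim} (\linkS4class{SimConfig}),
#'   \code{splice} (\linkS4class{SpliceConfig}), \code{classify}
#'   (\linkS4class{ClassifyConfig}), \code{overrides} (character),
#'   \code{maxGainSpan} (numeric).
#' @export
readPipelineConfig <- function(path) {
  raw <- if (is.null(path)) list() else yaml::read_yaml(path)
  simplify <- function(x) {
    if (is.list(x)) lapply(x, function(v) if (is.list(v)) unlist(v) else v)
    else x
  }
  list(
    sim = do.call(simConfig, simplify(raw$sim %||% list())),
    splice = do.call(spliceConfig, simplify(raw$splice %||% list())),
    classify = do.call(classifyConfig, simplify(raw$classify %||% list())),
    overrides = as.character(raw$events$overrides %||% character(0)),
    maxGainSpan = as.numeric(raw$events$maxGainSpan %||% Inf))
}
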