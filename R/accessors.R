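#' Construct a sampling design
#'
#' @param occasions `Date` vector (or ISO-8601 strings) of sampling
#'   occasions, strictly increasing.  Spacing is nominally 14 days; other
#'   spacings warn but are accepted.
#' @param trees `data.frame` with columns `tree_id`, `unit`, `treatment`
#'   (`"reference"`/`"fire_2021"`) and `burn_date` (`Date` or ISO string,
#'   `NA` for reference trees).
#' @param heights character height-stratum labels, bottom to top.
#' @return a [SamplingDesign-class] object.
#' @examples
#' d <- SamplingDesign(
#'   occasions = as.Date("2021-03-05") + 14 * 0:3,
#'   trees = data.frame(tree_id = c("R1", "F1"), unit = c("A", "B"),
#'                      treatment = c("reference", "fire_2021"),
#'                      burn_date = as.Date(c(NA, "2021-03-20"))),
#'   heights = c("3m", "6m"))
#' nOccasions(d)
#' @export
SamplingDesign <- function(occasions, trees,
                           heights = c("3m", "6m", "9m", "9plus")) {
  occasions <- as.Date(occasions)
  trees$tree_id <- as.character(trees$tree_id)
  trees$unit <- as.character(trees$unit)
  trees$treatment <- as.character(trees$treatment)
  trees$burn_date <- as.Date(trees$burn_date)
  obj <- new("SamplingDesign", occasions = occasions, trees = trees,
             heights = as.character(heights))
  sp <- diff(as.numeric(occasions))
  if (any(sp != 14))
    warning("occasion spacing deviates from the nominal 14 days")
  obj
}

#' @rdname SamplingDesign
#' @export
setMethod("occasions", "SamplingDesign", function(x) x@occasions)

#' @rdname SamplingDesign
#' @export
setMethod("studyTrees", "SamplingDesign", function(x) x@trees)

#' @rdname SamplingDesign
#' @export
setMethod("heightLabels", "SamplingDesign", function(x) x@heights)

#' @rdname SamplingDesign
#' @export
setMethod("nOccasions", "SamplingDesign", function(x) length(x@occasions))

#' @rdname SamplingDesign
#' @export
setMethod("nTrees", "SamplingDesign", function(x) nrow(x@trees))

#' @rdname SamplingDesign
#' @export
setMethod("nHeights", "SamplingDesign", function(x) length(x@heights))

setMethod("show", "SamplingDesign", function(object) {
  tr <- object@trees
  cat("SamplingDesign:", length(object@occasions), "occasions (",
      format(min(object@occasions)), "to", format(max(object@occasions)),
      "),", nrow(tr), "trees (", sum(tr$treatment == "reference"),
      "reference /", sum(tr$treatment == "fire_2021"), "fire_2021 ),",
      length(object@heights), "height strata:",
      paste(object@heights, collapse = ", "), "\n")
})

#' @rdname CaptureHistories
#' @export
setMethod("stateMatrix", "CaptureHistories", function(x) assay(x, "state"))

#' @rdname CaptureHistories
#' @export
setMethod("firstCapture", "CaptureHistories", function(x) rowData(x)$f)

#' @rdname CaptureHistories
#' @export
setMethod("lastOccasion", "CaptureHistories", function(x) rowData(x)$last)

#' @rdname CaptureHistories
#' @export
setMethod("removedFlag", "CaptureHistories", function(x) rowData(x)$removed)

#' @rdname CaptureHistories
#' @export
setMethod("exclusions", "CaptureHistories", function(x) metadata(x)$exclusions)

#' @rdname CaptureHistories
#' @export
setMethod("heightLabels", "CaptureHistories", function(x) metadata(x)$heights)

setMethod("show", "CaptureHistories", function(object) {
  y <- assay(object, "state")
  cat("CaptureHistories:", nrow(y), "individuals x", ncol(y), "occasions;",
      sum(y > 0), "detections;", sum(rowData(object)$removed),
      "removed on recovery;", nrow(metadata(object)$exclusions %||% data.frame()),
      "excluded records\n")
})

#' @rdname AbundanceTable
#' @export
setMethod("newCounts", "AbundanceTable", function(x) assay(x, "newCounts"))

#' @rdname AbundanceTable
#' @export
setMethod("totalCounts", "AbundanceTable", function(x) assay(x, "totalCounts"))

setMethod("show", "AbundanceTable", function(object) {
  cat("AbundanceTable:", nrow(object), "trees x", ncol(object),
      "occasions; new =", sum(assay(object, "newCounts")),
      ", total =", sum(assay(object, "totalCounts")), "\n")
})

#' @rdname MultistateParams
#' @export
setMethod("survivalProb", "MultistateParams", function(x) x@phi)

#' @rdname MultistateParams
#' @export
setMethod("movementMatrix", "MultistateParams", function(x) x@alpha)

#' @rdname MultistateParams
#' @export
setMethod("recaptureProb", "MultistateParams", function(x) x@p)

#' @rdname MultistateParams
#' @export
setMethod("nHeights", "MultistateParams", function(x) length(x@phi))

setMethod("show", "MultistateParams", function(object) {
  cat("MultistateParams over", length(object@phi), "height states\n")
  cat("  phi:", paste(format(object@phi, digits = 3), collapse = " "), "\n")
  cat("  p:  ", paste(format(object@p, digits = 3), collapse = " "), "\n")
  cat("  alpha diagonal:",
      paste(format(diag(object@alpha), digits = 3), collapse = " "), "\n")
})

#' @rdname PosteriorDraws
#' @export
setMethod("drawsMatrix", "PosteriorDraws", function(x) x@draws)

#' @rdname PosteriorDraws
#' @export
setMethod("chainId", "PosteriorDraws", function(x) x@chain)

#' @rdname PosteriorDraws
#' @export
setMethod("pointwiseLogLik", "PosteriorDraws", function(x) x@logLik)

#' @rdname PosteriorDraws
#' @export
setMethod("mcmcDiagnostics", "PosteriorDraws", function(x) x@diagnostics)

setMethod("show", "PosteriorDraws", function(object) {
  d <- object@diagnostics
  cat("PosteriorDraws [", object@model, "]: ", nrow(object@draws),
      " draws x ", ncol(object@draws), " parameters, ",
      length(unique(object@chain)), " chains\n", sep = "")
  if (nrow(d)) {
    cat("  max split R-hat = ", format(max(d$rhat), digits = 4),
        ", min ESS = ", format(min(d$ess), digits = 4), "\n", sep = "")
  }
})

setMethod("show", "WAICResult", function(object) {
  cat("WAIC = ", format(object@waic, digits = 6),
      " (lppd = ", format(object@lppd, digits = 6),
      ", pWAIC = ", format(object@pWaic, digits = 4),
      ", n = ", object@nPoints, ")\n", sep = "")
})

`%||%` <- function(a, b) if (is.null(a)) b else a
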