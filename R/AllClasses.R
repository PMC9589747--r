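#' @import methods
#' @importFrom S4Vectors DataFrame SimpleList metadata metadata<-
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays rowData colData
NULL

#' Sampling design of a BACI mark-recapture study
#'
#' Holds the skeleton of the experiment: ordered sampling occasions, the
#' study trees with their burn treatment, and the height strata at which
#' pipe refugia were set.  Occasions are nominally biweekly; a deviation
#' from 14-day spacing triggers a warning at construction, not an error.
#'
#' @slot occasions ordered `Date` vector of sampling occasions (length T).
#' @slot trees `data.frame` with columns `tree_id`, `unit`, `treatment`
#'   (`"reference"` or `"fire_2021"`) and `burn_date` (`Date`, `NA` for
#'   reference trees).
#' @slot heights character vector of height-stratum labels, ordered
#'   bottom to top (height index h = 1..H).
#'
#' @exportClass SamplingDesign
setClass("SamplingDesign",
  representation(
    occasions = "Date",
    trees     = "data.frame",
    heights   = "character"
  )
)

setValidity("SamplingDesign", function(object) {
  msg <- character()
  occ <- object@occasions
  if (length(occ) < 2L) msg <- c(msg, "need at least 2 occasions")
  if (anyNA(occ)) msg <- c(msg, "occasion dates must not be NA")
  if (length(occ) >= 2L && any(diff(as.numeric(occ)) <= 0))
    msg <- c(msg, "occasion dates must be strictly increasing")
  tr <- object@trees
  need <- c("tree_id", "unit", "treatment", "burn_date")
  if (!all(need %in% names(tr))) {
    msg <- c(msg, paste("trees must have columns", paste(need, collapse = ", ")))
  } else {
    if (anyDuplicated(tr$tree_id)) msg <- c(msg, "tree_id values must be unique")
    if (!all(tr$treatment %in% c("reference", "fire_2021")))
      msg <- c(msg, "treatment must be 'reference' or 'fire_2021'")
    fire <- tr$treatment == "fire_2021"
    if (any(fire & is.na(tr$burn_date)))
      msg <- c(msg, "fire_2021 trees must have a burn_date")
    if (any(!fire & !is.na(tr$burn_date)))
      msg <- c(msg, "reference trees must not have a burn_date")
    bd <- tr$burn_date[fire & !is.na(tr$burn_date)]
    if (length(bd) && length(occ) >= 2L &&
        (any(bd < min(occ)) || any(bd > max(occ))))
      msg <- c(msg, "burn_date must lie within the study window")
  }
  h <- object@heights
  if (length(h) < 2L) msg <- c(msg, "need at least 2 height strata")
  if (anyDuplicated(h)) msg <- c(msg, "height labels must be unique")
  if (length(msg)) msg else TRUE
})

#' Capture-history matrix with individual metadata
#'
#' A [SummarizedExperiment][SummarizedExperiment::SummarizedExperiment-class]
#' whose single assay `"state"` is an integer matrix (individuals x
#' occasions) with entries 0 = not seen and h = seen at height stratum h.
#' Row metadata carries the individual id, the tree of first capture, the
#' first-capture occasion `f`, the truncation occasion `last` (last
#' occasion entering the likelihood; `T` unless removed on recovery) and a
#' `removed` flag for individuals found dead.  `metadata()` holds the
#' height labels and the exclusion report.
#'
#' @exportClass CaptureHistories
setClass("CaptureHistories", contains = "SummarizedExperiment")

setValidity("CaptureHistories", function(object) {
  msg <- character()
  if (!"state" %in% names(assays(object)))
    return("assay 'state' is required")
  y <- assay(object, "state")
  H <- length(metadata(object)$heights)
  if (!is.numeric(y) || anyNA(y) || any(y < 0) || any(y > H) ||
      any(y != round(y)))
    msg <- c(msg, sprintf("state entries must be integers in 0..H (H = %d)", H))
  rd <- rowData(object)
  need <- c("individual_id", "tree_id", "f", "last", "removed")
  if (!all(need %in% names(rd)))
    return(paste("rowData must have columns", paste(need, collapse = ", ")))
  if (nrow(object) > 0L) {
    f <- rd$f
    if (any(f < 1L) || any(f > ncol(object)))
      msg <- c(msg, "f must lie in 1..T")
    bad <- which(y[cbind(seq_len(nrow(y)), f)] < 1)
    if (length(bad))
      msg <- c(msg, sprintf("history %d not seen at its first-capture occasion", bad[1L]))
    for (i in seq_len(nrow(y)))
      if (rd$f[i] > 1L && any(y[i, seq_len(rd$f[i] - 1L)] != 0))
        msg <- c(msg, sprintf("history %d has detections before f", i))
    if (any(rd$last < rd$f) || any(rd$last > ncol(object)))
      msg <- c(msg, "last must lie in f..T")
  }
  if (length(msg)) msg else TRUE
})

#' Per-tree, per-occasion count table
#'
#' A [SummarizedExperiment][SummarizedExperiment::SummarizedExperiment-class]
#' with assays `newCounts` (first detections of identified individuals) and
#' `totalCounts` (every detection event, including recaptures and
#' unidentified escapes), rows = trees, columns = occasions.
#'
#' @exportClass AbundanceTable
setClass("AbundanceTable", contains = "SummarizedExperiment")

setValidity("AbundanceTable", function(object) {
  msg <- character()
  if (!all(c("newCounts", "totalCounts") %in% names(assays(object))))
    return("assays 'newCounts' and 'totalCounts' are required")
  nw <- assay(object, "newCounts"); tt <- assay(object, "totalCounts")
  if (any(nw < 0) || any(tt < 0) || any(nw != round(nw)) || any(tt != round(tt)))
    msg <- c(msg, "counts must be nonnegative integers")
  if (any(tt < nw))
    msg <- c(msg, "totalCounts must be >= newCounts element-wise")
  if (length(msg)) msg else TRUE
})

#' Parameters of the height-structured multi-state model
#'
#' Apparent survival `phi[h]`, movement simplex `alpha[h, h']` (row h sums
#' to 1 over destination heights) and recapture probability `p[h]` for
#' live height states h = 1..H.  The dead state H+1 is implicit: it is
#' absorbing and unobservable.
#'
#' @slot phi numeric vector of per-interval apparent survival, one per height.
#' @slot alpha H x H movement probability matrix, rows are simplices.
#' @slot p numeric vector of recapture probabilities, one per height.
#' @slot heights optional height labels (length H).
#'
#' @exportClass MultistateParams
setClass("MultistateParams",
  representation(phi = "numeric", alpha = "matrix", p = "numeric",
                 heights = "character")
)

setValidity("MultistateParams", function(object) {
  msg <- character()
  H <- length(object@phi)
  if (H < 2L) msg <- c(msg, "need at least 2 height states")
  if (length(object@p) != H) msg <- c(msg, "phi and p must have equal length")
  if (!all(dim(object@alpha) == c(H, H)))
    msg <- c(msg, "alpha must be H x H")
  prob <- c(object@phi, object@p, object@alpha)
  if (anyNA(prob) || any(prob < 0) || any(prob > 1))
    msg <- c(msg, "all probabilities must lie in [0, 1]")
  else if (any(abs(rowSums(object@alpha) - 1) > 1e-12))
    msg <- c(msg, "each alpha row must sum to 1 (tolerance 1e-12)")
  if (length(object@heights) && length(object@heights) != H)
    msg <- c(msg, "heights must have length H")
  if (length(msg)) msg else TRUE
})

#' Prior specification for the multi-state model
#'
#' Beta priors per height for survival and recapture, Dirichlet
#' concentrations per row for the movement simplex.  Defaults are flat:
#' Beta(1, 1) and Dirichlet(1, ..., 1).
#'
#' @slot phiPrior H x 2 matrix of Beta (a, b) hyperparameters.
#' @slot pPrior H x 2 matrix of Beta (a, b) hyperparameters.
#' @slot alphaConc H x H matrix of Dirichlet concentrations (row h is the
#'   concentration vector for movement out of height h).
#'
#' @exportClass PriorSpec
setClass("PriorSpec",
  representation(phiPrior = "matrix", pPrior = "matrix", alphaConc = "matrix")
)

setValidity("PriorSpec", function(object) {
  if (any(object@phiPrior <= 0) || any(object@pPrior <= 0) ||
      any(object@alphaConc <= 0))
    "all hyperparameters must be > 0" else TRUE
})

#' Posterior draws with pointwise log-likelihood and diagnostics
#'
#' Retained MCMC draws (rows) over named parameters (columns), the chain
#' id of each draw, the pointwise log-likelihood matrix feeding WAIC (one
#' column per data point: capture history or count cell), and per-parameter
#' split R-hat / effective-sample-size diagnostics.
#'
#' @slot draws numeric matrix, S retained draws x named parameters.
#' @slot chain integer vector of length S.
#' @slot logLik numeric matrix, S x n data points.
#' @slot diagnostics `data.frame` with columns `parameter`, `rhat`, `ess`.
#' @slot model character tag identifying what was fitted.
#' @slot info list of fit metadata (heights, seed, prior settings, ...).
#'
#' @exportClass PosteriorDraws
setClass("PosteriorDraws",
  representation(draws = "matrix", chain = "integer", logLik = "matrix",
                 diagnostics = "data.frame", model = "character", info = "list")
)

setValidity("PosteriorDraws", function(object) {
  msg <- character()
  S <- nrow(object@draws)
  if (S < 1L) msg <- c(msg, "need at least one retained draw")
  if (length(object@chain) != S) msg <- c(msg, "chain must have one entry per draw")
  if (nrow(object@logLik) != S) msg <- c(msg, "logLik must have one row per draw")
  if (is.null(colnames(object@draws))) msg <- c(msg, "draws must have column names")
  if (length(msg)) msg else TRUE
})

#' WAIC of one fitted model
#'
#' Computed from the pointwise posterior log-likelihood matrix:
#' `lppd = sum_k log mean_s exp(ll[s, k])` (log-sum-exp stabilized),
#' `pWaic = sum_k var_s(ll[s, k])` (sample variance, denominator S - 1),
#' `waic = -2 (lppd - pWaic)`.  Lower WAIC indicates better expected
#' predictive fit.
#'
#' @slot lppd log pointwise predictive density.
#' @slot pWaic effective number of parameters.
#' @slot waic the criterion, -2 (lppd - pWaic).
#' @slot nPoints number of data points.
#' @slot pointwiseLppd,pointwisePWaic per-point contributions.
#'
#' @exportClass WAICResult
setClass("WAICResult",
  representation(lppd = "numeric", pWaic = "numeric", waic = "numeric",
                 nPoints = "integer", pointwiseLppd = "numeric",
                 pointwisePWaic = "numeric")
)

setValidity("WAICResult", function(object) {
  msg <- character()
  if (object@pWaic < 0) msg <- c(msg, "pWaic must be nonnegative")
  if (object@nPoints < 1L) msg <- c(msg, "need at least one data point")
  if (length(msg)) msg else TRUE
})
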