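#' @useDynLib canopymr, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Forward-algorithm log-likelihood of capture histories
#'
#' Marginal probability of the observations after first capture, summed
#' over all latent height/death paths by the hidden-Markov forward
#' recursion.  The likelihood conditions on first capture: the state at
#' occasion `f` is the observed height with probability 1, and the
#' product runs over occasions `f+1 .. last` (where `last < T` only for
#' individuals removed on recovery).  Detections contribute the
#' seen-at-height column of the observation matrix, non-detections the
#' not-seen column.  A parameter set that makes an observation
#' impossible yields `-Inf`, never `NaN`; per-step renormalization keeps
#' the recursion numerically stable.
#'
#' `loglikDataset()` evaluates all histories and returns the total with
#' the pointwise vector that feeds WAIC; `loglikHistory()` is the
#' single-history convenience wrapper.
#'
#' @param histories a [CaptureHistories-class].
#' @param params a [MultistateParams-class] with H matching the
#'   histories' height strata.
#' @return `loglikDataset()`: list with `total` and `pointwise` (named by
#'   individual); `loglikHistory()`: a single log-likelihood.
#' @examples
#' d <- fireStudyDesign()
#' det <- data.frame(individual_id = "a", occasion = c(2L, 3L),
#'                   tree_id = "SE-1", height = 2L, fate = "alive",
#'                   mark_status = c("new", "recapture"))
#' ch <- buildCaptureHistories(det, d)
#' pars <- MultistateParams(phi = rep(.8, 4), alpha = diag(4) * .5 + .125,
#'                          p = rep(.7, 4))
#' loglikDataset(ch, pars)$total
#' @export
loglikDataset <- function(histories, params) {
  validObject(params)
  y <- stateMatrix(histories)
  if (length(params@phi) != length(heightLabels(histories)))
    stop("params have ", length(params@phi), " height states but the ",
         "histories have ", length(heightLabels(histories)))
  if (nrow(y) == 0L)
    return(list(total = 0, pointwise = numeric(0)))
  pw <- .msForwardLoglik(y, firstCapture(histories),
                         lastOccasion(histories), params@phi,
                         params@alpha, params@p)
  if (anyNA(pw))
    stop("malformed history: not seen at its first-capture occasion")
  names(pw) <- rowData(histories)$individual_id
  list(total = sum(pw), pointwise = pw)
}

#' @rdname loglikDataset
#' @param y integer state vector over occasions (0 = not seen).
#' @param f first-capture occasion; defaults to the first nonzero entry.
#' @param last last occasion entering the likelihood (default `length(y)`).
#' @export
loglikHistory <- function(y, params, f = which(y > 0)[1L],
                          last = length(y)) {
  validObject(params)
  y <- as.integer(y)
  if (is.na(f) || y[f] < 1L) stop("malformed history: y[f] must be >= 1")
  pw <- .msForwardLoglik(matrix(y, nrow = 1L), as.integer(f),
                         as.integer(last), params@phi, params@alpha,
                         params@p)
  pw[[1L]]
}
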