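logColSumExp <- function(m) {
  mx <- apply(m, 2, max)
  mx + log(colSums(exp(sweep(m, 2, mx))))
}

#' Widely applicable information criterion
#'
#' Computes WAIC from a pointwise log-likelihood matrix (rows = posterior
#' draws, columns = data points): `lppd = sum_k log mean_s exp(ll[s,k])`
#' evaluated stably via log-sum-exp, the effective number of parameters
#' as either the variance form `pWaic2 = sum_k var_s(ll[s,k])` (sample
#' variance, denominator S-1; the default) or the mean-based form
#' `pWaic1 = 2 sum_k (log mean exp - mean)`, and
#' `waic = -2 (lppd - pWaic)`.
#'
#' @param logLik S x n numeric matrix of pointwise log-likelihoods, or a
#'   [PosteriorDraws-class] (its stored matrix is used).
#' @param variant `"variance"` (default) or `"mean"`.
#' @return a [WAICResult-class].
#' @examples
#' ll <- matrix(log(c(0.5, 0.25)), nrow = 2)
#' computeWAIC(ll)   # lppd = log 0.375
#' @export
computeWAIC <- function(logLik, variant = c("variance", "mean")) {
  variant <- match.arg(variant)
  if (is(logLik, "PosteriorDraws")) logLik <- pointwiseLogLik(logLik)
  logLik <- as.matrix(logLik)
  if (nrow(logLik) < 2L)
    stop("need at least 2 posterior draws to compute WAIC")
  if (ncol(logLik) < 1L) stop("need at least one data point")
  if (!all(is.finite(logLik)))
    stop("pointwise log-likelihood contains non-finite entries")
  S <- nrow(logLik)
  pointLppd <- logColSumExp(logLik) - log(S)
  pointP <- if (variant == "variance") {
    apply(logLik, 2, stats::var)
  } else {
    2 * (pointLppd - colMeans(logLik))
  }
  lppd <- sum(pointLppd); pWaic <- sum(pointP)
  new("WAICResult", lppd = lppd, pWaic = pWaic,
      waic = -2 * (lppd - pWaic), nPoints = ncol(logLik),
      pointwiseLppd = pointLppd, pointwisePWaic = pointP)
}

#' Compare models by WAIC
#'
#' Differences from the best (lowest-WAIC) model and Akaike-style
#' weights `exp(-dWAIC/2) / sum exp(-dWAIC/2)`, sorted ascending by
#' dWAIC.  All models must score the same data points.
#'
#' @param results named list of [WAICResult-class] objects (names become
#'   the `model` column).
#' @return `data.frame` with columns `model`, `waic`, `lppd`, `p_waic`,
#'   `dWAIC`, `weight`; the best model has `dWAIC = 0` and weights sum
#'   to 1.
#' @examples
#' ll <- matrix(rnorm(20), 10, 2)
#' compareModels(list(a = computeWAIC(ll), b = computeWAIC(ll + 0.1)))
#' @export
compareModels <- function(results) {
  if (length(results) < 2L) stop("need at least two models to compare")
  n <- vapply(results, function(r) r@nPoints, integer(1))
  if (length(unique(n)) != 1L)
    stop("models score different numbers of data points: ",
         paste(n, collapse = ", "))
  if (is.null(names(results)))
    names(results) <- paste0("model", seq_along(results))
  waic <- vapply(results, function(r) r@waic, numeric(1))
  d <- waic - min(waic)
  w <- exp(-0.5 * d)
  w <- w / sum(w)
  out <- data.frame(
    model = names(results), waic = waic,
    lppd = vapply(results, function(r) r@lppd, numeric(1)),
    p_waic = vapply(results, function(r) r@pWaic, numeric(1)),
    dWAIC = d, weight = w, stringsAsFactors = FALSE
  )
  out <- out[order(out$dWAIC), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Posterior contrast between two sets of draws
#'
#' Estimates `P(A > B)` by pairing draws (the shorter vector is resampled
#' with replacement to the longer length); ties count one half, so
#' identical samples give exactly 0.5.  Also reports the median and the
#' central 95% interval of the paired difference A - B.
#'
#' @param samplesA,samplesB numeric vectors of posterior draws.
#' @return list with `pAgtB`, `median`, `lower95`, `upper95`, `n`.
#' @export
posteriorContrast <- function(samplesA, samplesB) {
  if (!length(samplesA) || !length(samplesB))
    stop("both sample vectors must be nonempty")
  n <- max(length(samplesA), length(samplesB))
  if (length(samplesA) < n)
    samplesA <- sample(samplesA, n, replace = TRUE)
  if (length(samplesB) < n)
    samplesB <- sample(samplesB, n, replace = TRUE)
  diff <- samplesA - samplesB
  p <- (sum(diff > 0) + 0.5 * sum(diff == 0)) / n
  q <- stats::quantile(diff, c(0.025, 0.5, 0.975), names = FALSE)
  list(pAgtB = p, median = q[2L], lower95 = q[1L], upper95 = q[3L], n = n)
}

#' Read a pointwise log-likelihood CSV / write a comparison table
#'
#' The CSV dialect: rows = draws, columns = data points, header row.
#'
#' @param path CSV path.
#' @return `readPointwiseLogLik()` returns a numeric matrix.
#' @export
readPointwiseLogLik <- function(path) {
  as.matrix(utils::read.csv(path, check.names = FALSE))
}

#' @rdname readPointwiseLogLik
#' @param comparison `data.frame` from [compareModels()].
#' @export
writeComparison <- function(comparison, path) {
  utils::write.csv(comparison, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
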