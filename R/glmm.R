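#' Encode the fire condition of every tree-occasion cell
#'
#' Three-level condition driving the abundance models: `baseline` (no
#' 2021 fire, or before a tree's burn), `post_0_6wk` (within the 6-week
#' post-fire window) and `post_6pluswk` (6+ weeks after the burn).  The
#' default window is half-open `[0, 42)` days from the burn date with the
#' burn day itself counted as post-fire (frogs were in pipes the day
#' after fire); `boundary = "closed"` switches to `[0, 42]`.
#'
#' @param design a [SamplingDesign-class].
#' @param windowDays length of the early post-fire window (default 42).
#' @param boundary `"half_open"` (default) or `"closed"`.
#' @return character matrix (trees x occasions) with the three levels;
#'   rownames are tree ids.
#' @examples
#' cond <- encodeFireCondition(fireStudyDesign())
#' table(cond)
#' @export
encodeFireCondition <- function(design, windowDays = 42,
                                boundary = c("half_open", "closed")) {
  boundary <- match.arg(boundary)
  tr <- studyTrees(design)
  occ <- occasions(design)
  cond <- matrix("baseline", nrow(tr), length(occ),
                 dimnames = list(tr$tree_id, NULL))
  for (j in seq_len(nrow(tr))) {
    if (tr$treatment[j] != "fire_2021") next
    if (is.na(tr$burn_date[j]))
      stop("fire_2021 tree '", tr$tree_id[j], "' has no burn date")
    d <- as.numeric(occ - tr$burn_date[j])
    early <- if (boundary == "half_open") d >= 0 & d < windowDays else
      d >= 0 & d <= windowDays
    late <- if (boundary == "half_open") d >= windowDays else d > windowDays
    cond[j, early] <- "post_0_6wk"
    cond[j, late] <- "post_6pluswk"
  }
  cond
}

#' Abundance model specification
#'
#' The three candidate models of per-tree, per-occasion frog counts:
#' `FIRE_TIME_TREE` (fire-condition fixed effect plus time and tree
#' random effects), `TIME_TREE` (intercept plus the two random effects)
#' and `NULL_MEAN` (a single mean).  `response` selects new-frog counts
#' (first detections) or total counts.
#'
#' @param model one of `"FIRE_TIME_TREE"`, `"TIME_TREE"`, `"NULL_MEAN"`.
#' @param response `"new"` or `"total"`.
#' @return list of class `model_spec`.
#' @export
modelSpec <- function(model = c("FIRE_TIME_TREE", "TIME_TREE", "NULL_MEAN"),
                      response = c("new", "total")) {
  structure(list(model = match.arg(model), response = match.arg(response)),
            class = "model_spec")
}

#' Hyperpriors for the abundance models
#'
#' Declared defaults: fixed effects `beta ~ Normal(0, betaSd^2)` on the
#' log scale and random-effect standard deviations
#' `sigma ~ Half-Normal(0, sigmaScale)`.
#'
#' @param betaSd prior sd of the log-scale fixed effects (default 10).
#' @param sigmaScale scale of the half-Normal prior on sigmas (default 2).
#' @return a list of class `abundance_priors`.
#' @export
abundancePriors <- function(betaSd = 10, sigmaScale = 2) {
  structure(list(betaSd = betaSd, sigmaScale = sigmaScale),
            class = "abundance_priors")
}

fireLevels <- c("baseline", "post_0_6wk", "post_6pluswk")

# linear predictor matrix (J x T) for natural-scale params
glmmEta <- function(params, spec, cond, J, T) {
  eta <- matrix(0, J, T)
  if (spec$model == "FIRE_TIME_TREE") {
    b <- params$beta[match(cond, fireLevels)]
    eta <- matrix(b, J, T)
  } else {
    eta <- eta + params$beta[1L]
  }
  if (spec$model != "NULL_MEAN") {
    eta <- eta + rep(params$gamma, each = J) + params$delta
  }
  eta
}

#' Log-posterior of an abundance model
#'
#' Sum of Poisson log-probabilities of the selected counts at
#' `lambda = exp(eta)` with `eta = beta[condition] + gamma_i + delta_j`
#' (terms per the model spec), plus the Normal log-densities of the
#' random effects given their sds and the hyperpriors on `beta` and the
#' sds.  Finite for any valid parameter values.
#'
#' @param table an [AbundanceTable-class].
#' @param params list with `beta` (length 3 for `FIRE_TIME_TREE`, else 1),
#'   `gamma` (length T), `delta` (length J), `sigmaGamma`, `sigmaDelta`.
#' @param spec a [modelSpec()].
#' @param cond fire-condition matrix from [encodeFireCondition()]
#'   (required for `FIRE_TIME_TREE`).
#' @param priors an [abundancePriors()].
#' @return the log-posterior density (unnormalized).
#' @export
abundanceLogPosterior <- function(table, params, spec, cond = NULL,
                                  priors = abundancePriors()) {
  counts <- if (spec$response == "new") newCounts(table) else
    totalCounts(table)
  if (anyNA(counts) || any(counts < 0))
    stop("counts must be nonnegative and non-missing")
  J <- nrow(counts); T <- ncol(counts)
  if (spec$model == "FIRE_TIME_TREE" && is.null(cond))
    stop("FIRE_TIME_TREE requires a fire-condition matrix")
  eta <- glmmEta(params, spec, cond, J, T)
  lp <- sum(stats::dpois(counts, exp(eta), log = TRUE)) +
    sum(stats::dnorm(params$beta, 0, priors$betaSd, log = TRUE))
  if (spec$model != "NULL_MEAN") {
    lp <- lp +
      sum(stats::dnorm(params$gamma, 0, params$sigmaGamma, log = TRUE)) +
      sum(stats::dnorm(params$delta, 0, params$sigmaDelta, log = TRUE)) +
      stats::dnorm(params$sigmaGamma, 0, priors$sigmaScale, log = TRUE) +
      log(2) +
      stats::dnorm(params$sigmaDelta, 0, priors$sigmaScale, log = TRUE) +
      log(2)
  }
  lp
}

glmmNpar <- function(spec, J, T) {
  if (spec$model == "FIRE_TIME_TREE") 3L + T + J + 2L
  else if (spec$model == "TIME_TREE") 1L + T + J + 2L
  else 1L
}

# The sampler works in a non-centered parameterization: raw effects
# u ~ Normal(0, 1) with gamma = sigmaGamma * u (and likewise delta),
# which removes the funnel between effects and their sd when the data
# carry little information per effect.  theta = (beta, uGamma, uDelta,
# log sigmaGamma, log sigmaDelta).
glmmThetaToParams <- function(theta, spec, J, T) {
  nb <- if (spec$model == "FIRE_TIME_TREE") 3L else 1L
  if (spec$model == "NULL_MEAN")
    return(list(beta = theta[1L], gamma = NULL, delta = NULL,
                sigmaGamma = NULL, sigmaDelta = NULL))
  sg <- exp(theta[nb + T + J + 1L])
  sd_ <- exp(theta[nb + T + J + 2L])
  uG <- theta[nb + seq_len(T)]
  uD <- theta[nb + T + seq_len(J)]
  list(beta = theta[seq_len(nb)], uGamma = uG, uDelta = uD,
       gamma = sg * uG, delta = sd_ * uD,
       sigmaGamma = sg, sigmaDelta = sd_)
}

glmmParNames <- function(spec, table) {
  J <- nrow(table); T <- ncol(table)
  if (spec$model == "NULL_MEAN") return("beta_mean")
  bn <- if (spec$model == "FIRE_TIME_TREE")
    paste0("beta_", fireLevels) else "beta_mean"
  c(bn, paste0("gamma_", seq_len(T)),
    paste0("delta_", rownames(newCounts(table))),
    "sigma_gamma", "sigma_delta")
}

#' Fit an abundance model by MCMC
#'
#' Samples the posterior of the selected Poisson mixed model with the
#' component-wise adaptive Metropolis sampler (random-effect sds on the
#' log scale with Jacobian).  Random effects are sampled, not
#' marginalized; the pointwise log-likelihood stored for WAIC is the
#' conditional Poisson term of each (tree, occasion) cell given the
#' sampled effects.
#'
#' @param table an [AbundanceTable-class].
#' @param spec a [modelSpec()].
#' @param cond fire-condition matrix (required for `FIRE_TIME_TREE`).
#' @param priors an [abundancePriors()].
#' @param control an [mcmcControl()].
#' @return a [PosteriorDraws-class]; `pointwiseLogLik()` has one column
#'   per (tree, occasion) cell, column order tree-fastest.
#' @export
fitAbundance <- function(table, spec, cond = NULL,
                         priors = abundancePriors(),
                         control = mcmcControl()) {
  counts <- if (spec$response == "new") newCounts(table) else
    totalCounts(table)
  J <- nrow(counts); T <- ncol(counts)
  if (spec$model == "FIRE_TIME_TREE") {
    if (is.null(cond)) stop("FIRE_TIME_TREE requires a fire-condition matrix")
    present <- fireLevels %in% cond
    if (!all(present))
      warning("condition level(s) ", paste(fireLevels[!present],
              collapse = ", "), " absent from the design; their beta is ",
              "prior-only", call. = FALSE)
  }
  npar <- glmmNpar(spec, J, T)
  # precomputed index vectors make the sampler's log-posterior cheap; it
  # matches abundanceLogPosterior() up to the count-factorial constant
  cnt <- as.vector(counts)
  ci <- if (spec$model == "FIRE_TIME_TREE") match(as.vector(cond),
                                                 fireLevels)
  iOcc <- rep(seq_len(T), each = J)
  jTree <- rep(seq_len(J), times = T)
  logPost <- function(theta) {
    pl <- glmmThetaToParams(theta, spec, J, T)
    eta <- if (spec$model == "FIRE_TIME_TREE") pl$beta[ci] else
      rep(pl$beta[1L], J * T)
    if (spec$model != "NULL_MEAN")
      eta <- eta + pl$gamma[iOcc] + pl$delta[jTree]
    lp <- sum(cnt * eta - exp(eta)) +
      sum(stats::dnorm(pl$beta, 0, priors$betaSd, log = TRUE))
    if (spec$model != "NULL_MEAN") {
      lp <- lp +
        sum(stats::dnorm(pl$uGamma, log = TRUE)) +
        sum(stats::dnorm(pl$uDelta, log = TRUE)) +
        stats::dnorm(pl$sigmaGamma, 0, priors$sigmaScale, log = TRUE) +
        stats::dnorm(pl$sigmaDelta, 0, priors$sigmaScale, log = TRUE) +
        log(pl$sigmaGamma) + log(pl$sigmaDelta)   # log-sd Jacobian
    }
    if (!is.finite(lp)) -Inf else lp
  }
  meanLog <- log(mean(counts) + 0.1)
  init <- function(chain) {
    th <- stats::rnorm(npar, 0, 0.3)
    nb <- if (spec$model == "FIRE_TIME_TREE") 3L else 1L
    th[seq_len(nb)] <- meanLog + stats::rnorm(nb, 0, 0.5)
    th
  }
  run <- runAdaptiveMH(logPost, init, npar, control,
                       parNames = glmmParNames(spec, table),
                       method = "componentwise")
  draws <- run$draws
  if (spec$model != "NULL_MEAN") {
    # back to the natural scale: effects = sigma * u, sigma = exp(log sigma)
    nb <- if (spec$model == "FIRE_TIME_TREE") 3L else 1L
    sgCol <- nb + T + J + 1L; sdCol <- nb + T + J + 2L
    draws[, sgCol] <- exp(draws[, sgCol])
    draws[, sdCol] <- exp(draws[, sdCol])
    draws[, nb + seq_len(T)] <- draws[, nb + seq_len(T)] * draws[, sgCol]
    draws[, nb + T + seq_len(J)] <- draws[, nb + T + seq_len(J)] *
      draws[, sdCol]
  }
  S <- nrow(draws)
  ll <- matrix(NA_real_, S, J * T)
  colnames(ll) <- paste0(rep(rownames(counts), times = T), ":occ",
                         rep(seq_len(T), each = J))
  for (s in seq_len(S)) {
    pl <- glmmThetaToParams(run$draws[s, ], spec, J, T)
    eta <- if (spec$model == "FIRE_TIME_TREE") pl$beta[ci] else
      rep(pl$beta[1L], J * T)
    if (spec$model != "NULL_MEAN")
      eta <- eta + pl$gamma[iOcc] + pl$delta[jTree]
    ll[s, ] <- stats::dpois(cnt, exp(eta), log = TRUE)
  }
  diag <- diagnosticsTable(draws, run$chain, warnContext = "fitAbundance")
  new("PosteriorDraws", draws = draws, chain = as.integer(run$chain),
      logLik = ll, diagnostics = diag,
      model = paste0("abundance_", spec$model),
      info = list(spec = unclass(spec), J = J, T = T,
                  trees = rownames(counts), seed = control$seed,
                  chains = control$chains, iter = control$iter,
                  warmup = control$warmup))
}

#' Posterior predictive density of expected new frogs per tree-occasion
#'
#' For each retained draw of a `FIRE_TIME_TREE` fit, draws fresh random
#' effects `gamma* ~ Normal(0, sigma_gamma)` and
#' `delta* ~ Normal(0, sigma_delta)` and emits
#' `lambda* = exp(beta_category + gamma* + delta*)`: the predictive
#' distribution of the expected count in a new tree at a new occasion
#' under the requested fire condition.
#'
#' @param fit a [PosteriorDraws-class] from [fitAbundance()] of a
#'   `FIRE_TIME_TREE` model.
#' @param category one of `baseline`, `post_0_6wk`, `post_6pluswk`.
#' @param gridN number of grid points of the kernel-density export.
#' @return list with `samples` (one lambda* per retained draw) and
#'   `density` (`data.frame` with columns `x`, `density`).
#' @export
posteriorPredictiveDensity <- function(fit, category, gridN = 512L) {
  d <- drawsMatrix(fit)
  col <- paste0("beta_", category)
  if (!col %in% colnames(d))
    stop("category '", category, "' is not part of the fitted model")
  beta <- d[, col]
  lam <- if (all(c("sigma_gamma", "sigma_delta") %in% colnames(d))) {
    exp(beta + stats::rnorm(length(beta), 0, d[, "sigma_gamma"]) +
          stats::rnorm(length(beta), 0, d[, "sigma_delta"]))
  } else {
    exp(beta)
  }
  dens <- stats::density(lam, n = gridN, from = 0)
  list(samples = lam,
       density = data.frame(x = dens$x, density = dens$y))
}
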