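#' MCMC controls
#'
#' Settings shared by the multistate and abundance samplers: a
#' component-wise adaptive random-walk Metropolis on unconstrained
#' parameter scales.  Proposal scales adapt toward a 44% acceptance rate
#' (the component-wise optimum) in batches during warmup and are frozen
#' afterwards, so retained draws target the exact posterior.
#'
#' @param chains number of chains (>= 4 unless explicitly overridden;
#'   fewer chains trigger a message, not an error).
#' @param iter retained draws per chain (after thinning).
#' @param warmup adaptation iterations per chain (discarded); split
#'   between a component-wise scale-finding phase and a joint
#'   covariance-adaptation phase.
#' @param thin keep every `thin`-th post-warmup iteration.
#' @param seed integer seed; chain c uses `seed + 1000 * (c - 1)`.
#' @return a list of class `mcmc_control`.
#' @export
mcmcControl <- function(chains = 4L, iter = 1000L, warmup = 1000L,
                        thin = 1L, seed = 1L) {
  if (chains < 4L)
    message("running fewer than 4 chains (explicit override)")
  structure(list(chains = as.integer(chains), iter = as.integer(iter),
                 warmup = as.integer(warmup), thin = as.integer(thin),
                 seed = as.integer(seed)),
            class = "mcmc_control")
}

# Adaptive random-walk Metropolis: a component-wise scale-finding warmup
# phase followed by joint multivariate-normal proposals whose covariance
# adapts to the empirical posterior covariance (Haario-style) for the
# rest of warmup; adaptation is frozen for the retained draws, so they
# target the exact posterior.
#
# logPost(theta) must return a finite value or -Inf (never NaN).
# init(chain) returns the (dispersed) initial unconstrained vector.
# Returns list(draws, chain): draws is (chains * iter) x npar.
runAdaptiveMH <- function(logPost, init, npar, control,
                          parNames = NULL,
                          method = c("mixed", "componentwise")) {
  method <- match.arg(method)
  stopifnot(inherits(control, "mcmc_control"))
  allDraws <- vector("list", control$chains)
  cwIter <- if (method == "componentwise") control$warmup else
    max(50L, control$warmup %/% 3L)               # component-wise phase
  jointWarm <- control$warmup - cwIter
  for (cc in seq_len(control$chains)) {
    set.seed(control$seed + 1000L * (cc - 1L))
    theta <- init(cc)
    stopifnot(length(theta) == npar)
    lp <- logPost(theta)
    if (!is.finite(lp))
      stop("initial value has zero posterior density (chain ", cc, ")")

    # phase 1: per-coordinate random walk, scales adapted toward 0.44
    ls <- rep(-1, npar)
    accBatch <- rep(0, npar); batch <- 0L
    hist1 <- matrix(NA_real_, cwIter, npar)
    for (it in seq_len(cwIter)) {
      for (j in seq_len(npar)) {
        prop <- theta
        prop[j] <- theta[j] + exp(ls[j]) * stats::rnorm(1L)
        lpp <- logPost(prop)
        if (is.finite(lpp) && log(stats::runif(1L)) < lpp - lp) {
          theta <- prop; lp <- lpp
          accBatch[j] <- accBatch[j] + 1
        }
      }
      if (it %% 25L == 0L) {
        batch <- batch + 1L
        delta <- min(0.25, batch^-0.5)
        ls <- ls + ifelse(accBatch / 25 > 0.44, delta, -delta)
        accBatch[] <- 0
      }
      hist1[it, ] <- theta
    }

    if (method == "componentwise") {
      # sampling with frozen per-coordinate scales
      keep <- matrix(NA_real_, control$iter, npar)
      kept <- 0L
      for (it in seq_len(control$iter * control$thin)) {
        for (j in seq_len(npar)) {
          prop <- theta
          prop[j] <- theta[j] + exp(ls[j]) * stats::rnorm(1L)
          lpp <- logPost(prop)
          if (is.finite(lpp) && log(stats::runif(1L)) < lpp - lp) {
            theta <- prop; lp <- lpp
          }
        }
        if (it %% control$thin == 0L) {
          kept <- kept + 1L
          keep[kept, ] <- theta
        }
      }
      allDraws[[cc]] <- keep
      next
    }

    # phase 2: joint proposals, covariance adapted from the running draws
    half <- hist1[seq(cwIter %/% 2L + 1L, cwIter), , drop = FALSE]
    mu <- colMeans(half)
    cv <- stats::cov(half)
    if (npar == 1L) cv <- matrix(max(cv, 1e-8), 1L, 1L)
    lsc <- 0   # log of the global scale multiplier
    nseen <- nrow(half)
    base <- 2.38^2 / npar
    chol_S <- tryCatch(chol(base * cv + diag(1e-9, npar)),
                       error = function(e) diag(sqrt(base) * exp(ls)))
    for (it in seq_len(jointWarm)) {
      prop <- theta + exp(lsc / 2) * drop(stats::rnorm(npar) %*% chol_S)
      lpp <- logPost(prop)
      acc <- is.finite(lpp) && log(stats::runif(1L)) < lpp - lp
      if (acc) { theta <- prop; lp <- lpp }
      gam <- min(0.1, 5 / sqrt(it))
      lsc <- lsc + gam * ((if (acc) 1 else 0) - 0.234)
      # recursive mean/covariance update
      nseen <- nseen + 1L
      dlt <- theta - mu
      mu <- mu + dlt / nseen
      cv <- cv * (nseen - 2L) / (nseen - 1L) + tcrossprod(dlt) / nseen
      if (it %% 100L == 0L)
        chol_S <- tryCatch(chol(base * cv + diag(1e-9, npar)),
                           error = function(e) chol_S)
    }

    # sampling with frozen proposal
    chol_S <- exp(lsc / 2) * chol_S
    keep <- matrix(NA_real_, control$iter, npar)
    kept <- 0L
    for (it in seq_len(control$iter * control$thin)) {
      prop <- theta + drop(stats::rnorm(npar) %*% chol_S)
      lpp <- logPost(prop)
      if (is.finite(lpp) && log(stats::runif(1L)) < lpp - lp) {
        theta <- prop; lp <- lpp
      }
      if (it %% control$thin == 0L) {
        kept <- kept + 1L
        keep[kept, ] <- theta
      }
    }
    allDraws[[cc]] <- keep
  }
  draws <- do.call(rbind, allDraws)
  if (!is.null(parNames)) colnames(draws) <- parNames
  list(draws = draws,
       chain = rep(seq_len(control$chains), each = control$iter))
}

#' Split R-hat and effective sample size
#'
#' Standard convergence diagnostics computed from retained draws: each
#' chain is split in half, the potential scale reduction factor compares
#' between- and within-half variances, and the effective sample size uses
#' the multi-chain autocorrelation estimate with Geyer's initial monotone
#' positive sequence truncation.
#'
#' @param x numeric vector of stacked draws for one parameter.
#' @param chain integer chain id per draw.
#' @return `splitRhat()`/`effectiveSize()` return a single number.
#' @export
splitRhat <- function(x, chain) {
  halves <- splitChains(x, chain)
  n <- nrow(halves); m <- ncol(halves)
  if (n < 4L) return(NA_real_)
  mu <- colMeans(halves)
  s2 <- apply(halves, 2, stats::var)
  W <- mean(s2)
  B <- n * stats::var(mu)
  if (W <= 0) return(1)
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' @rdname splitRhat
#' @export
effectiveSize <- function(x, chain) {
  halves <- splitChains(x, chain)
  n <- nrow(halves); m <- ncol(halves)
  if (n < 4L) return(NA_real_)
  s2 <- apply(halves, 2, stats::var)
  W <- mean(s2)
  B <- n * stats::var(colMeans(halves))
  varplus <- (n - 1) / n * W + B / n
  if (varplus <= 0) return(n * m)
  lagMax <- n - 2L
  acov <- vapply(seq_len(m), function(j) {
    a <- stats::acf(halves[, j], lag.max = lagMax, type = "covariance",
                    plot = FALSE, demean = TRUE)$acf[, 1, 1]
    a
  }, numeric(lagMax + 1L))
  rho <- 1 - (W - rowMeans(acov)) / varplus
  rho[1L] <- 1
  # Geyer initial monotone positive sequence on paired sums
  npair <- (length(rho) - 1L) %/% 2L
  tau <- 0; prevPair <- Inf
  if (npair >= 1L) {
    for (k in seq_len(npair)) {
      pair <- rho[2L * k] + rho[2L * k + 1L]
      if (pair < 0) break
      pair <- min(pair, prevPair)
      tau <- tau + pair
      prevPair <- pair
    }
  }
  ess <- n * m / (1 + 2 * tau)
  min(ess, n * m)
}

splitChains <- function(x, chain) {
  ids <- unique(chain)
  pieces <- list()
  for (cc in ids) {
    xi <- x[chain == cc]
    h <- length(xi) %/% 2L
    pieces <- c(pieces, list(xi[seq_len(h)], xi[h + seq_len(h)]))
  }
  len <- min(lengths(pieces))
  vapply(pieces, function(p) p[seq_len(len)], numeric(len))
}

# Per-parameter diagnostics table with the convergence gate.
diagnosticsTable <- function(draws, chain, rhatGate = 1.05, essGate = 400,
                             warnContext = "sampler") {
  tab <- data.frame(
    parameter = colnames(draws),
    rhat = vapply(seq_len(ncol(draws)),
                  function(j) splitRhat(draws[, j], chain), numeric(1)),
    ess = vapply(seq_len(ncol(draws)),
                 function(j) effectiveSize(draws[, j], chain), numeric(1)),
    stringsAsFactors = FALSE
  )
  degenerate <- apply(draws, 2, function(v) stats::sd(v) < 1e-12)
  tab$rhat[degenerate] <- 1
  tab$ess[degenerate] <- nrow(draws)
  bad <- tab$rhat > rhatGate | tab$ess < essGate
  if (any(bad, na.rm = TRUE))
    warning(warnContext, ": convergence gate failed for ",
            paste(tab$parameter[which(bad)], collapse = ", "),
            " (split R-hat > ", rhatGate, " or ESS < ", essGate, ")",
            call. = FALSE)
  tab
}
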