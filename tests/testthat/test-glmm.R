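test_that("fire-condition encoding follows the 6-week half-open window", {
  d <- fireStudyDesign()
  cond <- encodeFireCondition(d)
  # reference trees are baseline throughout
  ref <- studyTrees(d)$treatment == "reference"
  expect_true(all(cond[ref, ] == "baseline"))
  # April-burn tree: burn day is post-fire, 14 and 28 days in the early
  # window, 42 days (half-open boundary) already 6+
  occ <- occasions(d)
  j <- which(studyTrees(d)$tree_id == "4-1")
  b <- as.Date("2021-04-16")
  expect_equal(unname(cond[j, occ == b]), "post_0_6wk")
  expect_equal(unname(cond[j, occ == b + 14]), "post_0_6wk")
  expect_equal(unname(cond[j, occ == b + 42]), "post_6pluswk")
  expect_equal(unname(cond[j, occ == b - 14]), "baseline")
  # closed boundary keeps day 42 in the early window
  cc <- encodeFireCondition(d, boundary = "closed")
  expect_equal(unname(cc[j, occ == b + 42]), "post_0_6wk")
  # all six burned trees experience the early window
  everEarly <- rownames(cond)[apply(cond == "post_0_6wk", 1, any)]
  expect_equal(sort(everEarly), sort(studyTrees(d)$tree_id[!ref]))
  # the April-burn unit carries nearly all the 6+ weeks exposure: its
  # trees have 8 such occasions, the July-burn trees only reach 44 days
  # post-burn at the final occasion
  late <- rowSums(cond == "post_6pluswk")
  expect_equal(unname(late[paste0("4-", 1:3)]), rep(8, 3))
  expect_equal(unname(late[paste0("SW-", 1:3)]), rep(1, 3))
  # a fire tree without a burn date is rejected at design construction
  tr <- studyTrees(d); tr$burn_date[tr$tree_id == "4-1"] <- NA
  expect_error(SamplingDesign(occasions(d), tr, heightLabels(d)),
               "must have a burn_date")
})

test_that("log-posterior matches an independently coded sum of densities", {
  d <- tinyDesign(T = 4L, H = 2L)
  set.seed(21)
  nw <- matrix(rpois(8, 2), 2, 4, dimnames = list(c("R1", "F1"), NULL))
  tab <- newAbundanceTable(nw, nw + rpois(8, 1), d)
  cond <- encodeFireCondition(d)
  pr <- abundancePriors()
  params <- list(beta = c(0.1, 0.5, -0.2), gamma = rnorm(4, 0, 0.3),
                 delta = rnorm(2, 0, 0.3), sigmaGamma = 0.4,
                 sigmaDelta = 0.6)
  got <- abundanceLogPosterior(tab, params, modelSpec("FIRE_TIME_TREE"),
                               cond, pr)
  # oracle: loop over cells and parameters term by term
  lev <- c("baseline", "post_0_6wk", "post_6pluswk")
  want <- 0
  for (j in 1:2) for (i in 1:4) {
    eta <- params$beta[match(cond[j, i], lev)] + params$gamma[i] +
      params$delta[j]
    want <- want + dpois(nw[j, i], exp(eta), log = TRUE)
  }
  for (b in params$beta) want <- want + dnorm(b, 0, 10, log = TRUE)
  for (g in params$gamma) want <- want + dnorm(g, 0, 0.4, log = TRUE)
  for (dd in params$delta) want <- want + dnorm(dd, 0, 0.6, log = TRUE)
  want <- want + dnorm(0.4, 0, 2, log = TRUE) + log(2) +
    dnorm(0.6, 0, 2, log = TRUE) + log(2)
  expect_equal(got, unname(want), tolerance = 1e-10)
})

test_that("a NULL_MEAN cell has the closed-form Poisson log-mass", {
  d <- tinyDesign(T = 2L, H = 2L)
  nw <- matrix(c(2L, 0L, 0L, 0L), 2, 2, dimnames = list(c("R1", "F1"), NULL))
  tab <- newAbundanceTable(nw, nw, d)
  params <- list(beta = log(2), gamma = NULL, delta = NULL,
                 sigmaGamma = NULL, sigmaDelta = NULL)
  got <- abundanceLogPosterior(tab, params, modelSpec("NULL_MEAN"))
  # Poisson(2; lambda=2) = 2 log 2 - 2 - log 2! plus three zero cells
  # (-2 each) plus the beta prior
  want <- (2 * log(2) - 2 - log(2)) + 3 * (-2) +
    dnorm(log(2), 0, 10, log = TRUE)
  expect_equal(got, want, tolerance = 1e-10)
  expect_equal(2 * log(2) - 2 - log(2), -1.3069, tolerance = 1e-4)

  # adding an all-zero occasion changes the likelihood by -sum(lambda)
  nw2 <- cbind(nw, c(0L, 0L))
  d3 <- tinyDesign(T = 3L, H = 2L)
  tab2 <- newAbundanceTable(nw2, nw2, d3)
  got2 <- abundanceLogPosterior(tab2, params, modelSpec("NULL_MEAN"))
  expect_equal(got2 - got, -2 * 2, tolerance = 1e-10)
})

test_that("NULL_MEAN posterior matches the conjugate Gamma-Poisson oracle", {
  d <- fireStudyDesign()
  set.seed(77)
  nw <- matrix(rpois(12 * 14, 3), 12, 14,
               dimnames = list(studyTrees(d)$tree_id, NULL))
  tab <- newAbundanceTable(nw, nw, d)
  fit <- quietFit(fitAbundance(tab, modelSpec("NULL_MEAN"),
                               control = mcmcControl(chains = 4,
                                                     iter = 1500,
                                                     warmup = 600,
                                                     seed = 5)))
  lam <- exp(drawsMatrix(fit)[, "beta_mean"])
  # flat prior on log lambda -> posterior ~ Gamma(sum y, n)
  shape <- sum(nw); rate <- length(nw)
  expect_lt(abs(mean(lam) - shape / rate), 0.3)
  expect_lt(abs(mean(lam) - shape / rate), 4 * sqrt(shape) / rate /
              sqrt(min(mcmcDiagnostics(fit)$ess)))
  qs <- quantile(lam, c(0.1, 0.5, 0.9))
  expect_lt(max(abs(qs - qgamma(c(0.1, 0.5, 0.9), shape, rate))), 0.08)
})

test_that("an all-zero table drives the mean to zero", {
  d <- tinyDesign(T = 4L, H = 2L)
  z <- matrix(0L, 2, 4, dimnames = list(c("R1", "F1"), NULL))
  tab <- newAbundanceTable(z, z, d)
  fit <- quietFit(fitAbundance(tab, modelSpec("NULL_MEAN"),
                               control = mcmcControl(chains = 4,
                                                     iter = 800,
                                                     warmup = 500,
                                                     seed = 2)))
  lam <- exp(drawsMatrix(fit)[, "beta_mean"])
  expect_lt(quantile(lam, 0.975), 0.5)
})

test_that("NULL_MEAN log-posterior is invariant to tree relabeling", {
  d <- fireStudyDesign()
  set.seed(13)
  nw <- matrix(rpois(12 * 14, 2), 12, 14,
               dimnames = list(studyTrees(d)$tree_id, NULL))
  tab <- newAbundanceTable(nw, nw, d)
  perm <- sample(12)
  tabP <- newAbundanceTable(nw[perm, ], nw[perm, ], d)
  params <- list(beta = 0.4, gamma = NULL, delta = NULL,
                 sigmaGamma = NULL, sigmaDelta = NULL)
  expect_equal(abundanceLogPosterior(tabP, params, modelSpec("NULL_MEAN")),
               abundanceLogPosterior(tab, params, modelSpec("NULL_MEAN")),
               tolerance = 1e-12)
})

test_that("posterior predictive density transforms as the link dictates", {
  # hand-made draws: no random-effect spread collapses the density to
  # exp(beta); shifting beta by log 2 doubles every sample
  S <- 500L
  set.seed(3)
  beta <- rnorm(S, log(2), 0.1)
  draws <- cbind(beta_baseline = beta, beta_post_0_6wk = beta + 1,
                 beta_post_6pluswk = beta, sigma_gamma = rep(0, S),
                 sigma_delta = rep(0, S))
  fit <- new("PosteriorDraws", draws = draws,
             chain = rep(1:4, length.out = S),
             logLik = matrix(0, S, 1), diagnostics = data.frame(),
             model = "abundance_FIRE_TIME_TREE", info = list())
  pp <- posteriorPredictiveDensity(fit, "baseline")
  expect_equal(sort(pp$samples), sort(exp(beta)), tolerance = 1e-12)
  fit2 <- fit
  fit2@draws[, "beta_baseline"] <- beta + log(2)
  pp2 <- posteriorPredictiveDensity(fit2, "baseline")
  expect_equal(sort(pp2$samples), 2 * sort(exp(beta)), tolerance = 1e-12)
  expect_error(posteriorPredictiveDensity(fit, "nonsense"), "not part")
})
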