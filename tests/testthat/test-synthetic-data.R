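test_that("the canonical scenario reproduces the study skeleton deterministically", {
  sc <- fireStudyScenario(seed = 7)
  expect_equal(nOccasions(sc$design), 14L)
  expect_equal(nTrees(sc$design), 12L)
  expect_equal(nHeights(sc$design), 4L)
  # generating values sit inside the ranges the study reported
  for (p in sc$msParams) {
    expect_true(all(survivalProb(p) >= 0.62 & survivalProb(p) <= 0.91))
    expect_true(all(recaptureProb(p) >= 0.62 & recaptureProb(p) <= 0.88))
  }
  # same seed, byte-identical detection files
  sc2 <- fireStudyScenario(seed = 7)
  f1 <- file.path(tempdir(), "sim1.csv"); f2 <- file.path(tempdir(), "sim2.csv")
  writeDetections(sc$detections, sc$design, f1)
  writeDetections(sc2$detections, sc2$design, f2)
  expect_identical(readLines(f1), readLines(f2))
  # different seeds differ
  expect_false(identical(fireStudyScenario(seed = 8)$detections,
                         sc$detections))
})

test_that("perfect detection and survival reveal the truth exactly", {
  d <- tinyDesign(T = 4L, H = 3L)
  ideal <- MultistateParams(phi = rep(1, 3), alpha = diag(3), p = rep(1, 3))
  sim <- simulateDataset(
    d, list(reference = ideal, fire_2021 = ideal),
    EntryModel(betaTrue = c(baseline = log(2), post_0_6wk = log(2),
                            post_6pluswk = log(2)),
               sigmaGamma = 0, sigmaDelta = 0,
               initialHeightDist = rep(1 / 3, 3)),
    seed = 5)
  tr <- sim$truth
  expect_gt(nrow(tr$individuals), 0)
  # every entrant is detected at its entry height at every occasion
  for (k in seq_len(nrow(tr$individuals))) {
    id <- tr$individuals$individual_id[k]
    e <- tr$individuals$entry[k]
    det <- sim$detections[sim$detections$individual_id == id, ]
    expect_equal(sort(det$occasion), e:4)
    expect_true(all(det$height == tr$z[k, e]))
  }
})

test_that("zero survival means no individual is detected twice", {
  d <- tinyDesign(T = 5L, H = 3L)
  doomed <- MultistateParams(phi = rep(0, 3), alpha = matrix(1 / 3, 3, 3),
                             p = rep(0.8, 3))
  sim <- simulateDataset(
    d, list(reference = doomed, fire_2021 = doomed),
    EntryModel(betaTrue = c(baseline = log(3), post_0_6wk = log(3),
                            post_6pluswk = log(3)),
               sigmaGamma = 0, sigmaDelta = 0,
               initialHeightDist = rep(1 / 3, 3)),
    seed = 9)
  expect_true(all(table(sim$detections$individual_id) == 1L))
})

test_that("detection fraction matches the closed form at p = 0.5, phi = 1", {
  # immortal individuals present from occasion 1 of T = 3, detected each
  # occasion with p = 0.5: P(ever detected) = 1 - 0.5^3 = 0.875
  H <- 2L
  pars <- MultistateParams(phi = rep(1, H), alpha = diag(H),
                           p = rep(0.5, H))
  psi <- transitionMatrix(pars)
  set.seed(404)
  n <- 2000L
  detected <- 0L
  for (i in seq_len(n)) {
    hits <- stats::runif(3) < 0.5
    if (any(hits)) detected <- detected + 1L
  }
  phat <- detected / n
  se <- sqrt(0.875 * 0.125 / n)
  expect_lt(abs(phat - 0.875), 3 * se)

  # the generator agrees: all entrants at occasion 1 via a 1-occasion
  # burn-in design is awkward, so check via simulateHistories rejection
  # accounting: accepted histories / attempts ~ 0.875 is implicit in the
  # entry-conditional design; instead verify the generator's per-capture
  # detection rate directly
  d <- tinyDesign(T = 3L, H = 2L)
  sim <- simulateDataset(
    d, list(reference = pars, fire_2021 = pars),
    EntryModel(betaTrue = c(baseline = log(200), post_0_6wk = log(200),
                            post_6pluswk = log(200)),
               sigmaGamma = 0, sigmaDelta = 0,
               initialHeightDist = rep(0.5, 2)),
    seed = 31)
  tr <- sim$truth$individuals
  early <- tr[tr$entry == 1L, ]
  frac <- mean(early$detected)
  se2 <- sqrt(0.875 * 0.125 / nrow(early))
  expect_lt(abs(frac - 0.875), 3 * se2)
})

test_that("realized entries match exp(beta + gamma + delta) on average", {
  d <- tinyDesign(T = 4L, H = 2L)
  pars <- MultistateParams(phi = rep(0.8, 2), alpha = matrix(0.5, 2, 2),
                           p = rep(0.7, 2))
  em <- EntryModel(betaTrue = c(baseline = log(2), post_0_6wk = log(4),
                                post_6pluswk = log(2)),
                   sigmaGamma = 0.3, sigmaDelta = 0.3,
                   initialHeightDist = c(0.5, 0.5))
  totalObs <- 0; totalExp <- 0
  for (s in 1:40) {
    sim <- simulateDataset(d, list(reference = pars, fire_2021 = pars),
                           em, seed = 1000 + s)
    cond <- sim$truth$condition
    lam <- exp(em$betaTrue[match(cond, c("baseline", "post_0_6wk",
                                         "post_6pluswk"))] +
                 rep(sim$truth$gamma, each = 2) + sim$truth$delta)
    totalExp <- totalExp + sum(lam)
    totalObs <- totalObs + nrow(sim$truth$individuals)
  }
  # Poisson totals: 3 SE band around the conditional expectation
  expect_lt(abs(totalObs - totalExp), 3 * sqrt(totalExp))
})

test_that("raising survival does not decrease detections per individual", {
  d <- tinyDesign(T = 6L, H = 2L)
  em <- EntryModel(betaTrue = c(baseline = log(20), post_0_6wk = log(20),
                                post_6pluswk = log(20)),
                   sigmaGamma = 0, sigmaDelta = 0,
                   initialHeightDist = c(0.5, 0.5))
  mk <- function(phi) MultistateParams(phi = rep(phi, 2),
                                       alpha = matrix(0.5, 2, 2),
                                       p = rep(0.6, 2))
  rate <- function(phi, seed) {
    sim <- simulateDataset(d, list(reference = mk(phi), fire_2021 = mk(phi)),
                           em, seed = seed)
    nrow(sim$detections) / max(1L, nrow(sim$truth$individuals))
  }
  # common random numbers: same seeds for both survival levels
  lo <- mean(vapply(1:10, function(s) rate(0.4, s), numeric(1)))
  hi <- mean(vapply(1:10, function(s) rate(0.9, s), numeric(1)))
  expect_gte(hi, lo)
})

test_that("mean detections per individual match the occupancy expectation", {
  # closed-form expectation of detections for an entrant at occasion e:
  # sum_t p * P(alive & at some height at t), from the transition matrix
  H <- 2L
  pars <- MultistateParams(phi = c(0.8, 0.7),
                           alpha = matrix(c(0.6, 0.4, 0.3, 0.7), 2,
                                          byrow = TRUE),
                           p = c(0.5, 0.6))
  T <- 5L
  psi <- transitionMatrix(pars)
  expDet <- function(e, h0) {
    g <- c(as.numeric(seq_len(H) == h0), 0)
    tot <- pars@p[h0]
    if (e < T) for (t in seq(e + 1L, T)) {
      g <- drop(g %*% psi)
      tot <- tot + sum(g[seq_len(H)] * pars@p)
    }
    tot
  }
  d <- tinyDesign(T = 5L, H = 2L)
  em <- EntryModel(betaTrue = c(baseline = log(10), post_0_6wk = log(10),
                                post_6pluswk = log(10)),
                   sigmaGamma = 0, sigmaDelta = 0,
                   initialHeightDist = c(0.5, 0.5))
  nTot <- 0; detTot <- 0; mu <- 0
  for (s in 1:10) {
    sim <- simulateDataset(d, list(reference = pars, fire_2021 = pars),
                           em, seed = 2000 + s)
    tr <- sim$truth$individuals
    nTot <- nTot + nrow(tr)
    detTot <- detTot + nrow(sim$detections)
    z0 <- sim$truth$z[cbind(seq_len(nrow(tr)), tr$entry)]
    mu <- mu + sum(vapply(seq_len(nrow(tr)),
                          function(k) expDet(tr$entry[k], z0[k]),
                          numeric(1)))
  }
  # 3 Monte-Carlo SE on the total detection count (Poisson-scale bound)
  expect_lt(abs(detTot - mu), 3 * sqrt(mu))
})
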