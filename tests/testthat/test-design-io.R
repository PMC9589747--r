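test_that("design construction enforces the BACI invariants", {
  d <- fireStudyDesign()
  expect_equal(nOccasions(d), 14L)
  expect_equal(nTrees(d), 12L)
  expect_equal(nHeights(d), 4L)
  tr <- studyTrees(d)
  expect_equal(sum(tr$treatment == "fire_2021"), 6L)
  expect_true(all(is.na(tr$burn_date[tr$treatment == "reference"])))
  expect_equal(sort(unique(format(tr$burn_date[!is.na(tr$burn_date)]))),
               c("2021-04-16", "2021-07-21"))

  # invalid: burn date on a reference tree
  bad <- studyTrees(d)
  bad$burn_date[1] <- as.Date("2021-04-16")
  expect_error(SamplingDesign(occasions(d), bad, heightLabels(d)),
               "reference trees")
  # invalid: non-increasing occasions
  expect_error(SamplingDesign(rep(as.Date("2021-03-05"), 3), studyTrees(d),
                              heightLabels(d)),
               "strictly increasing")
  # non-biweekly spacing warns but does not fail
  expect_warning(
    SamplingDesign(as.Date("2021-03-05") + c(0, 10, 200), studyTrees(d),
                   heightLabels(d)),
    "14 days")
})

test_that("design JSON/YAML round trip preserves the design", {
  d <- fireStudyDesign()
  for (ext in c("json", "yaml")) {
    path <- file.path(tempdir(), paste0("design.", ext))
    writeDesign(d, path)
    d2 <- readDesign(path)
    expect_equal(occasions(d2), occasions(d))
    expect_equal(studyTrees(d2), studyTrees(d))
    expect_equal(heightLabels(d2), heightLabels(d))
  }
})

test_that("detection CSV parsing validates rows against the design", {
  d <- fireStudyDesign()
  csv <- file.path(tempdir(), "det.csv")
  writeLines(c(
    "individual_id,date,tree_id,height_label,fate,mark_status",
    "a,2021-03-05,SE-1,3m,alive,new",
    "b,2021-03-19,4-2,9plus,alive,new",
    "a,2021-03-19,SE-1,6m,alive,recapture"), csv)
  det <- readDetections(csv, d)
  expect_equal(nrow(det), 3L)
  expect_equal(det$occasion, c(1L, 2L, 2L))
  expect_equal(det$height, c(1L, 4L, 2L))

  # unknown height label is rejected with the row number
  writeLines(c(
    "individual_id,date,tree_id,height_label,fate,mark_status",
    "a,2021-03-05,SE-1,3m,alive,new",
    "b,2021-03-05,SE-1,12m,alive,new"), csv)
  expect_error(readDetections(csv, d), "row 2.*12m")
  # missing column is a format error
  writeLines(c("individual_id,date,tree_id,height_label,fate",
               "a,2021-03-05,SE-1,3m,alive"), csv)
  expect_error(readDetections(csv, d), "missing column")
})

test_that("date matching tolerates one day of jitter, exact mode does not", {
  d <- fireStudyDesign()
  csv <- file.path(tempdir(), "jitter.csv")
  writeLines(c(
    "individual_id,date,tree_id,height_label,fate,mark_status",
    "a,2021-03-06,SE-1,3m,alive,new"), csv)
  expect_equal(readDetections(csv, d)$occasion, 1L)
  expect_error(readDetections(csv, d, tolerance = 0), "matches no occasion")
})

test_that("write/read of detections is the identity", {
  sc <- fireStudyScenario(seed = 42)
  path <- file.path(tempdir(), "roundtrip.csv")
  writeDetections(sc$detections, sc$design, path)
  again <- readDetections(path, sc$design)
  rownames(again) <- NULL
  expect_equal(again, sc$detections)
})

test_that("capture histories encode detections at the right occasions", {
  d <- tinyDesign(T = 5L, H = 3L)
  det <- data.frame(individual_id = "a", occasion = c(2L, 4L),
                    tree_id = "R1", height = c(1L, 3L), fate = "alive",
                    mark_status = c("new", "recapture"),
                    stringsAsFactors = FALSE)
  ch <- buildCaptureHistories(det, d)
  expect_equal(as.vector(stateMatrix(ch)), c(0L, 1L, 0L, 3L, 0L))
  expect_equal(firstCapture(ch), 2L)
  expect_equal(lastOccasion(ch), 5L)
  expect_false(removedFlag(ch))
})

test_that("unreadable marks and unidentified frogs are excluded, not history rows", {
  d <- tinyDesign()
  det <- data.frame(
    individual_id = c("UNIDENTIFIED", "x"),
    occasion = c(1L, 2L), tree_id = "R1", height = 1L, fate = "alive",
    mark_status = c("new", "unreadable"), stringsAsFactors = FALSE)
  ch <- buildCaptureHistories(det, d)
  expect_equal(nrow(ch), 0L)
  expect_equal(nrow(exclusions(ch)), 2L)
  expect_setequal(exclusions(ch)$reason, c("unidentified", "unreadable_mark"))
})

test_that("found-dead individuals are removed on recovery with truncation", {
  d <- tinyDesign(T = 5L)
  det <- data.frame(
    individual_id = "a", occasion = c(1L, 3L, 5L), tree_id = "R1",
    height = c(2L, 2L, 2L), fate = c("alive", "alive", "found_dead"),
    mark_status = c("new", "recapture", "recapture"),
    stringsAsFactors = FALSE)
  ch <- buildCaptureHistories(det, d)
  expect_true(removedFlag(ch))
  expect_equal(lastOccasion(ch), 3L)
  expect_equal(as.vector(stateMatrix(ch))[5L], 0L)
  expect_true("dead_recovery" %in% exclusions(ch)$reason)

  # the truncated likelihood equals brute force over the truncated window
  set.seed(7)
  pars <- randomParams(3L)
  ll <- loglikDataset(ch, pars)$pointwise[[1L]]
  expect_equal(ll, enumLoglik(c(2L, 0L, 2L, 0L, 0L), pars, f = 1L, last = 3L),
               tolerance = 1e-10)
})

test_that("conflicting same-occasion states raise an error", {
  d <- tinyDesign()
  det <- data.frame(
    individual_id = "a", occasion = c(2L, 2L), tree_id = "R1",
    height = c(1L, 3L), fate = "alive",
    mark_status = c("new", "recapture"), stringsAsFactors = FALSE)
  expect_error(buildCaptureHistories(det, d), "different states")
})

test_that("abundance table separates first detections from all detections", {
  d <- tinyDesign(T = 3L)
  det <- data.frame(
    individual_id = c("a", "a", "UNIDENTIFIED"),
    occasion = c(1L, 2L, 2L), tree_id = "R1", height = 1L,
    fate = "alive", mark_status = c("new", "recapture", "new"),
    stringsAsFactors = FALSE)
  tab <- buildAbundanceTable(det, d)
  expect_equal(newCounts(tab)["R1", ], c(1L, 0L, 0L))
  expect_equal(totalCounts(tab)["R1", ], c(1L, 2L, 0L))
  # empty detections give the all-zero table
  tab0 <- buildAbundanceTable(det[0, ], d)
  expect_true(all(totalCounts(tab0) == 0L))
})

test_that("histories and abundance table agree on first-capture counts", {
  sc <- fireStudyScenario(seed = 11)
  ch <- buildCaptureHistories(sc$detections, sc$design)
  tab <- buildAbundanceTable(sc$detections, sc$design)
  perOcc <- colSums(newCounts(tab))
  expect_equal(as.vector(perOcc), tabulate(firstCapture(ch),
                                           nOccasions(sc$design)))
  # every identified detection appears in exactly one history
  expect_equal(sum(stateMatrix(ch) > 0),
               sum(sc$detections$individual_id != "UNIDENTIFIED"))
})

test_that("dataset summary reproduces the field-style bookkeeping", {
  design <- fireStudyDesign()
  det <- headlineDetections(design)
  ch <- buildCaptureHistories(det, design)
  s <- summarizeDataset(ch, det)
  expect_equal(s$nIndividuals, 78L)
  expect_equal(s$nRecaptures, 199L)
  expect_equal(s$nUnidentified, 2L)
  expect_equal(s$nRecapturedIndividuals, 48L)
  # conservation: identified detections = individuals + recaptures
  expect_equal(sum(s$perHeightTotals), s$nIndividuals + s$nRecaptures)
  expect_equal(round(s$pctRecaptured), 62)
  expect_equal(round(s$meanCapturesAll, 1), 3.6)
  expect_equal(round(s$meanCapturesRecaptured, 1), 5.1)
  # grand total for the abundance models includes unidentified escapes
  tab <- buildAbundanceTable(det, design)
  expect_equal(sum(totalCounts(tab)), 279L)
})

test_that("single-capture and empty datasets summarize sanely", {
  d <- tinyDesign()
  det <- data.frame(individual_id = "a", occasion = 1L, tree_id = "R1",
                    height = 1L, fate = "alive", mark_status = "new",
                    stringsAsFactors = FALSE)
  ch <- buildCaptureHistories(det, d)
  s <- summarizeDataset(ch, det)
  expect_equal(s$meanCapturesAll, 1)
  expect_equal(s$pctRecaptured, 0)
  s0 <- summarizeDataset(buildCaptureHistories(det[0, ], d), det[0, ])
  expect_equal(s0$nIndividuals, 0L)
  expect_true(is.na(s0$meanCapturesAll))
})

test_that("capture-history CSV round trip preserves everything", {
  sc <- fireStudyScenario(seed = 5)
  ch <- buildCaptureHistories(sc$detections, sc$design)
  path <- file.path(tempdir(), "ch.csv")
  writeCaptureHistories(ch, path)
  ch2 <- readCaptureHistories(path, sc$design)
  expect_equal(unname(stateMatrix(ch2)), unname(stateMatrix(ch)))
  expect_equal(firstCapture(ch2), firstCapture(ch))
  expect_equal(removedFlag(ch2), removedFlag(ch))
})
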