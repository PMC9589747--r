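#' Descriptive summary of a mark-recapture dataset
#'
#' Totals and means in the form the field reports them: number of
#' identified individuals, number of recaptures (identified detections
#' minus individuals), unidentified escapes, excluded records, per-height
#' detection totals, mean captures per individual (all and among those
#' recaptured at least once), and the percent of individuals recaptured
#' at least once.  Because record exclusions can remove an individual
#' from the recapture tally, the percentage is reported under both the
#' raw denominator (all identified individuals) and the effective
#' denominator (individuals with a usable capture history).
#'
#' @param histories a [CaptureHistories-class].
#' @param detections the validated detection `data.frame` the histories
#'   were built from.
#' @return a list of class `canopymr_summary` with elements
#'   `nIndividuals`, `nRecaptures`, `nUnidentified`, `nExcluded`,
#'   `perHeightTotals`, `meanCapturesAll`, `meanCapturesRecaptured`,
#'   `nRecapturedIndividuals`, `nNeverRecaptured`, `pctRecaptured`,
#'   `pctRecapturedEffective`.  Means are `NA` on an empty dataset.
#' @export
summarizeDataset <- function(histories, detections) {
  H <- length(heightLabels(histories))
  ident <- detections$individual_id != "UNIDENTIFIED" &
    detections$mark_status != "unreadable"
  di <- detections[ident, , drop = FALSE]
  nInd <- length(unique(di$individual_id))
  nDet <- nrow(di)
  perHeight <- vapply(seq_len(H), function(h) sum(di$height == h), integer(1))
  names(perHeight) <- heightLabels(histories)
  capsPer <- if (nInd) table(di$individual_id) else integer(0)
  nRecapInd <- sum(capsPer >= 2)
  excl <- exclusions(histories)
  out <- list(
    nIndividuals = nInd,
    nRecaptures = nDet - nInd,
    nUnidentified = sum(detections$individual_id == "UNIDENTIFIED"),
    nExcluded = nrow(excl),
    perHeightTotals = perHeight,
    meanCapturesAll = if (nInd) nDet / nInd else NA_real_,
    meanCapturesRecaptured = if (nRecapInd)
      sum(capsPer[capsPer >= 2]) / nRecapInd else NA_real_,
    nRecapturedIndividuals = nRecapInd,
    nNeverRecaptured = nInd - nRecapInd,
    pctRecaptured = if (nInd) 100 * nRecapInd / nInd else NA_real_,
    pctRecapturedEffective = if (nrow(histories))
      100 * nRecapInd / nrow(histories) else NA_real_
  )
  class(out) <- "canopymr_summary"
  out
}

#' @export
print.canopymr_summary <- function(x, ...) {
  cat("Mark-recapture dataset summary\n")
  cat("  individuals:        ", x$nIndividuals, "\n")
  cat("  recaptures:         ", x$nRecaptures, "\n")
  cat("  unidentified:       ", x$nUnidentified, "\n")
  cat("  excluded records:   ", x$nExcluded, "\n")
  cat("  per-height totals:  ",
      paste(names(x$perHeightTotals), x$perHeightTotals, sep = "=",
            collapse = "  "), "\n")
  cat("  mean captures (all):", round(x$meanCapturesAll, 2), "\n")
  cat("  mean captures (recaptured):", round(x$meanCapturesRecaptured, 2), "\n")
  cat("  recaptured at least once: ", x$nRecapturedIndividuals, " (",
      round(x$pctRecaptured), "%)\n", sep = "")
  invisible(x)
}

#' Write a dataset summary as a two-column CSV
#'
#' @param x a `canopymr_summary`.
#' @param path CSV path.
#' @return `path` invisibly.
#' @export
writeSummary <- function(x, path) {
  flat <- c(
    nIndividuals = x$nIndividuals, nRecaptures = x$nRecaptures,
    nUnidentified = x$nUnidentified, nExcluded = x$nExcluded,
    stats::setNames(as.numeric(x$perHeightTotals),
                    paste0("perHeight_", names(x$perHeightTotals))),
    meanCapturesAll = x$meanCapturesAll,
    meanCapturesRecaptured = x$meanCapturesRecaptured,
    nRecapturedIndividuals = x$nRecapturedIndividuals,
    nNeverRecaptured = x$nNeverRecaptured,
    pctRecaptured = x$pctRecaptured,
    pctRecapturedEffective = x$pctRecapturedEffective
  )
  utils::write.csv(data.frame(quantity = names(flat), value = unname(flat)),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
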