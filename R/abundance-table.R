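#' Build the per-tree, per-occasion count table
#'
#' `newCounts` counts each identified individual exactly once, at its
#' first-capture occasion and tree.  `totalCounts` counts every detection
#' event: first captures, recaptures, unreadable-mark records and
#' UNIDENTIFIED escapes, so its grand total equals the number of
#' detection rows.
#'
#' @param detections validated detection `data.frame`.
#' @param design a [SamplingDesign-class].
#' @return an [AbundanceTable-class] (trees x occasions).
#' @export
buildAbundanceTable <- function(detections, design) {
  tr <- studyTrees(design)
  T <- nOccasions(design)
  J <- nrow(tr)
  nw <- matrix(0L, J, T, dimnames = list(tr$tree_id, NULL))
  tt <- matrix(0L, J, T, dimnames = list(tr$tree_id, NULL))
  if (nrow(detections)) {
    j <- match(detections$tree_id, tr$tree_id)
    for (k in seq_len(nrow(detections)))
      tt[j[k], detections$occasion[k]] <- tt[j[k], detections$occasion[k]] + 1L
    ident <- detections$individual_id != "UNIDENTIFIED" &
      detections$mark_status != "unreadable"
    di <- detections[ident, , drop = FALSE]
    if (nrow(di)) {
      ord <- order(di$occasion)
      di <- di[ord, , drop = FALSE]
      first <- !duplicated(di$individual_id)
      dfirst <- di[first, , drop = FALSE]
      jj <- match(dfirst$tree_id, tr$tree_id)
      for (k in seq_len(nrow(dfirst)))
        nw[jj[k], dfirst$occasion[k]] <- nw[jj[k], dfirst$occasion[k]] + 1L
    }
  }
  newAbundanceTable(nw, tt, design)
}

#' Low-level AbundanceTable constructor
#' @param newCounts,totalCounts integer matrices (trees x occasions).
#' @param design a [SamplingDesign-class].
#' @keywords internal
#' @export
newAbundanceTable <- function(newCounts, totalCounts, design) {
  storage.mode(newCounts) <- "integer"
  storage.mode(totalCounts) <- "integer"
  se <- SummarizedExperiment(
    assays = list(newCounts = newCounts, totalCounts = totalCounts),
    rowData = DataFrame(studyTrees(design)),
    colData = DataFrame(date = occasions(design))
  )
  obj <- new("AbundanceTable", se)
  validObject(obj)
  obj
}

#' Read / write an abundance table as long-format CSV
#'
#' Columns `tree_id`, `occasion`, `new_count`, `total_count`, one row per
#' (tree, occasion) cell.
#'
#' @param x an [AbundanceTable-class].
#' @param path CSV path.
#' @param design a [SamplingDesign-class].
#' @return `writeAbundanceTable()` returns `path` invisibly;
#'   `readAbundanceTable()` an [AbundanceTable-class].
#' @export
writeAbundanceTable <- function(x, path) {
  nw <- newCounts(x); tt <- totalCounts(x)
  out <- data.frame(
    tree_id = rep(rownames(nw), times = ncol(nw)),
    occasion = rep(seq_len(ncol(nw)), each = nrow(nw)),
    new_count = as.vector(nw),
    total_count = as.vector(tt),
    stringsAsFactors = FALSE
  )
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeAbundanceTable
#' @export
readAbundanceTable <- function(path, design) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  tr <- studyTrees(design)
  T <- nOccasions(design)
  nw <- matrix(0L, nrow(tr), T, dimnames = list(tr$tree_id, NULL))
  tt <- nw
  j <- match(x$tree_id, tr$tree_id)
  if (anyNA(j)) stop("unknown tree_id in abundance file")
  nw[cbind(j, x$occasion)] <- x$new_count
  tt[cbind(j, x$occasion)] <- x$total_count
  newAbundanceTable(nw, tt, design)
}
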