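#' Build capture histories from validated detections
#'
#' One history per identified individual: an integer vector over the T
#' occasions with 0 = not seen and h = seen at height h.  Records with
#' `individual_id = UNIDENTIFIED` or `mark_status = unreadable` never
#' enter a history; they go to the exclusion report.  An individual found
#' dead is treated as removed on recovery: its history is truncated at the
#' last occasion it was seen alive and flagged `removed`, and the death
#' observation itself is excluded from the multistate likelihood (dead
#' individuals are unobservable under the observation model).  An
#' individual's tree is the tree of its first capture.
#'
#' @param detections validated detection `data.frame`
#'   (see [readDetections()]).
#' @param design a [SamplingDesign-class].
#' @return a [CaptureHistories-class]; `exclusions(x)` holds the report
#'   (`data.frame` with columns `individual_id`, `occasion`, `reason`).
#' @examples
#' d <- fireStudyDesign()
#' det <- data.frame(individual_id = "a", occasion = c(2L, 4L),
#'                   tree_id = "SE-1", height = c(1L, 3L),
#'                   fate = "alive", mark_status = c("new", "recapture"))
#' ch <- buildCaptureHistories(det, d)
#' stateMatrix(ch)[1, ]   # 0 1 0 3 0 0 ...
#' @export
buildCaptureHistories <- function(detections, design) {
  T <- nOccasions(design)
  excl <- data.frame(individual_id = character(), occasion = integer(),
                     reason = character(), stringsAsFactors = FALSE)
  keep <- rep(TRUE, nrow(detections))
  unident <- detections$individual_id == "UNIDENTIFIED"
  if (any(unident)) {
    excl <- rbind(excl, data.frame(
      individual_id = detections$individual_id[unident],
      occasion = detections$occasion[unident],
      reason = "unidentified", stringsAsFactors = FALSE))
    keep <- keep & !unident
  }
  unread <- detections$mark_status == "unreadable"
  if (any(unread & keep)) {
    i <- unread & keep
    excl <- rbind(excl, data.frame(
      individual_id = detections$individual_id[i],
      occasion = detections$occasion[i],
      reason = "unreadable_mark", stringsAsFactors = FALSE))
    keep <- keep & !unread
  }
  det <- detections[keep, , drop = FALSE]

  ids <- unique(det$individual_id)
  y <- matrix(0L, nrow = length(ids), ncol = T)
  f <- integer(length(ids)); last <- integer(length(ids))
  removed <- logical(length(ids)); tree <- character(length(ids))
  drop_ind <- logical(length(ids))
  for (k in seq_along(ids)) {
    di <- det[det$individual_id == ids[k], , drop = FALSE]
    # conflicting duplicate detections at one occasion
    for (o in unique(di$occasion)) {
      st <- unique(di$height[di$occasion == o & di$fate == "alive"])
      if (length(st) > 1L)
        stop("individual '", ids[k], "' detected in different states at ",
             "occasion ", o)
    }
    alive <- di[di$fate == "alive", , drop = FALSE]
    dead <- di[di$fate == "found_dead", , drop = FALSE]
    if (nrow(dead)) {
      excl <- rbind(excl, data.frame(individual_id = ids[k],
                                     occasion = dead$occasion,
                                     reason = "dead_recovery",
                                     stringsAsFactors = FALSE))
    }
    if (nrow(alive) == 0L) {
      drop_ind[k] <- TRUE
      next
    }
    alive <- alive[order(alive$occasion), , drop = FALSE]
    y[k, alive$occasion] <- alive$height
    f[k] <- min(alive$occasion)
    tree[k] <- alive$tree_id[1L]
    if (nrow(dead)) {
      removed[k] <- TRUE
      last[k] <- max(alive$occasion)
      if (max(dead$occasion) <= last[k])
        stop("individual '", ids[k], "' found dead at or before a live ",
             "detection")
    } else {
      last[k] <- T
    }
  }
  sel <- !drop_ind
  newCaptureHistories(
    y = y[sel, , drop = FALSE],
    individual_id = ids[sel], tree_id = tree[sel], f = f[sel],
    last = last[sel], removed = removed[sel],
    design = design, exclusions = excl
  )
}

#' Low-level CaptureHistories constructor
#'
#' @param y integer state matrix (individuals x occasions).
#' @param individual_id,tree_id,f,last,removed per-individual metadata.
#' @param design a [SamplingDesign-class].
#' @param exclusions exclusion-report `data.frame`.
#' @return a [CaptureHistories-class].
#' @keywords internal
#' @export
newCaptureHistories <- function(y, individual_id, tree_id, f, last, removed,
                                design, exclusions = NULL) {
  if (is.null(exclusions))
    exclusions <- data.frame(individual_id = character(),
                             occasion = integer(), reason = character(),
                             stringsAsFactors = FALSE)
  storage.mode(y) <- "integer"
  rownames(y) <- individual_id
  se <- SummarizedExperiment(
    assays = list(state = y),
    rowData = DataFrame(individual_id = individual_id, tree_id = tree_id,
                        f = as.integer(f), last = as.integer(last),
                        removed = removed),
    colData = DataFrame(date = occasions(design)),
    metadata = list(heights = heightLabels(design),
                    exclusions = exclusions)
  )
  obj <- new("CaptureHistories", se)
  validObject(obj)
  obj
}

#' Export / import capture histories as a CSV matrix
#'
#' One row per individual with columns `individual_id`, `tree_id`, `f`,
#' `last`, `removed` and `occ_1 .. occ_T` holding the integer state codes.
#'
#' @param x a [CaptureHistories-class].
#' @param path output CSV path.
#' @return `path` invisibly; `readCaptureHistories()` returns a
#'   [CaptureHistories-class].
#' @export
writeCaptureHistories <- function(x, path) {
  y <- stateMatrix(x)
  colnames(y) <- paste0("occ_", seq_len(ncol(y)))
  rd <- rowData(x)
  out <- cbind(
    data.frame(individual_id = rd$individual_id, tree_id = rd$tree_id,
               f = rd$f, last = rd$last, removed = rd$removed,
               stringsAsFactors = FALSE),
    as.data.frame(y, row.names = NULL)
  )
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeCaptureHistories
#' @param design the [SamplingDesign-class] the histories refer to.
#' @export
readCaptureHistories <- function(path, design) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  occ_cols <- grep("^occ_", names(x))
  y <- as.matrix(x[, occ_cols, drop = FALSE])
  if (ncol(y) != nOccasions(design))
    stop("capture-history file has ", ncol(y), " occasions but the design ",
         "has ", nOccasions(design))
  newCaptureHistories(y = y, individual_id = x$individual_id,
                      tree_id = x$tree_id, f = x$f, last = x$last,
                      removed = as.logical(x$removed), design = design)
}
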