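#' Read detection records from CSV
#'
#' The CSV dialect has a header row with columns `individual_id`, `date`
#' (ISO-8601), `tree_id`, `height_label`, `fate` (`alive`/`found_dead`)
#' and `mark_status` (`new`/`recapture`/`unreadable`).  Rows are validated
#' against the design: unknown trees, height labels or dates are rejected
#' with row-numbered diagnostics.  The special id `UNIDENTIFIED` marks
#' frogs that escaped before identification.
#'
#' @param path CSV file path.
#' @param design a [SamplingDesign-class].
#' @param tolerance days of slack when matching dates to occasions
#'   (default 1; 0 = exact).
#' @return a `data.frame` of validated detections with columns
#'   `individual_id`, `occasion` (integer 1..T), `tree_id`, `height`
#'   (integer 1..H), `fate`, `mark_status`.
#' @export
readDetections <- function(path, design, tolerance = 1) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  need <- c("individual_id", "date", "tree_id", "height_label", "fate",
            "mark_status")
  missing <- setdiff(need, names(raw))
  if (length(missing))
    stop("detection file is missing column(s): ",
         paste(missing, collapse = ", "))
  validateDetections(raw, design, tolerance = tolerance)
}

#' @rdname readDetections
#' @param raw `data.frame` with the CSV columns (character).
#' @export
validateDetections <- function(raw, design, tolerance = 1) {
  n <- nrow(raw)
  if (n == 0L) {
    return(data.frame(individual_id = character(), occasion = integer(),
                      tree_id = character(), height = integer(),
                      fate = character(), mark_status = character(),
                      stringsAsFactors = FALSE))
  }
  problems <- character()
  occ <- matchOccasion(as.Date(raw$date), design, tolerance = tolerance)
  bad <- which(is.na(occ))
  if (length(bad))
    problems <- c(problems, sprintf("row %d: date '%s' matches no occasion",
                                    bad, raw$date[bad]))
  tr <- studyTrees(design)$tree_id
  bad <- which(!raw$tree_id %in% tr)
  if (length(bad))
    problems <- c(problems, sprintf("row %d: unknown tree '%s'",
                                    bad, raw$tree_id[bad]))
  h <- match(raw$height_label, heightLabels(design))
  bad <- which(is.na(h))
  if (length(bad))
    problems <- c(problems, sprintf("row %d: unknown height label '%s'",
                                    bad, raw$height_label[bad]))
  bad <- which(!raw$fate %in% c("alive", "found_dead"))
  if (length(bad))
    problems <- c(problems, sprintf("row %d: invalid fate '%s'",
                                    bad, raw$fate[bad]))
  bad <- which(!raw$mark_status %in% c("new", "recapture", "unreadable"))
  if (length(bad))
    problems <- c(problems, sprintf("row %d: invalid mark_status '%s'",
                                    bad, raw$mark_status[bad]))
  if (length(problems))
    stop("invalid detection records:\n  ",
         paste(problems, collapse = "\n  "))
  data.frame(individual_id = raw$individual_id, occasion = occ,
             tree_id = raw$tree_id, height = h, fate = raw$fate,
             mark_status = raw$mark_status, stringsAsFactors = FALSE)
}

#' Write detection records to CSV
#'
#' Inverse of [readDetections()]: internal occasion and height indices are
#' rendered back to occasion dates and height labels, so a write/read
#' round trip is the identity.
#'
#' @param detections validated detection `data.frame`.
#' @param design a [SamplingDesign-class].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
writeDetections <- function(detections, design, path) {
  out <- data.frame(
    individual_id = detections$individual_id,
    date = format(occasions(design)[detections$occasion]),
    tree_id = detections$tree_id,
    height_label = heightLabels(design)[detections$height],
    fate = detections$fate,
    mark_status = detections$mark_status,
    stringsAsFactors = FALSE
  )
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
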