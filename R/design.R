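#' The canonical BACI study design
#'
#' Twelve longleaf pines in four burn units: six reference trees in units
#' burned the year before the study (SE, 3N) and six trees in units burned
#' during the study (unit 4 on 16 April 2021, unit SW on 21 July 2021,
#' three trees each).  Fourteen biweekly sampling occasions starting
#' 5 March 2021, four height strata (3 m, 6 m, 9 m, 9+ m).
#'
#' @return a [SamplingDesign-class].
#' @examples
#' d <- fireStudyDesign()
#' nOccasions(d)  # 14
#' @export
fireStudyDesign <- function() {
  units <- data.frame(
    unit = c("SE", "3N", "4", "SW"),
    treatment = c("reference", "reference", "fire_2021", "fire_2021"),
    burn_date = as.Date(c(NA, NA, "2021-04-16", "2021-07-21")),
    stringsAsFactors = FALSE
  )
  trees <- do.call(rbind, lapply(seq_len(nrow(units)), function(u) {
    data.frame(
      tree_id = paste0(units$unit[u], "-", 1:3),
      unit = units$unit[u],
      treatment = units$treatment[u],
      burn_date = units$burn_date[u],
      stringsAsFactors = FALSE
    )
  }))
  SamplingDesign(
    occasions = as.Date("2021-03-05") + 14 * 0:13,
    trees = trees,
    heights = c("3m", "6m", "9m", "9plus")
  )
}

#' Read / write a sampling design as JSON or YAML
#'
#' The on-disk form lists occasion dates (ISO-8601), trees with unit,
#' treatment and burn date, and the ordered height labels.  Format is
#' chosen by file extension (`.json`, `.yaml`/`.yml`).
#'
#' @param path file path.
#' @return `readDesign()` returns a [SamplingDesign-class];
#'   `writeDesign()` returns `path` invisibly.
#' @export
readDesign <- function(path) {
  x <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  }
  trees <- as.data.frame(x$trees, stringsAsFactors = FALSE)
  if (is.null(trees$burn_date)) trees$burn_date <- NA_character_
  trees$burn_date[trees$burn_date %in% c("", "NA")] <- NA_character_
  suppressWarnings(SamplingDesign(
    occasions = as.Date(unlist(x$occasions)),
    trees = trees,
    heights = unlist(x$heights)
  ))
}

#' @rdname readDesign
#' @param design a [SamplingDesign-class].
#' @export
writeDesign <- function(design, path) {
  tr <- studyTrees(design)
  obj <- list(
    occasions = format(occasions(design)),
    trees = data.frame(tree_id = tr$tree_id, unit = tr$unit,
                       treatment = tr$treatment,
                       burn_date = ifelse(is.na(tr$burn_date), NA,
                                          format(tr$burn_date)),
                       stringsAsFactors = FALSE),
    heights = heightLabels(design)
  )
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::write_yaml(obj, path)
  } else {
    jsonlite::write_json(obj, path, auto_unbox = FALSE, na = "null",
                         pretty = TRUE)
  }
  invisible(path)
}

#' Match calendar dates to design occasions
#'
#' Field schedules jitter; by default a date within +/- 1 day of an
#' occasion is matched to it.  `tolerance = 0` demands exact matches.
#'
#' @param dates `Date` vector.
#' @param design a [SamplingDesign-class].
#' @param tolerance days of slack (default 1).
#' @return integer occasion indices, `NA` where unmatched.
#' @keywords internal
matchOccasion <- function(dates, design, tolerance = 1) {
  occ <- as.numeric(occasions(design))
  vapply(as.numeric(as.Date(dates)), function(d) {
    dd <- abs(occ - d)
    i <- which.min(dd)
    if (dd[i] <= tolerance) i else NA_integer_
  }, integer(1))
}
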