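#' Construct a BehaviorTable
#'
#' @param subjectId character vector of subject ids.
#' @param age numeric vector (years).
#' @param meanFD numeric vector (mm).
#' @param measures data.frame of numeric behavioral measure columns.
#' @param extraConfounds optional data.frame of further numeric confound
#'   columns.
#' @return A [BehaviorTable-class].
#' @export
behaviorTable <- function(subjectId, age, meanFD, measures,
                          extraConfounds = NULL) {
  conf <- data.frame(age = as.numeric(age), mean_fd = as.numeric(meanFD))
  if (!is.null(extraConfounds)) conf <- cbind(conf, extraConfounds)
  new("BehaviorTable", subjectId = as.character(subjectId),
      confounds = conf, measures = as.data.frame(measures, optional = TRUE))
}

.meqBreaks <- data.frame(
  lo = c(16L, 31L, 42L, 59L, 70L),
  hi = c(30L, 41L, 58L, 69L, 86L),
  label = c("definitely evening", "moderately evening", "neutral",
            "moderately morning", "definitely morning")
)

#' MEQ category labels, in evening-to-morning order
#' @export
meqCategories <- function() .meqBreaks$label

#' Classify MEQ global scores into the five chronotype categories
#'
#' Bins the Morningness-Eveningness Questionnaire global sum (range 16-86)
#' into the conventional five-point scale: definitely evening (16-30),
#' moderately evening (31-41), neutral (42-58), moderately morning (59-69)
#' and definitely morning (70-86); all bin edges inclusive.
#'
#' @param meqGlobal numeric vector of global MEQ scores.
#' @return A factor with levels in evening-to-morning order.
#' @export
classifyMEQ <- function(meqGlobal) {
  if (any(!is.finite(meqGlobal)))
    stop("MEQ scores must be finite")
  if (any(meqGlobal < 16 | meqGlobal > 86))
    stop("MEQ global scores must lie in [16, 86]; offending value(s): ",
         paste(utils::head(meqGlobal[meqGlobal < 16 | meqGlobal > 86], 5),
               collapse = ", "))
  idx <- findInterval(meqGlobal, c(.meqBreaks$lo, 87L))
  factor(.meqBreaks$label[idx], levels = .meqBreaks$label)
}

#' Chronotype/test-time synchrony score
#'
#' Quantifies how well each subject's scan time matched their chronotype.
#' Scan midpoint times (24-h decimal hours) are reflected as `24 - t`, so
#' that larger values mean earlier (morning) sessions, mirroring high MEQ
#' scores meaning morning chronotype. Both the MEQ scores and the reflected
#' times are z-scored across the supplied sample (n - 1 denominator), and the
#' synchrony score is one minus the absolute difference of the two z-scores:
#' `s_i = 1 - | z(meq)_i - z(24 - t_i) |`. The maximum attainable score is 1
#' (perfect chronotype/test-time match); there is no lower bound.
#'
#' @param meqGlobal numeric vector of MEQ global scores.
#' @param scanMidpointTime numeric vector of scan-session midpoints as 24-h
#'   decimal hours in [0, 24).
#' @return Numeric vector of synchrony scores (unitless).
#' @export
computeSynchrony <- function(meqGlobal, scanMidpointTime) {
  if (length(meqGlobal) != length(scanMidpointTime))
    stop("inputs must have equal length")
  if (length(meqGlobal) < 3L)
    stop("at least 3 subjects are required to z-score")
  if (anyNA(meqGlobal) || anyNA(scanMidpointTime))
    stop("missing values are not allowed")
  if (any(scanMidpointTime < 0 | scanMidpointTime >= 24))
    stop("scan midpoint times must lie in [0, 24) decimal hours")
  reflected <- 24 - scanMidpointTime
  if (stats::sd(meqGlobal) == 0)
    stop("MEQ scores have zero variance; synchrony is undefined")
  if (stats::sd(reflected) == 0)
    stop("scan times have zero variance; synchrony is undefined")
  zMeq <- (meqGlobal - mean(meqGlobal)) / stats::sd(meqGlobal)
  zTime <- (reflected - mean(reflected)) / stats::sd(reflected)
  1 - abs(zMeq - zTime)
}

#' Extract an ordered subjects x measures matrix from a BehaviorTable
#'
#' @param table a [BehaviorTable-class].
#' @param measureOrder character vector of measure names; the matrix columns
#'   follow this order exactly. Defaults to the table's column order.
#' @return Numeric matrix with subject ids as rownames and the requested
#'   measure names as colnames.
#' @export
buildBehaviorBlock <- function(table, measureOrder = NULL) {
  stopifnot(is(table, "BehaviorTable"))
  if (is.null(measureOrder)) measureOrder <- names(table@measures)
  missing <- setdiff(measureOrder, names(table@measures))
  if (length(missing))
    stop("measure column(s) not present: ", paste(missing, collapse = ", "))
  block <- as.matrix(table@measures[measureOrder])
  if (anyNA(block))
    stop("behavior block contains missing values; complete cases required")
  rownames(block) <- table@subjectId
  block
}

#' Read a behavior table from TSV
#'
#' Expects a header row with at least `subject_id`, `age` and `mean_fd`
#' columns; every remaining numeric column is treated as a behavioral
#' measure. Dot-decimal, tab-separated.
#'
#' @param path file path.
#' @param measureColumns optionally restrict which columns are measures.
#' @return A [BehaviorTable-class].
#' @export
readBehaviorTable <- function(path, measureColumns = NULL) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  need <- c("subject_id", "age", "mean_fd")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("behavior table lacks required column(s): ",
         paste(missing, collapse = ", "))
  rest <- setdiff(names(df), need)
  if (is.null(measureColumns)) measureColumns <- rest
  behaviorTable(df$subject_id, df$age, df$mean_fd,
                df[measureColumns])
}

#' Write a behavior table to TSV
#'
#' @param table a [BehaviorTable-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeBehaviorTable <- function(table, path) {
  stopifnot(is(table, "BehaviorTable"))
  df <- cbind(data.frame(subject_id = table@subjectId),
              table@confounds, table@measures)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Subset a BehaviorTable by subject
#'
#' @param table a [BehaviorTable-class].
#' @param keep subject ids (or logical/integer index) to retain.
#' @return A [BehaviorTable-class].
#' @export
subsetBehavior <- function(table, keep) {
  stopifnot(is(table, "BehaviorTable"))
  if (is.character(keep)) {
    idx <- match(keep, table@subjectId)
    if (anyNA(idx))
      stop("unknown subject id(s): ",
           paste(keep[is.na(idx)], collapse = ", "))
  } else idx <- keep
  new("BehaviorTable", subjectId = table@subjectId[idx],
      confounds = table@confounds[idx, , drop = FALSE],
      measures = table@measures[idx, , drop = FALSE])
}
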