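#' Construct a ConfoundSpec
#'
#' Defaults follow the primary analysis: age and mean framewise displacement
#' are removed from the voxelwise brain block, age from every behavioral
#' score.
#'
#' @param brainConfounds confound names regressed from the brain block.
#' @param behaviorConfounds confound names regressed from the behavior block.
#' @return A [ConfoundSpec-class].
#' @export
confoundSpec <- function(brainConfounds = c("age", "mean_fd"),
                         behaviorConfounds = "age") {
  new("ConfoundSpec", brainConfounds = brainConfounds,
      behaviorConfounds = behaviorConfounds)
}

#' Residualize a matrix of columns on a confound design
#'
#' Replaces every column of `X` by its residual from an ordinary
#' least-squares fit on an intercept plus all confound columns jointly (one
#' multiple regression per column, so the result is invariant to confound
#' order). Residual columns have mean zero and are orthogonal to the span of
#' the confound design; the operation is idempotent.
#'
#' @param X numeric matrix, subjects x variables.
#' @param C numeric matrix or data.frame, subjects x confounds; column names
#'   are used in error messages.
#' @return A matrix of residuals, same shape and dimnames as `X`.
#' @export
residualizeColumns <- function(X, C) {
  X <- as.matrix(X)
  C <- as.matrix(C)
  if (nrow(X) != nrow(C))
    stop("X and confounds must have the same number of rows")
  if (anyNA(X) || anyNA(C))
    stop("missing values are not allowed; supply complete cases")
  n <- nrow(X)
  if (n < ncol(C) + 2L)
    stop(sprintf("need at least %d subjects for %d confound(s)",
                 ncol(C) + 2L, ncol(C)))
  sds <- .colSDs(C)
  if (any(sds == 0)) {
    nm <- colnames(C)
    lab <- if (is.null(nm)) paste0("#", which(sds == 0)) else nm[sds == 0]
    stop("constant confound column(s): ", paste(lab, collapse = ", "))
  }
  D <- cbind(intercept = 1, C)
  qrD <- qr(D)
  if (qrD$rank < ncol(D)) {
    drop <- colnames(D)[qrD$pivot[seq(qrD$rank + 1L, ncol(D))]]
    stop("rank-deficient confound design; offending column(s): ",
         paste(drop, collapse = ", "))
  }
  res <- qr.resid(qrD, X)
  dimnames(res) <- dimnames(X)
  res
}

#' Prepare aligned, residualized brain and behavior blocks for PLS
#'
#' The full-sample analysis removes age and mean FD from the brain block and
#' age from the behavioral scores (`adjust = TRUE`). The unadjusted variant
#' used for the younger subsample removes only mean FD from the brain block
#' and leaves behavioral scores as they are (`adjust = FALSE`). Subject order
#' is preserved and must agree across blocks.
#'
#' @param sd an [SDMatrix-class].
#' @param behavior a [BehaviorTable-class] aligned with `sd` by subject id.
#' @param spec a [ConfoundSpec-class].
#' @param adjust logical; see Description.
#' @return A list with elements `sd` (residualized [SDMatrix-class]) and
#'   `behavior` (residualized [BehaviorTable-class]).
#' @export
prepareBlocks <- function(sd, behavior, spec = confoundSpec(),
                          adjust = TRUE) {
  stopifnot(is(sd, "SDMatrix"), is(behavior, "BehaviorTable"),
            is(spec, "ConfoundSpec"))
  .assertAligned(rownames(sd@values), behavior@subjectId)
  conf <- behavior@confounds
  brainNames <- if (adjust) spec@brainConfounds else
    setdiff(spec@brainConfounds, spec@behaviorConfounds)
  missing <- setdiff(union(brainNames, spec@behaviorConfounds), names(conf))
  if (length(missing))
    stop("confound column(s) absent from the behavior table: ",
         paste(missing, collapse = ", "))
  sdOut <- sd
  if (length(brainNames))
    sdOut <- initialize(sd, values = residualizeColumns(
      sd@values, conf[brainNames]))
  behOut <- behavior
  if (adjust && length(spec@behaviorConfounds)) {
    resid <- residualizeColumns(as.matrix(behavior@measures),
                                conf[spec@behaviorConfounds])
    behOut <- initialize(behavior,
                         measures = as.data.frame(resid,
                                                  optional = TRUE))
  }
  list(sd = sdOut, behavior = behOut)
}
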