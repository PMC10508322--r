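#' Accessor generics
#'
#' Small accessor family for the package's S4 containers. Each returns the
#' corresponding slot; none of them copies more than it must.
#'
#' @param object an S4 object from this package.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("subjectIds", function(object) standardGeneric("subjectIds"))

#' @rdname accessors
#' @export
setGeneric("sdValues", function(object) standardGeneric("sdValues"))

#' @rdname accessors
#' @export
setGeneric("voxelIndex", function(object) standardGeneric("voxelIndex"))

#' @rdname accessors
#' @export
setGeneric("measures", function(object) standardGeneric("measures"))

#' @rdname accessors
#' @export
setGeneric("confounds", function(object) standardGeneric("confounds"))

#' @rdname accessors
#' @export
setGeneric("singularValues", function(object) standardGeneric("singularValues"))

#' @rdname accessors
#' @export
setGeneric("covarianceExplained",
           function(object) standardGeneric("covarianceExplained"))

#' @rdname accessors
#' @export
setGeneric("behaviorSaliences",
           function(object) standardGeneric("behaviorSaliences"))

#' @rdname accessors
#' @export
setGeneric("voxelSaliences", function(object) standardGeneric("voxelSaliences"))

#' @rdname accessors
#' @export
setGeneric("brainScores", function(object) standardGeneric("brainScores"))

#' @rdname accessors
#' @export
setGeneric("pValues", function(object) standardGeneric("pValues"))

#' @rdname accessors
#' @export
setGeneric("bsr", function(object) standardGeneric("bsr"))

#' @rdname accessors
#' @export
setGeneric("behaviorCorrelations",
           function(object) standardGeneric("behaviorCorrelations"))

#' @rdname accessors
#' @export
setGeneric("correlationCI", function(object) standardGeneric("correlationCI"))
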