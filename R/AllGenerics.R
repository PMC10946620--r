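#' Accessors for EcoParallel classes
#'
#' Small accessor generics: \code{background} and \code{geneSets} for
#' \linkS4class{GeneSetCollection}; \code{geneScores}, \code{sampleScores}
#' and \code{inertiaFractions} for \linkS4class{CRDAResult}; \code{sfsMatrix}
#' and \code{sfsCounts} for SFS containers.
#'
#' @param object an EcoParallel S4 object.
#' @return the stored component.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("background", function(object) standardGeneric("background"))
#' @rdname accessors
#' @export
setGeneric("geneSets", function(object) standardGeneric("geneSets"))
#' @rdname accessors
#' @export
setGeneric("geneScores", function(object) standardGeneric("geneScores"))
#' @rdname accessors
#' @export
setGeneric("sampleScores", function(object) standardGeneric("sampleScores"))
#' @rdname accessors
#' @export
setGeneric("inertiaFractions",
           function(object) standardGeneric("inertiaFractions"))
#' @rdname accessors
#' @export
setGeneric("sfsMatrix", function(object) standardGeneric("sfsMatrix"))
#' @rdname accessors
#' @export
setGeneric("sfsCounts", function(object) standardGeneric("sfsCounts"))

#' @rdname accessors
setMethod("background", "GeneSetCollection", function(object) object@background)
#' @rdname accessors
setMethod("geneSets", "GeneSetCollection", function(object) object@sets)
#' @rdname accessors
setMethod("geneScores", "CRDAResult", function(object) object@geneScores)
#' @rdname accessors
setMethod("sampleScores", "CRDAResult", function(object) object@sampleScores)
#' @rdname accessors
setMethod("inertiaFractions", "CRDAResult", function(object) object@fractions)
#' @rdname accessors
setMethod("sfsMatrix", "JointFoldedSFS", function(object) object@mat)
#' @rdname accessors
setMethod("sfsCounts", "FoldedSFS", function(object) object@counts)
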