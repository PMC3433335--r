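#' Accessors
#'
#' Accessor generics for the package classes. \code{hypSize} is the number N
#' of scorable downstream genes of a HYP; \code{downstreamGenes} and
#' \code{downstreamSigns} return the parallel gene/sign vectors;
#' \code{droppedAmbiguous} lists genes excluded for contradictory regulation
#' signs; \code{evidence} returns the per-gene citation sets.
#'
#' @param object a package object.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("upstream", function(object) standardGeneric("upstream"))

#' @rdname accessors
#' @export
setGeneric("downstreamGenes",
           function(object) standardGeneric("downstreamGenes"))

#' @rdname accessors
#' @export
setGeneric("downstreamSigns",
           function(object) standardGeneric("downstreamSigns"))

#' @rdname accessors
#' @export
setGeneric("evidence", function(object) standardGeneric("evidence"))

#' @rdname accessors
#' @export
setGeneric("droppedAmbiguous",
           function(object) standardGeneric("droppedAmbiguous"))

#' @rdname accessors
#' @export
setGeneric("hypSize", function(object) standardGeneric("hypSize"))

#' @rdname accessors
#' @export
setGeneric("contrastName", function(object) standardGeneric("contrastName"))

#' @rdname accessors
#' @export
setGeneric("contrastData", function(object) standardGeneric("contrastData"))

#' @rdname accessors
#' @export
setGeneric("scoreValue", function(object) standardGeneric("scoreValue"))

#' @rdname accessors
#' @export
setGeneric("confint2", function(object) standardGeneric("confint2"))

#' @rdname accessors
#' @export
setGeneric("cadres", function(object) standardGeneric("cadres"))

#' @rdname accessors
#' @export
setMethod("upstream", "Hyp", function(object) object@upstream)

#' @rdname accessors
#' @export
setMethod("downstreamGenes", "Hyp", function(object) object@gene)

#' @rdname accessors
#' @export
setMethod("downstreamSigns", "Hyp", function(object)
  stats::setNames(object@sign, object@gene))

#' @rdname accessors
#' @export
setMethod("evidence", "Hyp", function(object)
  stats::setNames(object@evidence, object@gene))

#' @rdname accessors
#' @export
setMethod("droppedAmbiguous", "Hyp", function(object)
  object@droppedAmbiguous)

#' @rdname accessors
#' @export
setMethod("hypSize", "Hyp", function(object) length(object@gene))

#' @rdname accessors
#' @export
setMethod("contrastName", "Contrast", function(object) object@name)

#' @rdname accessors
#' @export
setMethod("contrastData", "Contrast", function(object) object@data)

#' @rdname accessors
#' @export
setMethod("scoreValue", "NPAResult", function(object) object@value)

#' @rdname accessors
#' @export
setMethod("confint2", "NPAResult", function(object)
  c(low = object@ciLow, high = object@ciHigh))

#' @rdname accessors
#' @export
setMethod("cadres", "CadreIndex", function(object) object@cadres)
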