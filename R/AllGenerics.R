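#' @rdname EnzymeConstrainedModel-class
#' @param x,object an object.
#' @export
setGeneric("metaboliteIds", function(x) standardGeneric("metaboliteIds"))

#' @rdname EnzymeConstrainedModel-class
#' @export
setGeneric("reactionIds", function(x) standardGeneric("reactionIds"))

#' @rdname EnzymeConstrainedModel-class
#' @export
setGeneric("enzymeIds", function(x) standardGeneric("enzymeIds"))

#' @rdname EnzymeConstrainedModel-class
#' @export
setGeneric("stoichMatrix", function(x) standardGeneric("stoichMatrix"))

#' @rdname EnzymeConstrainedModel-class
#' @export
setGeneric("kcatMatrix", function(x) standardGeneric("kcatMatrix"))

#' @rdname EnzymeConstrainedModel-class
#' @export
setGeneric("biomassReaction", function(x) standardGeneric("biomassReaction"))

#' @rdname EnzymeConstrainedModel-class
#' @export
setGeneric("fluxBounds", function(x) standardGeneric("fluxBounds"))

#' @rdname EnzymeConstrainedModel-class
#' @export
setGeneric("poolTotal", function(x) standardGeneric("poolTotal"))

#' @rdname EnzymeConstrainedModel-class
#' @param value replacement value.
#' @export
setGeneric("poolTotal<-", function(x, value) standardGeneric("poolTotal<-"))

#' @rdname EnzymeConstrainedModel-class
#' @export
setGeneric("enzymeBounds", function(x) standardGeneric("enzymeBounds"))

#' @rdname EnzymeConstrainedModel-class
#' @export
setGeneric("enzymeBounds<-",
           function(x, value) standardGeneric("enzymeBounds<-"))

#' @rdname EnzymeAllocation-class
#' @param x an object.
#' @export
setGeneric("allocationValues",
           function(x) standardGeneric("allocationValues"))

#' @rdname EnzymeAllocation-class
#' @export
setGeneric("allocationTotal", function(x) standardGeneric("allocationTotal"))

#' @rdname SolveResult-class
#' @param x an object.
#' @export
setGeneric("predictedAllocation",
           function(x) standardGeneric("predictedAllocation"))

#' @rdname SolveResult-class
#' @export
setGeneric("fluxes", function(x) standardGeneric("fluxes"))

#' @rdname SolveResult-class
#' @export
setGeneric("objectiveValue", function(x) standardGeneric("objectiveValue"))

#' @rdname SolveResult-class
#' @export
setGeneric("solveStatus", function(x) standardGeneric("solveStatus"))
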