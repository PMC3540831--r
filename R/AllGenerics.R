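#' @rdname geneCircuit-accessors
#' @export
setGeneric("nGenes", function(x) standardGeneric("nGenes"))

#' @rdname geneCircuit-accessors
#' @export
setGeneric("geneNames", function(x) standardGeneric("geneNames"))

#' @rdname geneCircuit-accessors
#' @export
setGeneric("wMatrix", function(x) standardGeneric("wMatrix"))

#' @rdname geneCircuit-accessors
#' @export
setGeneric("maternalCount", function(x) standardGeneric("maternalCount"))

#' @rdname geneCircuit-accessors
#' @export
setGeneric("obligatoryCount", function(x) standardGeneric("obligatoryCount"))

#' @rdname positions-accessors
#' @export
setGeneric("positions", function(x) standardGeneric("positions"))

#' @rdname positions-accessors
#' @export
setGeneric("profiles", function(x) standardGeneric("profiles"))

#' @rdname positions-accessors
#' @export
setGeneric("bcdProfile", function(x) standardGeneric("bcdProfile"))

#' @rdname positions-accessors
#' @export
setGeneric("cadProfile", function(x) standardGeneric("cadProfile"))

#' @rdname expressionState-accessors
#' @export
setGeneric("concentrations", function(x) standardGeneric("concentrations"))

#' @rdname expressionState-accessors
#' @export
setGeneric("simTime", function(x) standardGeneric("simTime"))

#' @rdname evolutionResult-accessors
#' @export
setGeneric("bestIndividual", function(x) standardGeneric("bestIndividual"))

#' @rdname evolutionResult-accessors
#' @export
setGeneric("runLog", function(x) standardGeneric("runLog"))

#' @rdname evolutionResult-accessors
#' @export
setGeneric("succeeded", function(x) standardGeneric("succeeded"))

#' @rdname evolutionResult-accessors
#' @export
setGeneric("evaluationsUsed", function(x) standardGeneric("evaluationsUsed"))
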