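#' Accessors for GeneCircuit objects
#'
#' @param x a \linkS4class{GeneCircuit}
#' @return \code{nGenes}: integer gene count; \code{geneNames}: character
#'   vector; \code{wMatrix}: the interaction matrix with dimnames
#'   (regulators in columns); \code{maternalCount}, \code{obligatoryCount}:
#'   integers.
#' @name geneCircuit-accessors
NULL

#' @rdname geneCircuit-accessors
#' @export
setMethod("nGenes", "GeneCircuit", function(x) nrow(x@W))

#' @rdname geneCircuit-accessors
#' @export
setMethod("geneNames", "GeneCircuit", function(x) x@geneNames)

#' @rdname geneCircuit-accessors
#' @export
setMethod("wMatrix", "GeneCircuit", function(x) {
  W <- x@W
  dimnames(W) <- list(x@geneNames,
                      c(c("Bcd", "Cad")[seq_len(x@nMaternal)], x@geneNames))
  W
})

#' @rdname geneCircuit-accessors
#' @export
setMethod("maternalCount", "GeneCircuit", function(x) x@nMaternal)

#' @rdname geneCircuit-accessors
#' @export
setMethod("obligatoryCount", "GeneCircuit", function(x) x@obligatory)

#' Accessors for grid-based objects
#'
#' @param x a \linkS4class{MaternalInputs} or \linkS4class{TargetPatterns}
#' @return \code{positions}: numeric %EL positions; \code{profiles}: named
#'   list of target profiles; \code{bcdProfile}/\code{cadProfile}: numeric
#'   maternal profiles (\code{cadProfile} is \code{NULL} for Bcd-only inputs).
#' @name positions-accessors
NULL

#' @rdname positions-accessors
#' @export
setMethod("positions", "MaternalInputs", function(x) x@positions)

#' @rdname positions-accessors
#' @export
setMethod("positions", "TargetPatterns", function(x) x@positions)

#' @rdname positions-accessors
#' @export
setMethod("profiles", "TargetPatterns", function(x) x@profiles)

#' @rdname positions-accessors
#' @export
setMethod("bcdProfile", "MaternalInputs", function(x) x@bcd)

#' @rdname positions-accessors
#' @export
setMethod("cadProfile", "MaternalInputs",
          function(x) if (length(x@cad)) x@cad else NULL)

#' Accessors for ExpressionState
#'
#' @param x an \linkS4class{ExpressionState}
#' @return \code{concentrations}: the gene x nucleus matrix; \code{simTime}:
#'   the simulation time.
#' @name expressionState-accessors
NULL

#' @rdname expressionState-accessors
#' @export
setMethod("concentrations", "ExpressionState", function(x) x@v)

#' @rdname expressionState-accessors
#' @export
setMethod("simTime", "ExpressionState", function(x) x@t)

#' Accessors for EvolutionResult
#'
#' @param x an \linkS4class{EvolutionResult}
#' @return \code{bestIndividual}: list with elements \code{W}, \code{marks}
#'   and \code{E}; \code{runLog}: per-generation data.frame; \code{succeeded}:
#'   logical; \code{evaluationsUsed}: integer.
#' @name evolutionResult-accessors
NULL

#' @rdname evolutionResult-accessors
#' @export
setMethod("bestIndividual", "EvolutionResult", function(x) x@best)

#' @rdname evolutionResult-accessors
#' @export
setMethod("runLog", "EvolutionResult", function(x) x@log)

#' @rdname evolutionResult-accessors
#' @export
setMethod("succeeded", "EvolutionResult", function(x) x@success)

#' @rdname evolutionResult-accessors
#' @export
setMethod("evaluationsUsed", "EvolutionResult", function(x) x@evaluations)

setMethod("show", "GeneCircuit", function(object) {
  cat(sprintf("GeneCircuit: %d genes (%d obligatory), %d maternal input%s\n",
              nGenes(object), object@obligatory, object@nMaternal,
              if (object@nMaternal > 1L) "s" else ""))
  cat("  genes:", paste(object@geneNames, collapse = ", "), "\n")
  cat(sprintf("  W range: [%.3g, %.3g]\n", min(object@W), max(object@W)))
})

setMethod("show", "MaternalInputs", function(object) {
  cat(sprintf("MaternalInputs on %d nuclei (%.4g-%.4g %%EL): Bcd%s\n",
              length(object@positions), min(object@positions),
              max(object@positions),
              if (length(object@cad)) " + Cad" else ""))
})

setMethod("show", "TargetPatterns", function(object) {
  cat(sprintf("TargetPatterns on %d nuclei: %s\n", length(object@positions),
              paste(names(object@profiles), collapse = ", ")))
})

setMethod("show", "ExpressionState", function(object) {
  cat(sprintf("ExpressionState: %d genes x %d nuclei at t = %.4g\n",
              nrow(object@v), ncol(object@v), object@t))
})

setMethod("show", "EvolutionResult", function(object) {
  cat(sprintf(
    "EvolutionResult: %s after %d generations, %d evaluations (best E = %.5g)\n",
    if (object@success) "converged" else "stopped", object@generations,
    object@evaluations, object@best$E))
})
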