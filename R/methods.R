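#' @describeIn ComplementMatrix-class the species x counts table.
#' @param x,object a \linkS4class{ComplementMatrix}.
#' @export
setGeneric("complementTable", function(x) standardGeneric("complementTable"))

#' @export
setMethod("complementTable", "ComplementMatrix", function(x) x@table)

#' @describeIn ComplementMatrix-class QC side table of rejected records.
#' @export
setGeneric("rejectedCalls", function(x) standardGeneric("rejectedCalls"))

#' @export
setMethod("rejectedCalls", "ComplementMatrix", function(x) x@qc)

#' @describeIn ComplementMatrix-class provenance flag.
#' @export
setGeneric("provenance", function(x) standardGeneric("provenance"))

#' @export
setMethod("provenance", "ComplementMatrix", function(x) x@provenance)

setMethod("show", "ComplementMatrix", function(object) {
  cat(sprintf("ComplementMatrix (%s): %d species, %d rejected records in QC\n",
              object@provenance, nrow(object@table), nrow(object@qc)))
  print(utils::head(object@table, 6))
  if (nrow(object@table) > 6) cat("...\n")
})

#' @describeIn SimilarityGraph-class component membership per node.
#' @param x,object a \linkS4class{SimilarityGraph}.
#' @export
setGeneric("componentMembership", function(x) standardGeneric("componentMembership"))

#' @export
setMethod("componentMembership", "SimilarityGraph", function(x) x@membership)

#' @describeIn SimilarityGraph-class the retained edges.
#' @export
setGeneric("graphEdges", function(x) standardGeneric("graphEdges"))

#' @export
setMethod("graphEdges", "SimilarityGraph", function(x) x@edges)

setMethod("show", "SimilarityGraph", function(object) {
  cat(sprintf("SimilarityGraph: %d nodes, %d edges at threshold %.3g (%s), %d components\n",
              length(object@nodes), nrow(object@edges), object@threshold,
              object@normalization, length(unique(object@membership))))
})

#' @describeIn DolloReconstruction-class states per ape node number.
#' @param x,object a reconstruction object.
#' @export
setGeneric("nodeStates", function(x) standardGeneric("nodeStates"))

#' @export
setMethod("nodeStates", "DolloReconstruction", function(x) x@nodeStates)

#' @export
setMethod("nodeStates", "SankoffReconstruction", function(x) x@nodeCounts)

#' @describeIn SankoffReconstruction-class edges with a count change.
#' @export
setGeneric("countEvents", function(x) standardGeneric("countEvents"))

#' @export
setMethod("countEvents", "SankoffReconstruction", function(x) x@events)

#' @describeIn DolloReconstruction-class loss edges.
#' @export
setGeneric("lossEdges", function(x) standardGeneric("lossEdges"))

#' @export
setMethod("lossEdges", "DolloReconstruction", function(x) x@lossEdges)

#' @describeIn DolloReconstruction-class ape node number of the gain.
#' @export
setGeneric("gainNode", function(x) standardGeneric("gainNode"))

#' @export
setMethod("gainNode", "DolloReconstruction", function(x) x@gainNode)

setMethod("show", "DolloReconstruction", function(object) {
  cat(sprintf("DolloReconstruction of %s: gain at node %d (%s), %d loss edge(s)\n",
              object@character, object@gainNode,
              .nodeLabel(object@tree, object@gainNode), nrow(object@lossEdges)))
})

setMethod("show", "SankoffReconstruction", function(object) {
  root <- ape::Ntip(object@tree) + 1L
  cat(sprintf("SankoffReconstruction of %s: root count %d, total cost %g, %d change edge(s)\n",
              object@character, object@nodeCounts[root], object@totalCost,
              nrow(object@events)))
})

setMethod("show", "ArchitectureSpec", function(object) {
  sig <- architectureSignature(object)
  cat(sprintf("ArchitectureSpec '%s' [%s]%s\n", object@label, sig,
              if (object@isFullLength) "" else " (partial)"))
})

setMethod("show", "SpeciesFixtureSpec", function(object) {
  cat(sprintf("SpeciesFixtureSpec %s (%s): %d receptor, %d ligand, %d decoy spec(s)\n",
              object@species, object@clade, length(object@receptorSpecs),
              length(object@ligandSpecs), length(object@decoySpecs)))
})

setMethod("show", "ScanProfile", function(object) {
  cat(sprintf(paste0("ScanProfile: TM window %d @ %.2f (min len %d); SP first %d res,",
                     " stretch >= %d @ %.2f, start <= %d;\n  Cys window %d >= %d;",
                     " EGF gaps [%s]-[%s]; Ig tag <= %d mismatches\n"),
              object@tmWindow, object@tmThreshold, object@tmMinLen,
              object@spSearchLen, object@spMinLen, object@spThreshold,
              object@spMaxStart, object@cysWindow, object@cysMin,
              paste(object@egfGapMin, collapse = ","),
              paste(object@egfGapMax, collapse = ","),
              object@igMaxMismatch))
})
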