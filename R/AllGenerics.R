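#' @rdname CodonProfileSet-class
#' @param object,x A `CodonProfileSet`.
#' @export
setGeneric("profileCounts", function(x) standardGeneric("profileCounts"))

#' @rdname CodonProfileSet-class
#' @export
setGeneric("cdsSequences", function(x) standardGeneric("cdsSequences"))

#' @rdname CodonProfileSet-class
#' @export
setGeneric("orfIds", function(x) standardGeneric("orfIds"))

#' @rdname CodonProfileSet-class
#' @export
setGeneric("codonLengths", function(x) standardGeneric("codonLengths"))

#' @rdname TpmPartition-class
#' @export
setGeneric("tpmValues", function(x) standardGeneric("tpmValues"))

#' @rdname TpmPartition-class
#' @export
setGeneric("binAssignments", function(x) standardGeneric("binAssignments"))

#' @rdname TpmPartition-class
#' @export
setGeneric("binEdges", function(x) standardGeneric("binEdges"))

#' @rdname PauseCallSet-class
#' @export
setGeneric("pauseCalls", function(x) standardGeneric("pauseCalls"))

#' @rdname PauseCallSet-class
#' @export
setGeneric("pauseSites", function(x) standardGeneric("pauseSites"))

#' @rdname PauseCallSet-class
#' @export
setGeneric("callParams", function(x) standardGeneric("callParams"))

# ---- methods ----------------------------------------------------------------

#' @rdname CodonProfileSet-class
#' @export
setMethod("profileCounts", "CodonProfileSet", function(x) x@counts)

#' @rdname CodonProfileSet-class
#' @export
setMethod("cdsSequences", "CodonProfileSet", function(x) x@sequences)

#' @rdname CodonProfileSet-class
#' @export
setMethod("orfIds", "CodonProfileSet", function(x) names(x@counts))

#' @rdname CodonProfileSet-class
#' @export
setMethod("codonLengths", "CodonProfileSet",
          function(x) vapply(x@counts, length, integer(1)))

#' @rdname TpmPartition-class
#' @export
setMethod("tpmValues", "TpmPartition", function(x) x@tpm)

#' @rdname TpmPartition-class
#' @export
setMethod("binAssignments", "TpmPartition", function(x) x@bin)

#' @rdname TpmPartition-class
#' @export
setMethod("binEdges", "TpmPartition", function(x) x@binEdges)

#' @rdname PauseCallSet-class
#' @export
setMethod("pauseCalls", "PauseCallSet", function(x) x@calls)

#' @rdname PauseCallSet-class
#' @export
setMethod("pauseSites", "PauseCallSet",
          function(x) x@calls[x@calls$is_pause, , drop = FALSE])

#' @rdname PauseCallSet-class
#' @export
setMethod("callParams", "PauseCallSet", function(x) x@params)

setMethod("show", "CodonProfileSet", function(object) {
  L <- codonLengths(object)
  cat(sprintf("CodonProfileSet with %d ORFs (median length %s codons)\n",
              length(L), if (length(L)) stats::median(L) else NA))
  if (!is.null(object@sequences) && length(object@sequences))
    cat(sprintf("  coding sequences attached for %d ORFs\n",
                length(object@sequences)))
})

setMethod("show", "TpmPartition", function(object) {
  nb <- length(object@binEdges) - 1L
  cat(sprintf("TpmPartition: %d ORFs in %d expression bins\n",
              length(object@tpm), nb))
  print(table(bin = object@bin))
})

setMethod("show", "EifModel", function(object) {
  cat(sprintf(
    "EifModel: %d trees, psi = %d, max depth = %d, d = %d, seed = %s\n",
    object@nTrees, object@psi, object@maxDepth, object@d,
    format(object@seed)))
})

setMethod("show", "PauseCallSet", function(object) {
  cat(sprintf("PauseCallSet: %d scored codons, %d pausing peaks (%d bins)\n",
              nrow(object@calls), sum(object@calls$is_pause),
              length(unique(object@calls$bin))))
})

#' @export
setMethod("length", "CodonProfileSet", function(x) length(x@counts))
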