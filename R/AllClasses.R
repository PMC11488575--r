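#' CodonProfileSet: per-codon footprint counts for a set of ORFs
#'
#' Container for codon-level ribosome footprint coverage. Each ORF is a
#' numeric vector of non-negative counts, one entry per sense codon of the
#' coding sequence (the stop codon is excluded from the length). Optionally
#' carries the coding sequences (including the stop codon) as a
#' [Biostrings::DNAStringSet].
#'
#' @slot counts Named list of non-negative numeric vectors, one per ORF.
#' @slot sequences A `DNAStringSet` of coding sequences, or of length 0.
#' @export
setClass("CodonProfileSet",
  representation(counts = "list", sequences = "ANY"),
  prototype(counts = list(), sequences = NULL)
)

setValidity("CodonProfileSet", function(object) {
  cts <- object@counts
  if (length(cts) && is.null(names(cts)))
    return("counts must be a named list (ORF ids)")
  if (anyDuplicated(names(cts)))
    return("duplicated ORF ids in counts")
  bad <- vapply(cts, function(v) !is.numeric(v) || length(v) < 1L ||
                  anyNA(v) || any(v < 0), logical(1))
  if (any(bad))
    return(sprintf("counts for %s must be non-negative numeric vectors",
                   paste(head(names(cts)[bad], 3), collapse = ", ")))
  sq <- object@sequences
  if (!is.null(sq) && length(sq)) {
    if (!methods::is(sq, "DNAStringSet"))
      return("sequences must be a DNAStringSet or NULL")
    shared <- intersect(names(cts), names(sq))
    lens <- Biostrings::width(sq)[match(shared, names(sq))]
    L <- vapply(cts[shared], length, integer(1))
    # sequence carries the stop codon; counts do not
    if (any(lens != 3L * (L + 1L) & lens != 3L * L))
      return("sequence lengths disagree with codon counts (expect 3*L or 3*(L+1) nt)")
  }
  TRUE
})

#' TpmPartition: expression-quantile assignment of ORFs
#'
#' Result of partitioning ORFs into expression bins by TPM quantiles.
#'
#' @slot tpm Named numeric vector of TPM values (sums to 1e6).
#' @slot binEdges Numeric vector of quantile boundaries (length nBins + 1).
#' @slot bin Named integer vector, bin index in 0..(nBins-1) per ORF.
#' @export
setClass("TpmPartition",
  representation(tpm = "numeric", binEdges = "numeric", bin = "integer")
)

setValidity("TpmPartition", function(object) {
  if (length(object@tpm) != length(object@bin))
    return("tpm and bin must have the same length")
  if (!identical(names(object@tpm), names(object@bin)))
    return("tpm and bin must share names")
  if (length(object@tpm) &&
      abs(sum(object@tpm) - 1e6) > 1e-6 * 1e6)
    return("tpm must sum to 1e6")
  nb <- length(object@binEdges) - 1L
  if (length(object@bin) && (min(object@bin) < 0L || max(object@bin) >= nb))
    return("bin indices out of range")
  TRUE
})

#' EifModel: a fitted extended isolation forest
#'
#' Ensemble of randomized hyperplane-split trees over d-dimensional points.
#' Each internal node holds a normal vector and an intercept point; a query
#' descends left when `(x - p) . n <= 0`. Leaves record their training point
#' count, used for the standard path-length adjustment.
#'
#' @slot trees List of trees (each a list of flat node arrays).
#' @slot nTrees Number of trees.
#' @slot psi Subsample size used per tree.
#' @slot maxDepth Depth limit, `ceiling(log2(psi))`.
#' @slot d Dimensionality of the training points.
#' @slot seed Integer seed the forest was grown from.
#' @export
setClass("EifModel",
  representation(trees = "list", nTrees = "integer", psi = "integer",
                 maxDepth = "integer", d = "integer", seed = "numeric")
)

setValidity("EifModel", function(object) {
  if (object@nTrees < 1L) return("nTrees must be >= 1")
  if (object@psi < 2L) return("psi must be >= 2")
  if (length(object@trees) != object@nTrees)
    return("length(trees) != nTrees")
  TRUE
})

#' PauseCallSet: scored codons with pause labels
#'
#' @slot calls data.frame with columns orf_id, codon_index (0-based P-site
#'   codon), score, is_pause, bin.
#' @slot params List of the calling parameters (nTrees, thresholdQuantile,
#'   seed, psi per bin).
#' @slot binSummary data.frame of per-bin codon counts, thresholds and flag
#'   counts.
#' @export
setClass("PauseCallSet",
  representation(calls = "data.frame", params = "list",
                 binSummary = "data.frame")
)

setValidity("PauseCallSet", function(object) {
  need <- c("orf_id", "codon_index", "score", "is_pause", "bin")
  if (!all(need %in% names(object@calls)))
    return(sprintf("calls must have columns %s", paste(need, collapse = ", ")))
  if (nrow(object@calls) && any(!is.finite(object@calls$score)))
    return("scores must be finite")
  TRUE
})
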