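#' Construct a CodonProfileSet
#'
#' @param counts Named list of non-negative per-codon count vectors (one per
#'   ORF, stop codon excluded), or a data.frame with columns
#'   `orf_id`, `codon_index` (0-based) and `count`.
#' @param sequences Optional `DNAStringSet` (or named character vector) of
#'   coding sequences; may include the stop codon.
#' @return A [CodonProfileSet-class] object.
#' @export
CodonProfileSet <- function(counts, sequences = NULL) {
  if (is.data.frame(counts)) counts <- .countsFromTable(counts)
  if (!is.null(sequences) && !methods::is(sequences, "DNAStringSet"))
    sequences <- Biostrings::DNAStringSet(sequences)
  methods::new("CodonProfileSet", counts = counts, sequences = sequences)
}

.countsFromTable <- function(df) {
  need <- c("orf_id", "codon_index", "count")
  if (!all(need %in% names(df)))
    stop("counts table needs columns: ", paste(need, collapse = ", "))
  split_idx <- split(seq_len(nrow(df)), df$orf_id)
  lapply(split_idx, function(i) {
    L <- max(df$codon_index[i]) + 1L
    v <- numeric(L)
    v[df$codon_index[i] + 1L] <- df$count[i]
    v
  })
}

.asCountsList <- function(profiles) {
  if (methods::is(profiles, "CodonProfileSet")) return(profileCounts(profiles))
  if (is.data.frame(profiles)) return(.countsFromTable(profiles))
  if (!is.list(profiles) || is.null(names(profiles)))
    stop("profiles must be a CodonProfileSet or a named list of count vectors")
  profiles
}

#' Transcripts-per-million from codon-level counts
#'
#' TPM for ORF i is `total_i / (L_i * 3 / 1000)` rescaled so that the values
#' sum to one million. Length is the sense-codon count of the ORF (stop
#' excluded).
#'
#' @param profiles A [CodonProfileSet-class], named list of count vectors, or
#'   long-format counts data.frame.
#' @return Named numeric vector of TPM values summing to 1e6.
#' @export
computeTpm <- function(profiles) {
  counts <- .asCountsList(profiles)
  totals <- vapply(counts, sum, numeric(1))
  if (all(totals == 0)) stop("no reads: all ORFs have zero total counts")
  L <- vapply(counts, length, numeric(1))
  rate <- totals / (L * 3 / 1000)
  rate / sum(rate) * 1e6
}

#' Normalize one codon-level profile
#'
#' Divides the per-codon counts by the ORF mean count and attaches the
#' normalized codon position `x_i = (i + 1) / L` (0-based i), which maps the
#' ramp-affected termini of ORFs of any length onto comparable coordinates.
#'
#' @param counts Numeric vector of per-codon counts with positive total.
#' @param orfId Optional ORF identifier recorded in the result.
#' @return List with elements `orf_id`, `u` (normalized counts, mean 1) and
#'   `x` (normalized positions in (0, 1]).
#' @export
normalizeProfile <- function(counts, orfId = NA_character_) {
  L <- length(counts)
  if (L == 0L) stop("empty profile (L == 0)")
  if (sum(counts) <= 0) stop("zero-coverage profile cannot be normalized")
  list(orf_id = orfId,
       u = counts / mean(counts),
       x = seq_len(L) / L)
}

#' Partition ORFs into expression-quantile bins
#'
#' Assigns each ORF to one of `nBins` TPM quantile intervals
#' ((0-20\%), \[20-40\%), ..., \[80-100\%] for the default five bins).
#' Quantiles use linear interpolation; a TPM equal to an interior bin edge is
#' assigned to the lower bin, which makes the partition deterministic and
#' independent of input order.
#'
#' @param tpm Named numeric vector of TPM values (see [computeTpm()]).
#' @param nBins Number of quantile bins (default 5).
#' @return A [TpmPartition-class] object.
#' @export
partitionByTpm <- function(tpm, nBins = 5L) {
  if (is.null(names(tpm))) stop("tpm must be named by ORF id")
  keep <- tpm > 0
  if (!all(keep)) {
    message(sum(!keep), " ORFs with zero TPM dropped before binning")
    tpm <- tpm[keep]
  }
  if (length(tpm) < nBins)
    stop("fewer ORFs (", length(tpm), ") than bins (", nBins, ")")
  edges <- stats::quantile(tpm, probs = seq(0, 1, length.out = nBins + 1L),
                           names = FALSE, type = 7)
  if (edges[1] == edges[length(edges)]) {
    warning("degenerate TPM distribution: all ORFs fall in one bin")
    bin <- setNames(rep(0L, length(tpm)), names(tpm))
    return(methods::new("TpmPartition", tpm = tpm, binEdges = edges, bin = bin))
  }
  # value == interior edge goes to the lower bin: intervals (e_k, e_{k+1}]
  bin <- findInterval(tpm, edges, left.open = TRUE, all.inside = TRUE) - 1L
  bin <- setNames(as.integer(bin), names(tpm))
  methods::new("TpmPartition", tpm = tpm, binEdges = edges, bin = bin)
}

#' Drop low-coverage ORFs
#'
#' Removes ORFs whose mean per-codon count falls below a threshold.
#' Zero-coverage ORFs are always removed (they cannot be normalized); the
#' threshold defaults to 0, i.e. keep every ORF with at least one read.
#'
#' @param profiles Named list of count vectors or [CodonProfileSet-class].
#' @param minMeanCoverage Minimum mean count per codon (default 0).
#' @return Named list of count vectors passing the filter.
#' @export
filterProfiles <- function(profiles, minMeanCoverage = 0) {
  counts <- .asCountsList(profiles)
  keep <- vapply(counts, function(v) sum(v) > 0 && mean(v) >= minMeanCoverage,
                 logical(1))
  counts[keep]
}

# ---- text-format I/O --------------------------------------------------------

#' Read codon-level counts from TSV
#'
#' Expects a header `orf_id  codon_index  count` with 0-based codon indices.
#'
#' @param path Path to the TSV file.
#' @return Named list of per-codon count vectors.
#' @export
readCodonCounts <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  .countsFromTable(df)
}

#' Write codon-level counts to TSV
#'
#' @param counts Named list of per-codon count vectors (or CodonProfileSet).
#' @param path Output path.
#' @export
writeCodonCounts <- function(counts, path) {
  counts <- .asCountsList(counts)
  df <- data.frame(
    orf_id = rep(names(counts), lengths(counts)),
    codon_index = unlist(lapply(counts, function(v) seq_along(v) - 1L),
                         use.names = FALSE),
    count = unlist(counts, use.names = FALSE))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read coding sequences from FASTA
#'
#' @param path FASTA of CDS (lengths divisible by 3).
#' @return A `DNAStringSet`.
#' @export
readCds <- function(path) {
  sq <- Biostrings::readDNAStringSet(path)
  names(sq) <- sub("\\s.*$", "", names(sq))
  if (any(Biostrings::width(sq) %% 3L != 0L))
    stop("CDS lengths must be divisible by 3")
  sq
}

#' Write a TPM partition to TSV (`orf_id  tpm  bin`)
#'
#' @param partition A [TpmPartition-class].
#' @param path Output path.
#' @export
writeTpmPartition <- function(partition, path) {
  df <- data.frame(orf_id = names(tpmValues(partition)),
                   tpm = unname(tpmValues(partition)),
                   bin = unname(binAssignments(partition)))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
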