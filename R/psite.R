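#' Read an aligned-read table (`orf_id  five_prime_offset  length`)
#'
#' Positions are nucleotide offsets of the read 5' end relative to the A of
#' the initiation ATG (0-based; negative values lie upstream of the start
#' codon).
#'
#' @param path TSV path with the header above.
#' @return data.frame with those three columns.
#' @export
readReadTable <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("orf_id", "five_prime_offset", "length")
  if (!all(need %in% names(df)))
    stop("read table needs columns: ", paste(need, collapse = ", "))
  df
}

#' Retain read lengths with clear 3-nt periodicity
#'
#' A footprint length is kept when the fraction of its reads whose 5' end
#' falls in the modal reading frame reaches `threshold`. "Clear 3-nt
#' periodicity" is a qualitative criterion; it is quantified here as a
#' modal-frame fraction of at least 0.6 by default.
#'
#' @param reads data.frame as from [readReadTable()].
#' @param minReads Minimum reads required to evaluate a length (default 100).
#' @param threshold Modal-frame fraction required (default 0.6).
#' @param lengthRange Allowed footprint lengths (default 17:34 nt).
#' @return Integer vector of retained read lengths.
#' @export
periodicityFilter <- function(reads, minReads = 100L, threshold = 0.6,
                              lengthRange = 17:34) {
  if (!nrow(reads)) stop("empty read table")
  reads <- reads[reads$length %in% lengthRange, , drop = FALSE]
  kept <- integer(0)
  for (len in sort(unique(reads$length))) {
    sub <- reads[reads$length == len, , drop = FALSE]
    if (nrow(sub) < minReads) next
    frames <- table(factor(((sub$five_prime_offset %% 3L) + 3L) %% 3L,
                           levels = 0:2))
    if (max(frames) / sum(frames) >= threshold) kept <- c(kept, len)
  }
  kept
}

#' Estimate the P-site offset for one read length
#'
#' Offset is the modal distance from a read's 5' end to the initiation
#' codon, taken over reads whose 5' end lies upstream of the ATG (the
#' initiating ribosome has the start codon in its P site). Ties are broken
#' toward the smaller offset.
#'
#' @param reads data.frame as from [readReadTable()].
#' @param length Footprint length to estimate for.
#' @return Integer P-site offset in nucleotides.
#' @export
estimatePsiteOffset <- function(reads, length) {
  sub <- reads[reads$length == length & reads$five_prime_offset < 0, ,
               drop = FALSE]
  if (!nrow(sub))
    stop("no initiation-proximal reads for length ", length)
  cand <- -sub$five_prime_offset
  tab <- table(cand)
  best <- as.integer(names(tab)[tab == max(tab)])
  min(best)
}

#' Annotate reads to codon-level counts with P-site offsets
#'
#' Each read contributes one count to the codon
#' `floor((five_prime_offset + offset[length]) / 3)`. Reads of lengths
#' without an offset, or whose P site falls outside the CDS, are dropped and
#' summarized in a message.
#'
#' @param reads data.frame as from [readReadTable()].
#' @param offsets Named integer vector, P-site offset (nt) per read length.
#' @param orfLengths Named integer vector of ORF lengths in codons (stop
#'   excluded).
#' @return Named list of per-codon count vectors (all ORFs in `orfLengths`,
#'   zero-filled), with a `dropped` attribute holding the drop counts.
#' @export
annotateCodonCounts <- function(reads, offsets, orfLengths) {
  lenKnown <- reads$length %in% as.integer(names(offsets))
  nBadLen <- sum(!lenKnown)
  reads <- reads[lenKnown, , drop = FALSE]
  if (!nrow(reads)) warning("no reads from retained lengths; empty profiles")
  codon <- if (nrow(reads)) {
    floor((reads$five_prime_offset +
             offsets[as.character(reads$length)]) / 3)
  } else integer(0)
  Lmap <- orfLengths[reads$orf_id]
  inCds <- !is.na(Lmap) & codon >= 0 & codon < Lmap
  nOut <- sum(!inCds)
  counts <- lapply(orfLengths, function(L) numeric(L))
  if (any(inCds)) {
    tab <- table(paste(reads$orf_id[inCds], codon[inCds]))
    key <- strsplit(names(tab), " ")
    for (i in seq_along(tab)) {
      id <- key[[i]][1]
      counts[[id]][as.integer(key[[i]][2]) + 1L] <- as.numeric(tab[i])
    }
  }
  if (nBadLen + nOut > 0)
    message(nBadLen, " reads of excluded lengths and ", nOut,
            " reads outside the CDS dropped")
  attr(counts, "dropped") <- c(excluded_length = nBadLen, outside_cds = nOut)
  counts
}
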