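#' Call ribosome pausing peaks with per-bin extended isolation forests
#'
#' The core detection step. For each expression bin, the (normalized count,
#' normalized position) pairs of all codons of all ORFs in the bin are
#' stacked into one 2-D point set; an extended isolation forest is fitted
#' with subsample size `psi` equal to the rounded mean ORF length of the bin
#' (unless overridden), every codon is scored, and codons whose anomaly
#' score is at or above the `thresholdQuantile` of the bin's scores are
#' flagged as pausing peaks. The flagged codon is interpreted as the P-site
#' codon of the paused ribosome.
#'
#' @param profiles Named list of per-codon count vectors (raw or already
#'   normalized; each ORF is divided by its own mean), a
#'   [CodonProfileSet-class], or a long counts data.frame.
#' @param partition A [TpmPartition-class]; only ORFs present in both inputs
#'   are scored.
#' @param nTrees Trees per forest (default 200).
#' @param thresholdQuantile Score quantile above which a codon is a pausing
#'   peak (default 0.95; quantiles use linear interpolation and ties at the
#'   threshold are all flagged).
#' @param seed Integer seed; each bin uses an independent derived stream.
#' @param psi Optional fixed subsample size; default is the rounded mean ORF
#'   length per bin.
#' @return A [PauseCallSet-class].
#' @export
callPauses <- function(profiles, partition, nTrees = 200L,
                       thresholdQuantile = 0.95, seed = 1L, psi = NULL) {
  counts <- .asCountsList(profiles)
  bins <- binAssignments(partition)
  shared <- intersect(names(counts), names(bins))
  if (!length(shared)) stop("no ORFs shared between profiles and partition")
  counts <- counts[shared]
  bins <- bins[shared]

  callRows <- list()
  binRows <- list()
  psiUsed <- integer(0)
  for (b in sort(unique(bins))) {
    ids <- names(bins)[bins == b]
    if (length(ids) < 2L) {
      warning("bin ", b, " has fewer than 2 ORFs; skipped")
      next
    }
    norm <- lapply(ids, function(id) normalizeProfile(counts[[id]], id))
    u <- unlist(lapply(norm, `[[`, "u"), use.names = FALSE)
    x <- unlist(lapply(norm, `[[`, "x"), use.names = FALSE)
    L <- vapply(counts[ids], length, integer(1))
    pts <- cbind(u, x)
    psiBin <- if (is.null(psi)) as.integer(round(mean(L))) else as.integer(psi)
    psiBin <- max(2L, min(psiBin, nrow(pts)))
    model <- fitEif(pts, nTrees = nTrees, psi = psiBin,
                    seed = as.numeric(seed) + 1000003 * (b + 1))
    sc <- anomalyScore(model, pts)$score
    thr <- stats::quantile(sc, thresholdQuantile, names = FALSE, type = 7)
    flag <- sc >= thr
    callRows[[as.character(b)]] <- data.frame(
      orf_id = rep(ids, L),
      codon_index = unlist(lapply(L, function(l) seq_len(l) - 1L),
                           use.names = FALSE),
      score = sc, is_pause = flag, bin = b)
    binRows[[as.character(b)]] <- data.frame(
      bin = b, n_orfs = length(ids), n_codons = length(sc), psi = psiBin,
      threshold = thr, n_pauses = sum(flag))
    psiUsed[as.character(b)] <- psiBin
  }
  if (!length(callRows)) stop("no bin could be scored")
  methods::new("PauseCallSet",
    calls = do.call(rbind, unname(callRows)),
    params = list(nTrees = as.integer(nTrees),
                  thresholdQuantile = thresholdQuantile,
                  seed = as.numeric(seed), psi = psiUsed),
    binSummary = do.call(rbind, unname(binRows)))
}

#' Position-specific z-score pausing baseline
#'
#' The conventional pausing statistic the forest is compared against. Within
#' each expression bin, the mean and SD of the normalized counts at position
#' i are taken over all ORFs of the bin that reach position i, and
#' `z = (u - mean_i) / sd_i`. The last 10 codons of every ORF are excluded
#' (from both the statistics and the output) so stop-proximal coverage does
#' not enter the distributions. SD is the sample standard deviation
#' (denominator n - 1).
#'
#' @param profiles As in [callPauses()].
#' @param partition A [TpmPartition-class].
#' @param excludeLast Number of trailing codons to exclude (default 10).
#' @return data.frame with columns orf_id, codon_index, z (NA where the
#'   positional SD is zero or only one ORF covers the position), bin.
#' @export
zscoreBaseline <- function(profiles, partition, excludeLast = 10L) {
  counts <- .asCountsList(profiles)
  bins <- binAssignments(partition)
  shared <- intersect(names(counts), names(bins))
  counts <- counts[shared]
  bins <- bins[shared]

  out <- list()
  for (b in sort(unique(bins))) {
    ids <- names(bins)[bins == b]
    norm <- lapply(ids, function(id) normalizeProfile(counts[[id]], id))
    L <- vapply(counts[ids], length, integer(1))
    keepL <- pmax(0L, L - as.integer(excludeLast))
    if (all(keepL == 0L)) next
    u <- unlist(lapply(seq_along(ids),
                       function(k) norm[[k]]$u[seq_len(keepL[k])]),
                use.names = FALSE)
    pos <- unlist(lapply(keepL, function(l) seq_len(l) - 1L),
                  use.names = FALSE)
    id <- rep(ids, keepL)
    grp <- factor(pos)
    n_i <- as.vector(table(grp))[grp]
    mean_i <- ave(u, grp)
    # sample SD per position
    ssq <- ave((u - mean_i)^2, grp, FUN = sum)
    sd_i <- ifelse(n_i > 1L, sqrt(ssq / (n_i - 1L)), NA_real_)
    z <- ifelse(!is.na(sd_i) & sd_i > 0, (u - mean_i) / sd_i, NA_real_)
    out[[as.character(b)]] <- data.frame(
      orf_id = id, codon_index = pos, z = z, bin = b)
  }
  do.call(rbind, unname(out))
}

#' Fraction of pause sites carrying each codon at a ribosome site
#'
#' @param calls A [PauseCallSet-class].
#' @param sequences `DNAStringSet` (or named character) of coding sequences.
#' @param site Ribosome site read out relative to the flagged P-site codon:
#'   "E" (-1), "P" (0) or "A" (+1).
#' @return Named numeric vector over the 61 sense codons, summing to 1.
#'   Pause sites whose site codon falls outside the ORF are dropped (count
#'   reported via a message).
#' @export
pauseSiteCodonFraction <- function(calls, sequences, site = c("A", "P", "E")) {
  site <- match.arg(site)
  ps <- pauseSites(calls)
  cod <- .codonAt(ps$orf_id, ps$codon_index + .siteOffset(site), sequences)
  dropped <- sum(is.na(cod))
  if (dropped) message(dropped, " pause sites without a valid ", site,
                       "-site codon dropped")
  cod <- cod[!is.na(cod)]
  if (!length(cod)) stop("no pause sites with a valid site codon")
  universe <- senseCodons()
  tab <- table(factor(cod, levels = universe))
  as.numeric(tab) / sum(tab) -> frac
  setNames(frac, universe)
}

# codon (DNA 3-mer) of each (orf, codon index); NA outside the ORF
.codonAt <- function(orf, index, sequences) {
  chars <- .seqChar(sequences)
  s <- chars[orf]
  L <- nchar(s) %/% 3L  # includes the stop codon if present
  ok <- !is.na(s) & index >= 0L & index < L
  out <- rep(NA_character_, length(orf))
  out[ok] <- substr(s[ok], 3L * index[ok] + 1L, 3L * index[ok] + 3L)
  # never report a stop codon as a site codon
  out[out %in% c("TAA", "TAG", "TGA")] <- NA_character_
  out
}

.seqChar <- function(sequences) {
  if (methods::is(sequences, "DNAStringSet"))
    return(setNames(as.character(sequences), names(sequences)))
  if (is.character(sequences)) {
    if (is.null(names(sequences))) stop("sequences must be named")
    return(toupper(gsub("U", "T", sequences)))
  }
  if (methods::is(sequences, "CodonProfileSet"))
    return(.seqChar(cdsSequences(sequences)))
  stop("unsupported sequences object")
}

#' Pearson concordance of per-codon pause fractions between replicates
#'
#' @param fracs1,fracs2 Named fraction vectors from
#'   [pauseSiteCodonFraction()] (same codon universe).
#' @return Pearson correlation coefficient (NA with a warning if either
#'   vector has zero variance).
#' @export
replicateConcordance <- function(fracs1, fracs2) {
  shared <- intersect(names(fracs1), names(fracs2))
  if (length(shared) < 3L) stop("need a shared codon universe")
  x <- fracs1[shared]; y <- fracs2[shared]
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("zero variance; correlation undefined")
    return(NA_real_)
  }
  stats::cor(x, y)
}

#' Fraction of pause sites of one call set recovered in another
#'
#' @param calls1,calls2 [PauseCallSet-class] objects on the same translatome
#'   coordinates.
#' @return `|pause(calls1) intersect pause(calls2)| / |pause(calls1)|`.
#' @export
overlapFraction <- function(calls1, calls2) {
  p1 <- pauseSites(calls1)
  p2 <- pauseSites(calls2)
  if (!nrow(p1)) {
    warning("empty reference pause set; overlap undefined")
    return(NA_real_)
  }
  k1 <- paste(p1$orf_id, p1$codon_index)
  k2 <- paste(p2$orf_id, p2$codon_index)
  mean(k1 %in% k2)
}

#' Write pause calls as a BED-like TSV
#'
#' Columns `orf_id codon_start codon_end score is_pause bin` with 0-based,
#' half-open codon coordinates; optionally a JSON side-car with per-bin
#' summaries and the calling parameters.
#'
#' @param calls A [PauseCallSet-class].
#' @param path Output TSV path.
#' @param summaryPath Optional path for the JSON summary.
#' @export
writePauseCalls <- function(calls, path, summaryPath = NULL) {
  df <- pauseCalls(calls)
  out <- data.frame(orf_id = df$orf_id, codon_start = df$codon_index,
                    codon_end = df$codon_index + 1L, score = df$score,
                    is_pause = df$is_pause, bin = df$bin)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(summaryPath)) {
    jsonlite::write_json(list(params = callParams(calls),
                              bins = calls@binSummary),
                         summaryPath, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}
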