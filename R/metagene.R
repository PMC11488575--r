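# Metagene machinery: anchored averaging of a per-codon signal around a set
# of (orf, codon) anchors, with a seeded random-anchor bootstrap background.

# signalFn(orf_ids, codon_indices) -> numeric (NA where undefined/outside)
.metageneTrace <- function(anchors, orfLengths, window, signalFn,
                           backgroundDraws = 1000L, seed = 1L,
                           backgroundValue = NULL) {
  offsets <- seq(-window, window)
  value <- nn <- numeric(length(offsets))
  for (k in seq_along(offsets)) {
    pos <- anchors$codon_index + offsets[k]
    v <- signalFn(anchors$orf_id, pos)
    nn[k] <- sum(!is.na(v))
    value[k] <- if (nn[k]) mean(v, na.rm = TRUE) else NA_real_
  }
  bg <- rep(NA_real_, length(offsets))
  ciLo <- ciHi <- rep(NA_real_, length(offsets))
  if (backgroundDraws > 0L) {
    set.seed(seed)
    ids <- names(orfLengths)
    pool <- data.frame(
      orf_id = rep(ids, orfLengths),
      codon_index = unlist(lapply(orfLengths, function(l) seq_len(l) - 1L),
                           use.names = FALSE))
    nA <- nrow(anchors)
    draws <- matrix(NA_real_, nrow = backgroundDraws, ncol = length(offsets))
    for (d in seq_len(backgroundDraws)) {
      sel <- pool[sample.int(nrow(pool), min(nA, nrow(pool))), , drop = FALSE]
      for (k in seq_along(offsets)) {
        v <- signalFn(sel$orf_id, sel$codon_index + offsets[k])
        draws[d, k] <- mean(v, na.rm = TRUE)
      }
    }
    bg <- colMeans(draws, na.rm = TRUE)
    ciLo <- apply(draws, 2, stats::quantile, 0.025, na.rm = TRUE)
    ciHi <- apply(draws, 2, stats::quantile, 0.975, na.rm = TRUE)
  } else if (!is.null(backgroundValue)) {
    bg <- rep(backgroundValue, length(offsets))
  }
  data.frame(offset = offsets, value = value, background = bg, n = nn,
             ci_lo = ciLo, ci_hi = ciHi)
}

.callLengths <- function(calls) {
  df <- pauseCalls(calls)
  tapply(df$codon_index, df$orf_id, function(v) max(v) + 1L)[
    unique(df$orf_id)] -> L
  setNames(as.integer(L), unique(df$orf_id))
}

# fast membership lookup for (orf, index) pause keys
.pauseLookup <- function(calls) {
  ps <- pauseSites(calls)
  keys <- paste(ps$orf_id, ps$codon_index)
  function(orf, idx) {
    out <- as.numeric(paste(orf, idx) %in% keys)
    out
  }
}

#' Pause-peak frequency around external anchor positions
#'
#' At each offset d in `-window..window`, the fraction of anchors with a
#' pausing peak at `anchor + d` (offsets falling outside the scored ORF are
#' dropped per position; `n` records the contributing anchors). The
#' background repeats the computation on `backgroundDraws` seeded random
#' anchor sets of equal size drawn from all scored codons, yielding a mean
#' and 2.5/97.5 percentile band.
#'
#' @param calls A [PauseCallSet-class].
#' @param anchors data.frame with columns `orf_id`, `codon_index`
#'   (e.g. factor-binding positions).
#' @param window Half-width of the trace in codons.
#' @param backgroundDraws Random anchor sets for the background (default
#'   1000; 0 disables).
#' @param seed Seed for the background draws.
#' @return data.frame `offset value background n ci_lo ci_hi`.
#' @export
pauseFrequencyTrace <- function(calls, anchors, window = 20L,
                                backgroundDraws = 1000L, seed = 1L) {
  if (!nrow(anchors)) stop("empty anchor set")
  df <- pauseCalls(calls)
  orfL <- .callLengths(calls)
  anchors <- anchors[anchors$orf_id %in% names(orfL), , drop = FALSE]
  if (!nrow(anchors)) stop("no anchors on scored ORFs")
  ps <- pauseSites(calls)
  keys <- paste(ps$orf_id, ps$codon_index)
  sig <- function(orf, idx) {
    L <- orfL[orf]
    v <- as.numeric(paste(orf, idx) %in% keys)
    v[is.na(L) | idx < 0 | idx >= L] <- NA_real_
    v
  }
  .metageneTrace(anchors, orfL, window, sig, backgroundDraws, seed)
}

#' Mean residue/codon property around pausing peaks
#'
#' Averages a numeric scale (per codon, or per residue applied through the
#' ORF translation) at each offset from the pause P sites. The background
#' band comes from seeded random anchor sets of equal size.
#'
#' @param calls A [PauseCallSet-class].
#' @param sequences Coding sequences.
#' @param scale Named numeric vector: names are codons (3-mers) or
#'   one-letter amino acids (e.g. [kyteDoolittleScale()]).
#' @param window Half-width in codons.
#' @param backgroundDraws,seed Background bootstrap controls.
#' @return data.frame `offset value background n ci_lo ci_hi`.
#' @export
propertyTrace <- function(calls, sequences, scale, window = 20L,
                          backgroundDraws = 1000L, seed = 1L) {
  chars <- .seqChar(sequences)
  codScale <- .asCodonScale(scale)
  orfL <- .callLengths(calls)
  orfL <- orfL[names(orfL) %in% names(chars)]
  anchors <- pauseSites(calls)
  anchors <- anchors[anchors$orf_id %in% names(orfL), c("orf_id",
                                                        "codon_index")]
  if (!nrow(anchors)) stop("no pause anchors with sequences")
  sig <- function(orf, idx) unname(codScale[.codonAt(orf, idx, chars)])
  .metageneTrace(anchors, orfL, window, sig, backgroundDraws, seed)
}

.asCodonScale <- function(scale) {
  if (is.null(names(scale))) stop("scale must be named")
  if (all(nchar(names(scale)) == 3L))
    return(setNames(as.numeric(scale), toupper(gsub("U", "T", names(scale)))))
  # residue scale -> apply through translation
  cods <- senseCodons()
  aa <- translateCodons(cods)
  setNames(as.numeric(scale[aa]), cods)
}

#' Secondary-structure content around pausing peaks
#'
#' For each structure class, the fraction of residues of that class at each
#' offset from the pause P sites, versus a random-anchor background. ORFs
#' without annotation are skipped (logged via message).
#'
#' @param calls A [PauseCallSet-class].
#' @param ssAnnotations data.frame `orf_id residue_index class` (0-based
#'   residues; classes e.g. helix/strand/loop).
#' @param window Half-width in codons.
#' @param backgroundDraws,seed Background bootstrap controls.
#' @return Named list of trace data.frames, one per structure class.
#' @export
secondaryStructureTrace <- function(calls, ssAnnotations, window = 20L,
                                    backgroundDraws = 200L, seed = 1L) {
  need <- c("orf_id", "residue_index", "class")
  if (!all(need %in% names(ssAnnotations)))
    stop("annotations need columns: ", paste(need, collapse = ", "))
  orfL <- .callLengths(calls)
  annotated <- intersect(names(orfL), unique(ssAnnotations$orf_id))
  skipped <- setdiff(names(orfL), annotated)
  if (length(skipped))
    message(length(skipped), " scored ORFs lack structure annotation; skipped")
  orfL <- orfL[annotated]
  if (!length(orfL)) stop("no annotated ORFs among the scored set")
  ssKey <- setNames(as.character(ssAnnotations$class),
                    paste(ssAnnotations$orf_id, ssAnnotations$residue_index))
  anchors <- pauseSites(calls)
  anchors <- anchors[anchors$orf_id %in% annotated, c("orf_id", "codon_index")]
  classes <- sort(unique(as.character(ssAnnotations$class)))
  out <- lapply(classes, function(cl) {
    sig <- function(orf, idx) {
      v <- ssKey[paste(orf, idx)]
      as.numeric(v == cl)
    }
    .metageneTrace(anchors, orfL, window, sig, backgroundDraws, seed)
  })
  names(out) <- classes
  out
}

#' Built-in residue property scales
#'
#' `kyteDoolittleScale()`: Kyte-Doolittle hydropathy per residue.
#' `sideChainVolumeScale()`: Zamyatnin side-chain volumes (A^3).
#' Both are also shipped as editable TSVs under `inst/extdata`.
#'
#' @return Named numeric vector over the 20 common amino acids.
#' @export
kyteDoolittleScale <- function() {
  c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5, E = -3.5,
    G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9, M = 1.9, F = 2.8,
    P = -1.6, S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2)
}

#' @rdname kyteDoolittleScale
#' @export
sideChainVolumeScale <- function() {
  c(A = 88.6, R = 173.4, N = 114.1, D = 111.1, C = 108.5, Q = 143.8,
    E = 138.4, G = 60.1, H = 153.2, I = 166.7, L = 166.7, K = 168.6,
    M = 162.9, F = 189.9, P = 112.7, S = 89.0, T = 116.1, W = 227.8,
    Y = 193.6, V = 140.0)
}

#' Write a metagene trace as TSV
#'
#' @param trace Trace data.frame (`offset value background n ci_lo ci_hi`).
#' @param path Output path.
#' @export
writeTrace <- function(trace, path) {
  utils::write.table(trace, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
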