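# Disome-seq: collided-ribosome footprints protect a long fragment covering
# a leading (paused) and a trailing (colliding) ribosome. The pause pipeline
# is applied per footprint-length population; site geometry maps the called
# codon onto the E/P/A frames of both ribosomes.

#' Split disome reads into the two footprint-length populations
#'
#' Disome-seq shows two footprint-length populations separated by about
#' three nucleotides. The split point is the antimode of the (optionally
#' smoothed) read-length histogram between its two highest local maxima;
#' ties go to the lower length. Lengths at or below the antimode form the
#' "short" population.
#'
#' @param reads data.frame with a `length` column (e.g. from
#'   [readReadTable()]).
#' @param smoothWindow Half-width of the moving-average smoothing of the
#'   histogram (default 0 = raw histogram).
#' @return List with `short`, `long` (row subsets of `reads`) and
#'   `split_length` (the antimode).
#' @export
splitPopulations <- function(reads, smoothWindow = 0L) {
  lens <- reads$length
  rng <- seq(min(lens), max(lens))
  h <- as.numeric(table(factor(lens, levels = rng)))
  hs <- h
  if (smoothWindow > 0L) {
    k <- 2L * smoothWindow + 1L
    hs <- as.numeric(stats::filter(h, rep(1 / k, k), sides = 2))
    hs[is.na(hs)] <- h[is.na(hs)]
  }
  n <- length(hs)
  isMax <- vapply(seq_len(n), function(i) {
    left <- if (i > 1) hs[i - 1] else -Inf
    right <- if (i < n) hs[i + 1] else -Inf
    hs[i] > 0 && hs[i] >= left && hs[i] >= right &&
      (hs[i] > left || hs[i] > right)
  }, logical(1))
  peaks <- which(isMax)
  # merge plateau peaks
  if (length(peaks) > 1) peaks <- peaks[c(TRUE, diff(peaks) > 1)]
  if (length(peaks) < 2L)
    stop("unimodal read-length histogram: cannot split populations ",
         "(peaks at ", paste(rng[peaks], collapse = ", "), ")")
  top2 <- peaks[order(hs[peaks], decreasing = TRUE)][1:2]
  lo <- min(top2); hi <- max(top2)
  between <- seq(lo + 1L, hi - 1L)
  if (!length(between)) between <- lo
  anti <- between[which.min(hs[between])]  # which.min: ties -> lower length
  splitLen <- rng[anti]
  list(short = reads[reads$length <= splitLen, , drop = FALSE],
       long = reads[reads$length > splitLen, , drop = FALSE],
       split_length = splitLen)
}

#' Call disome pausing peaks for one footprint population
#'
#' Identical contract to [callPauses()]; provided so disome workflows read
#' naturally and can be parameterized per population.
#'
#' @inheritParams callPauses
#' @return A [PauseCallSet-class].
#' @export
callDisomePauses <- function(profiles, partition, nTrees = 200L,
                             thresholdQuantile = 0.95, seed = 1L,
                             psi = NULL) {
  callPauses(profiles, partition, nTrees = nTrees,
             thresholdQuantile = thresholdQuantile, seed = seed, psi = psi)
}

#' E/P/A site frames of the leading and trailing ribosomes of a disome
#'
#' The called codon is the P site of the 3' trailing ribosome (for the long
#' footprint population the call is first shifted by `longShift` codons, the
#' one-codon displacement that matches the one-codon read-length
#' difference). The leading ribosome's P site sits `displacement` codons
#' downstream. Frames extending beyond the ORF are dropped and counted.
#'
#' @param calls A [PauseCallSet-class] from one disome population.
#' @param orfLengths Named integer vector of ORF codon lengths; defaults to
#'   lengths inferred from the scored codons.
#' @param displacement Leading-ribosome displacement in codons (default 10,
#'   about one 30-nt monosome footprint).
#' @param population "short" or "long".
#' @param longShift Codon shift applied to long-population calls (default
#'   -1).
#' @return data.frame with orf_id and trailing/leading E, P, A codon
#'   indices; dropped frame count in attribute `"dropped"`.
#' @export
siteFrames <- function(calls, orfLengths = NULL, displacement = 10L,
                       population = c("short", "long"), longShift = -1L) {
  population <- match.arg(population)
  if (displacement <= 0L) stop("displacement must be positive")
  if (is.null(orfLengths)) orfLengths <- .callLengths(calls)
  ps <- pauseSites(calls)
  p3 <- ps$codon_index + if (population == "long") as.integer(longShift) else 0L
  out <- data.frame(
    orf_id = ps$orf_id,
    trailing_E = p3 - 1L, trailing_P = p3, trailing_A = p3 + 1L,
    leading_E = p3 + displacement - 1L, leading_P = p3 + displacement,
    leading_A = p3 + displacement + 1L)
  L <- orfLengths[out$orf_id]
  ok <- !is.na(L) & out$trailing_E >= 0L & out$leading_A < L
  dropped <- sum(!ok)
  if (dropped) message(dropped, " disome calls with frames outside the ORF dropped")
  out <- out[ok, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "dropped") <- dropped
  out
}

#' Monosome pause frequency around disome trailing P sites
#'
#' Metagene trace of monosome pausing-peak frequency anchored at the
#' trailing-ribosome P sites of disome calls; a peak at the
#' leading-ribosome offset (and not at 0) is the signature of collisions
#' onto a single paused leading ribosome.
#'
#' @param disomeCalls,monosomeCalls [PauseCallSet-class] objects on shared
#'   coordinates.
#' @param window Half-width in codons (take it larger than the expected
#'   leading displacement).
#' @param population,displacement,longShift As in [siteFrames()] (used only
#'   to place the trailing anchors).
#' @param backgroundDraws,seed Background bootstrap controls.
#' @return Trace data.frame as in [pauseFrequencyTrace()].
#' @export
monosomeOverlapTrace <- function(disomeCalls, monosomeCalls, window = 15L,
                                 population = c("short", "long"),
                                 displacement = 10L, longShift = -1L,
                                 backgroundDraws = 200L, seed = 1L) {
  population <- match.arg(population)
  ps <- pauseSites(disomeCalls)
  shift <- if (population == "long") as.integer(longShift) else 0L
  anchors <- data.frame(orf_id = ps$orf_id,
                        codon_index = ps$codon_index + shift)
  pauseFrequencyTrace(monosomeCalls, anchors, window = window,
                      backgroundDraws = backgroundDraws, seed = seed)
}
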