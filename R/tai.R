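# tRNA adaptation index (tAI): per-codon decoding capacity from tRNA gene
# copy numbers weighted by wobble-pairing efficiency, and gene-level tAI as
# the geometric mean over codons.

#' Default wobble selective constraints (dos Reis values)
#'
#' The s value of a pairing type is the selective penalty of that
#' codon:anticodon interaction; the recognizing anticodon contributes
#' `(1 - s) * tGCN` to the codon's absolute adaptiveness. Types: `WC`
#' (Watson-Crick at the third position), `GU` (anticodon G34 reading codon
#' U3), `IC` (inosine from genomic A34 reading C3), `IA` (inosine reading
#' A3), `UG` (anticodon U34 reading codon G3).
#'
#' @return Named numeric vector of s values in \[0, 1\].
#' @export
taiDefaultS <- function() {
  c(WC = 0, GU = 0.41, IC = 0.28, IA = 0.9999, UG = 0.68)
}

#' Codon:anticodon recognition rules with wobble pairing
#'
#' Built from the genetic code: for every sense codon, the Watson-Crick
#' anticodon plus the standard eukaryotic wobble reader of its third base
#' (G34:U3, I34:C3, I34:A3, U34:G3; inosine arises from genomic A34). ATG is
#' restricted to its Watson-Crick anticodon (CAT) since initiator/elongator
#' methionine tRNAs do not wobble onto it.
#'
#' @return data.frame `codon anticodon pairing`.
#' @export
wobbleRules <- function() {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  revcomp3 <- function(cod) {
    s <- strsplit(cod, "")[[1]]
    paste0(comp[s[3]], comp[s[2]], comp[s[1]])
  }
  rows <- list()
  for (cod in senseCodons()) {
    wc <- revcomp3(cod)
    third <- substr(cod, 3, 3)
    tail2 <- substr(wc, 2, 3)
    rows[[length(rows) + 1L]] <- data.frame(
      codon = cod, anticodon = wc, pairing = "WC")
    if (cod == "ATG") next
    wob <- switch(third,
      "T" = c(paste0("G", tail2), "GU"),
      "C" = c(paste0("A", tail2), "IC"),
      "A" = c(paste0("A", tail2), "IA"),
      "G" = c(paste0("T", tail2), "UG"))
    rows[[length(rows) + 1L]] <- data.frame(
      codon = cod, anticodon = wob[1], pairing = wob[2])
  }
  do.call(rbind, rows)
}

#' Relative codon adaptiveness w from tRNA gene copy numbers
#'
#' Absolute adaptiveness `W_codon = sum_over_recognizing_anticodons
#' (1 - s_pairing) * tGCN(anticodon)`; relative adaptiveness `w = W / max(W)`;
#' codons with W = 0 (no recognizing tRNA encoded) are imputed with the
#' geometric mean of the nonzero w values, following the original tAI
#' definition.
#'
#' @param tgcn Named non-negative vector of tRNA gene copy numbers keyed by
#'   genomic anticodon (DNA alphabet, 5'->3').
#' @param s Named pairing constraints (see [taiDefaultS()]).
#' @param rules Recognition table (default [wobbleRules()]).
#' @return data.frame `codon W w`.
#' @export
codonW <- function(tgcn, s = taiDefaultS(), rules = wobbleRules()) {
  if (is.null(names(tgcn))) stop("tgcn must be named by anticodon")
  names(tgcn) <- toupper(gsub("U", "T", names(tgcn)))
  if (any(tgcn < 0)) stop("tgcn must be non-negative")
  if (all(tgcn == 0)) stop("all-zero tGCN")
  if (any(s < 0 | s > 1)) stop("s values must lie in [0, 1]")
  g <- tgcn[rules$anticodon]
  g[is.na(g)] <- 0
  contrib <- (1 - s[rules$pairing]) * g
  W <- tapply(contrib, rules$codon, sum)
  W <- setNames(as.numeric(W), names(W))[senseCodons()]
  w <- W / max(W)
  zero <- w == 0
  if (any(zero)) w[zero] <- exp(mean(log(w[!zero])))
  data.frame(codon = senseCodons(), W = unname(W), w = unname(w))
}

#' Gene-level tAI: geometric mean of codon adaptiveness
#'
#' @param sequence A coding sequence (character or `DNAString`), or a
#'   character vector of codons. Stop codons are excluded.
#' @param w Either the data.frame from [codonW()] or a named codon -> w
#'   vector.
#' @return tAI in (0, 1].
#' @export
geneTai <- function(sequence, w) {
  if (is.data.frame(w)) w <- setNames(w$w, w$codon)
  if (length(sequence) == 1L && nchar(sequence)[1] > 3L) {
    s <- toupper(gsub("U", "T", as.character(sequence)))
    if (nchar(s) %% 3L != 0L) stop("sequence length must be divisible by 3")
    cods <- substring(s, seq(1, nchar(s) - 2, 3), seq(3, nchar(s), 3))
  } else {
    cods <- toupper(gsub("U", "T", as.character(sequence)))
  }
  cods <- cods[!cods %in% c("TAA", "TAG", "TGA")]
  if (!length(cods)) stop("no sense codons in sequence")
  wv <- w[cods]
  if (anyNA(wv)) stop("unknown codon: ",
                      paste(unique(cods[is.na(wv)]), collapse = ", "))
  exp(mean(log(wv)))
}

#' Per-codon tAI scale for metagene traces
#'
#' @param tgcn,s,rules As in [codonW()].
#' @return Named codon -> w vector usable as a [propertyTrace()] scale.
#' @export
taiScale <- function(tgcn, s = taiDefaultS(), rules = wobbleRules()) {
  cw <- codonW(tgcn, s, rules)
  setNames(cw$w, cw$codon)
}
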