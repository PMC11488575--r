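#' Information-content logo matrix from an ungapped alignment
#'
#' For alignment column l and amino acid i, the contribution is
#' `H(l,i) = q(l,i) * log2(q(l,i) / p_i)` with `0 * log 0 := 0`, where q is
#' the observed column frequency and p the background proteome frequency.
#' Column totals `H_l = sum_i H(l,i)` are the per-position information
#' content; individual terms are negative exactly where a residue is rarer
#' than expected.
#'
#' @param alignment Character vector of equal-length residue strings.
#' @param p Named background frequencies over the 20 amino acids (strictly
#'   positive, summing to 1); default: uniform.
#' @return List of class `LogoMatrix` with `H` and `q` (columns x residues
#'   matrices), `p`, and `column_totals`.
#' @export
informationContent <- function(alignment, p = NULL) {
  if (!length(alignment)) stop("empty alignment")
  L <- unique(nchar(alignment))
  if (length(L) != 1L) stop("alignment strings must have equal length")
  aaSet <- sort(unique(translateCodons(senseCodons())))
  if (is.null(p)) p <- setNames(rep(1 / length(aaSet), length(aaSet)), aaSet)
  p <- p[aaSet]
  if (anyNA(p) || any(p <= 0)) stop("background must be positive over all 20 residues")
  p <- p / sum(p)
  m <- do.call(rbind, strsplit(alignment, ""))
  q <- t(apply(m, 2, function(col) {
    tab <- table(factor(col, levels = aaSet))
    as.numeric(tab) / length(col)
  }))
  colnames(q) <- aaSet
  H <- q * log2(sweep(q, 2, p, "/"))
  H[q == 0] <- 0
  out <- list(H = H, q = q, p = p, column_totals = rowSums(H))
  class(out) <- "LogoMatrix"
  out
}

#' @export
print.LogoMatrix <- function(x, ...) {
  cat(sprintf("LogoMatrix: %d columns x %d residues; column totals:\n",
              nrow(x$H), ncol(x$H)))
  print(round(x$column_totals, 3))
  invisible(x)
}

#' Residue background frequencies of a set of coding sequences
#'
#' @param sequences Coding sequences (`DNAStringSet` or named character).
#' @return Named frequency vector over the 20 amino acids.
#' @export
proteomeFrequencies <- function(sequences) {
  chars <- .seqChar(sequences)
  cods <- unlist(lapply(chars, function(s)
    substring(s, seq(1, nchar(s) - 2, 3), seq(3, nchar(s), 3))),
    use.names = FALSE)
  aa <- translateCodons(cods)
  aa <- aa[aa != "*"]
  tab <- table(factor(aa, levels = sort(unique(translateCodons(senseCodons())))))
  as.numeric(tab) / sum(tab) -> f
  setNames(f, names(tab))
}

#' Significantly enriched E-P-A tripeptides at pausing peaks
#'
#' The tripeptide is the residue triplet decoded in the E, P and A sites
#' when the flagged codon is in the P site. Each tripeptide observed at
#' pause sites is tested (Fisher exact, BH) against the background of
#' non-pause tripeptides; tripeptides with q < alpha and OR > 1 are
#' reported.
#'
#' @param calls A [PauseCallSet-class].
#' @param sequences Coding sequences.
#' @param alpha BH q-value cutoff (default 0.05).
#' @return data.frame of significant tripeptides with their enrichment
#'   statistics (possibly 0 rows).
#' @export
enrichedTripeptides <- function(calls, sequences, alpha = 0.05) {
  df <- pauseCalls(calls)
  chars <- .seqChar(sequences)
  df <- df[df$orf_id %in% names(chars), , drop = FALSE]
  tri <- .tripeptideAt(df$orf_id, df$codon_index, chars)
  ok <- !is.na(tri)
  res <- .enrichTable(tri[ok & df$is_pause], tri[ok & !df$is_pause])
  sig <- res[res$q < alpha & res$odds_ratio > 1 &
               res$feature %in% tri[ok & df$is_pause], , drop = FALSE]
  rownames(sig) <- NULL
  sig
}

.tripeptideAt <- function(orf, pIndex, chars) {
  e <- .codonAt(orf, pIndex - 1L, chars)
  p <- .codonAt(orf, pIndex, chars)
  a <- .codonAt(orf, pIndex + 1L, chars)
  ok <- !(is.na(e) | is.na(p) | is.na(a))
  out <- rep(NA_character_, length(orf))
  out[ok] <- paste0(translateCodons(e[ok]), translateCodons(p[ok]),
                    translateCodons(a[ok]))
  out
}

#' Optimal string alignment (restricted Damerau-Levenshtein) distance
#'
#' Edit distance allowing substitution, insertion, deletion and adjacent
#' transposition, with no substring edited twice.
#'
#' @param s1,s2 Character vectors (recycled to a common length).
#' @return Integer vector of distances.
#' @export
osaDistance <- function(s1, s2) {
  n <- max(length(s1), length(s2))
  osa_distance_cpp(rep_len(as.character(s1), n), rep_len(as.character(s2), n))
}

#' Hierarchical clustering of tripeptide motifs
#'
#' Agglomerative clustering (default UPGMA/average linkage) on the pairwise
#' restricted Damerau-Levenshtein distance matrix, cut into `k` clusters
#' (default 5). Deterministic given the linkage; input order does not
#' change the partition.
#'
#' @param tripeptides Character vector of residue 3-mers (E-P-A order).
#' @param k Number of clusters (default 5; reduced to the number of distinct
#'   tripeptides when fewer).
#' @param method Linkage passed to [stats::hclust()] (default "average").
#' @return data.frame `tripeptide cluster`, with the `hclust` object as
#'   attribute `"hclust"`.
#' @export
clusterTripeptides <- function(tripeptides, k = 5L, method = "average") {
  tripeptides <- as.character(tripeptides)
  if (length(tripeptides) < 1L) stop("no tripeptides to cluster")
  uniq <- sort(unique(tripeptides))
  if (length(uniq) == 1L) {
    out <- data.frame(tripeptide = tripeptides, cluster = 1L)
    return(out)
  }
  nd <- length(uniq)
  dm <- matrix(0L, nd, nd, dimnames = list(uniq, uniq))
  for (i in seq_len(nd - 1)) {
    j <- (i + 1):nd
    dm[i, j] <- dm[j, i] <- osaDistance(rep(uniq[i], length(j)), uniq[j])
  }
  hc <- stats::hclust(stats::as.dist(dm), method = method)
  kk <- min(k, nd)
  cl <- stats::cutree(hc, k = kk)
  out <- data.frame(tripeptide = tripeptides,
                    cluster = unname(cl[tripeptides]))
  attr(out, "hclust") <- hc
  out
}
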