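#' Fisher's exact test with a closed-form odds ratio
#'
#' The p-value is the exact two-sided hypergeometric probability (via
#' [stats::fisher.test()]); the reported odds ratio is the sample odds ratio
#' `(a*d)/(b*c)`, with the Haldane-Anscombe correction (0.5 added to every
#' cell) if and only if any cell is zero, so the estimate stays finite and
#' reproducible in closed form. The conditional-MLE estimate that
#' `fisher.test` reports is available with `estimator = "cmle"`.
#'
#' @param a,b,c,d Non-negative integer cells of the 2x2 table
#'   (rows: in class / not; columns: foreground / background).
#' @param estimator "sample" (default) or "cmle".
#' @return List with `odds_ratio` and `p`.
#' @export
fisherOr <- function(a, b, c, d, estimator = c("sample", "cmle")) {
  estimator <- match.arg(estimator)
  cells <- c(a, b, c, d)
  if (any(cells < 0) || any(cells != round(cells)))
    stop("cells must be non-negative integers")
  if (a + b == 0 || c + d == 0) {
    warning("empty margin; odds ratio undefined")
    return(list(odds_ratio = NA_real_, p = NA_real_))
  }
  ft <- stats::fisher.test(matrix(c(a, b, c, d), nrow = 2, byrow = TRUE))
  or <- if (estimator == "cmle") {
    unname(ft$estimate)
  } else {
    if (any(cells == 0)) {
      ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (c + 0.5))
    } else {
      (a * d) / (b * c)
    }
  }
  list(odds_ratio = or, p = ft$p.value)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' @param p Numeric vector of p-values in (0, 1].
#' @return Step-up adjusted q-values (monotone in rank, capped at 1).
#' @export
bhAdjust <- function(p) {
  stats::p.adjust(p, method = "BH")
}

# foreground/background site codons for enrichment analyses ------------------
# returns list(fg, bg): character vectors of codons at `offset` from pause /
# background positions; background = all non-pause codons of analyzed ORFs
.siteCodonSets <- function(calls, sequences, offset) {
  df <- pauseCalls(calls)
  chars <- .seqChar(sequences)
  df <- df[df$orf_id %in% names(chars), , drop = FALSE]
  cod <- .codonAt(df$orf_id, df$codon_index + offset, chars)
  ok <- !is.na(cod)
  list(fg = cod[ok & df$is_pause], bg = cod[ok & !df$is_pause])
}

.enrichTable <- function(fgFeat, bgFeat) {
  feats <- sort(unique(c(fgFeat, bgFeat)))
  res <- lapply(feats, function(f) {
    a <- sum(fgFeat == f); b <- length(fgFeat) - a
    cc <- sum(bgFeat == f); dd <- length(bgFeat) - cc
    fo <- fisherOr(a, b, cc, dd)
    data.frame(feature = f, a = a, b = b, c = cc, d = dd,
               odds_ratio = fo$odds_ratio, p = fo$p)
  })
  res <- do.call(rbind, res)
  res$q <- bhAdjust(res$p)
  res
}

#' Feature enrichment at a ribosome site of pausing peaks
#'
#' For each feature (e.g. amino acid), builds the 2x2 table of pause sites
#' with/without the feature at the chosen site against background positions
#' (all non-pause codons of the analyzed ORFs, read at the same site
#' offset), and reports the Fisher odds ratio, p and BH q.
#'
#' @param calls A [PauseCallSet-class].
#' @param sequences Coding sequences (`DNAStringSet` or named character).
#' @param site "E", "P" or "A" (offset -1/0/+1 from the flagged P-site
#'   codon), or an integer offset in codons.
#' @param featureMap Named character vector mapping codon -> feature; the
#'   default translates codons to amino acids.
#' @return data.frame `feature a b c d odds_ratio p q`, one row per feature.
#' @export
siteFeatureEnrichment <- function(calls, sequences, site = "A",
                                  featureMap = NULL) {
  offset <- if (is.character(site)) .siteOffset(site) else as.integer(site)
  sets <- .siteCodonSets(calls, sequences, offset)
  if (!length(sets$fg)) stop("no pause sites with a valid site codon")
  if (is.null(featureMap)) {
    cods <- senseCodons()
    featureMap <- setNames(translateCodons(cods), cods)
  }
  .enrichTable(unname(featureMap[sets$fg]), unname(featureMap[sets$bg]))
}

#' Read a codon optimality scale from TSV (`codon  class  [score]`)
#'
#' A `class` column with O/N labels is used directly; otherwise a numeric
#' `score` column is binarized at its median (above median = O).
#'
#' @param path TSV path.
#' @return Named character vector codon -> "O"/"N" over the 61 sense codons.
#' @export
readOptimalityScale <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!"codon" %in% names(df)) stop("scale needs a 'codon' column")
  cod <- toupper(gsub("U", "T", df$codon))
  if ("class" %in% names(df) && !all(is.na(df$class))) {
    cls <- toupper(df$class)
  } else if ("score" %in% names(df)) {
    cls <- ifelse(df$score > stats::median(df$score), "O", "N")
  } else stop("scale needs a 'class' or 'score' column")
  if (!all(cls %in% c("O", "N"))) stop("classes must be O or N")
  sc <- setNames(cls, cod)
  missing <- setdiff(senseCodons(), names(sc))
  if (length(missing))
    stop("scale must cover all 61 sense codons; missing: ",
         paste(head(missing, 5), collapse = ", "))
  sc[senseCodons()]
}

#' Optimality-triplet (O/N over E, P, A) enrichment at pausing peaks
#'
#' Each pause site with a full E-P-A codon context maps to one of the eight
#' optimal/non-optimal triplets (e.g. "OON": optimal codons in E and P,
#' non-optimal in A); the triplet frequencies are tested against background
#' (non-pause) triplets with Fisher's exact test.
#'
#' @param calls A [PauseCallSet-class].
#' @param sequences Coding sequences.
#' @param scale Named codon -> "O"/"N" vector (see [readOptimalityScale()]).
#' @param anchorSite Site carrying the flagged codon; "P" (default) places
#'   the E/P/A context at offsets -1/0/+1, "A" at -2/-1/0.
#' @return data.frame as in [siteFeatureEnrichment()], features "OOO".."NNN".
#' @export
optimalityTripletEnrichment <- function(calls, sequences, scale,
                                        anchorSite = c("P", "A")) {
  anchorSite <- match.arg(anchorSite)
  shift <- if (anchorSite == "P") 0L else -1L
  df <- pauseCalls(calls)
  chars <- .seqChar(sequences)
  df <- df[df$orf_id %in% names(chars), , drop = FALSE]
  tri <- .tripletClass(df$orf_id, df$codon_index + shift, chars, scale)
  ok <- !is.na(tri)
  nDrop <- sum(!ok & df$is_pause)
  if (nDrop) message(nDrop, " pause sites without full E-P-A context dropped")
  .enrichTable(tri[ok & df$is_pause], tri[ok & !df$is_pause])
}

.tripletClass <- function(orf, pIndex, chars, scale) {
  e <- .codonAt(orf, pIndex - 1L, chars)
  p <- .codonAt(orf, pIndex, chars)
  a <- .codonAt(orf, pIndex + 1L, chars)
  out <- paste0(scale[e], scale[p], scale[a])
  out[is.na(e) | is.na(p) | is.na(a)] <- NA_character_
  out
}

#' Bicodon-pair enrichment at anchored pausing sites
#'
#' Among pause sites whose P-site codon equals `anchorCodon`, tests whether
#' each partner codon at `partnerOffset` codons (default +1: the A site) is
#' seen more often than among background occurrences of the anchor codon
#' (non-pause positions, translatome-wide). `partnerOffset = -1` tests the
#' inversely ordered pairs.
#'
#' @param calls A [PauseCallSet-class].
#' @param sequences Coding sequences.
#' @param anchorCodon Codon at the pause P site (e.g. "AGG").
#' @param partnerCodons Codons to test at the partner position (default the
#'   four proline codons).
#' @param partnerOffset Offset of the partner codon (default +1).
#' @return data.frame as in [siteFeatureEnrichment()], one row per partner
#'   codon present.
#' @export
bicodonPairEnrichment <- function(calls, sequences, anchorCodon = "AGG",
                                  partnerCodons = c("CCA", "CCC", "CCG", "CCT"),
                                  partnerOffset = 1L) {
  anchorCodon <- toupper(gsub("U", "T", anchorCodon))
  partnerCodons <- toupper(gsub("U", "T", partnerCodons))
  df <- pauseCalls(calls)
  chars <- .seqChar(sequences)
  df <- df[df$orf_id %in% names(chars), , drop = FALSE]
  own <- .codonAt(df$orf_id, df$codon_index, chars)
  partner <- .codonAt(df$orf_id, df$codon_index + partnerOffset, chars)
  ok <- !is.na(own) & !is.na(partner) & own == anchorCodon
  fg <- partner[ok & df$is_pause]
  bg <- partner[ok & !df$is_pause]
  if (!length(fg)) {
    warning("no pause sites anchored at ", anchorCodon)
    return(NULL)
  }
  res <- .enrichTable(fg, bg)
  res <- res[res$feature %in% partnerCodons, , drop = FALSE]
  if (!nrow(res)) warning("no tested partner codon follows the anchor")
  res$q <- bhAdjust(res$p)
  rownames(res) <- NULL
  res
}

#' Theil-Sen regression with MAD outlier flagging
#'
#' Robust comparison of per-codon pause fractions between two conditions:
#' slope is the median of all pairwise slopes, intercept the median of
#' `y - slope * x`, and codons whose absolute residual exceeds
#' `k * mad(residuals)` are flagged as outliers (i.e. codons whose pausing
#' behaviour changed between the conditions).
#'
#' @param x,y Named numeric vectors (e.g. codon fractions in two strains).
#' @param k MAD multiplier for outlier flagging (default 3).
#' @return List with `slope`, `intercept`, `residuals`, `outliers` (names).
#' @export
theilSenOutliers <- function(x, y, k = 3) {
  if (length(x) != length(y) || length(x) < 3L)
    stop("need >= 3 paired observations")
  if (!is.null(names(x)) && !is.null(names(y))) y <- y[names(x)]
  n <- length(x)
  ij <- utils::combn(n, 2)
  dx <- x[ij[2, ]] - x[ij[1, ]]
  dy <- y[ij[2, ]] - y[ij[1, ]]
  keep <- dx != 0
  if (!any(keep)) stop("all x identical; slope undefined")
  slope <- stats::median(dy[keep] / dx[keep])
  intercept <- stats::median(y - slope * x)
  res <- y - (slope * x + intercept)
  m <- stats::mad(res)
  # degenerate exact fits have MAD 0; any real deviation is then an outlier
  thr <- if (m > 0) k * m else 1e-8
  outliers <- names(x)[abs(res) > thr]
  if (is.null(names(x))) outliers <- which(abs(res) > thr)
  list(slope = unname(slope), intercept = unname(intercept),
       residuals = res, outliers = outliers)
}
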