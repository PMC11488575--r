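#' Configuration for the synthetic translatome generator
#'
#' Defaults describe a budding-yeast-like translatome: log-normal ORF
#' lengths with median ~400 codons, per-codon expression spanning roughly
#' three orders of magnitude, negative-binomial counting noise with variance
#' about twice the mean at mean 10 (size = 10), elevated coverage ramps at
#' both ORF ends from initiation/termination pile-up, and optional
#' codon-specific dwell-time multipliers.
#'
#' @param nOrfs Number of ORFs.
#' @param lengthMeanLog,lengthSdLog Log-normal codon-length parameters
#'   (median `exp(lengthMeanLog)`).
#' @param minLength,maxLength Codon-length clamp.
#' @param exprMeanLog,exprSdLog Log-normal mean-reads-per-codon parameters.
#' @param nbSize Negative-binomial size (dispersion) parameter.
#' @param ramp5Height,ramp5Length Linear 5' coverage ramp: multiplier at the
#'   first codon and the number of codons over which it decays to 1.
#' @param ramp3Height,ramp3Length Same for the 3' end.
#' @param dwell Named numeric vector of per-codon dwell multipliers
#'   (codons not named have multiplier 1).
#' @param dwellSite Ribosome site whose codon drives the dwell multiplier of
#'   a position ("A", the decoding site, by default: footprint density at
#'   P-site codon i is elevated when codon i+1 is slow; "P" applies the
#'   multiplier at the codon itself).
#' @param codonWeights Optional named sampling weights over the 61 sense
#'   codons (default uniform).
#' @param pausesPerOrf Injected pauses per ORF used by [injectPauses()].
#' @param seed Integer seed.
#' @return A list of class `simConfig`.
#' @export
simConfig <- function(nOrfs = 2000L,
                      lengthMeanLog = log(400), lengthSdLog = 0.45,
                      minLength = 50L, maxLength = 2500L,
                      exprMeanLog = log(2), exprSdLog = 1.6,
                      nbSize = 10,
                      ramp5Height = 2, ramp5Length = 50L,
                      ramp3Height = 1.5, ramp3Length = 20L,
                      dwell = NULL, dwellSite = c("A", "P"),
                      codonWeights = NULL,
                      pausesPerOrf = 1L, seed = 1L) {
  dwellSite <- match.arg(dwellSite)
  if (!is.null(dwell) && (is.null(names(dwell)) || any(dwell < 0)))
    stop("dwell must be a named, non-negative multiplier vector")
  if (ramp5Height < 1 || ramp3Height < 1)
    stop("ramp multipliers must be >= 1")
  cfg <- as.list(environment())
  class(cfg) <- "simConfig"
  cfg
}

# per-position dwell multipliers: the codon of the chosen ribosome site
# drives the dwell at each (P-site-annotated) position
.dwellVector <- function(cv, dwell, dwellSite) {
  key <- if (dwellSite == "A") c(cv[-1], NA) else cv
  mult <- unname(dwell[key])
  mult[is.na(mult)] <- 1
  mult
}

.rampProfile <- function(L, h5, k5, h3, k3) {
  i <- seq_len(L)
  r5 <- 1 + (h5 - 1) * pmax(0, (k5 - i + 1) / k5)
  r3 <- 1 + (h3 - 1) * pmax(0, (k3 - (L - i)) / k3)
  r5 * r3
}

#' Generate a seeded synthetic translatome with ground truth
#'
#' Sequences start with ATG, continue with sense codons drawn from
#' `codonWeights` and end with a TAA stop. Per-codon counts are drawn as
#' `NegBin(mean = expression * ramp_i * dwell(codon_i), size = nbSize)`.
#'
#' @param cfg A [simConfig()].
#' @return List with `profiles` (named list of integer count vectors),
#'   `sequences` (`DNAStringSet`, stop codon included), `truth` (list with
#'   the dwell multipliers and per-ORF expression), and `config`.
#' @export
generateTranslatome <- function(cfg = simConfig()) {
  stopifnot(inherits(cfg, "simConfig"))
  set.seed(cfg$seed)
  L <- pmin(pmax(round(rlnorm(cfg$nOrfs, cfg$lengthMeanLog, cfg$lengthSdLog)),
                 cfg$minLength), cfg$maxLength)
  expr <- rlnorm(cfg$nOrfs, cfg$exprMeanLog, cfg$exprSdLog)
  ids <- sprintf("ORF%04d", seq_len(cfg$nOrfs))

  codons <- senseCodons()
  w <- rep(1, length(codons))
  if (!is.null(cfg$codonWeights)) {
    w <- cfg$codonWeights[codons]
    w[is.na(w)] <- 0
  }
  dwell <- setNames(rep(1, length(codons)), codons)
  if (!is.null(cfg$dwell)) {
    nm <- toupper(gsub("U", "T", names(cfg$dwell)))
    dwell[nm[nm %in% codons]] <- cfg$dwell[nm %in% codons]
  }

  profiles <- vector("list", cfg$nOrfs)
  seqs <- character(cfg$nOrfs)
  for (k in seq_len(cfg$nOrfs)) {
    body <- sample(codons, L[k] - 1L, replace = TRUE, prob = w)
    cv <- c("ATG", body)
    seqs[k] <- paste0(paste(cv, collapse = ""), "TAA")
    mu <- expr[k] *
      .rampProfile(L[k], cfg$ramp5Height, cfg$ramp5Length,
                   cfg$ramp3Height, cfg$ramp3Length) *
      .dwellVector(cv, dwell, cfg$dwellSite)
    profiles[[k]] <- as.numeric(rnbinom(L[k], mu = mu, size = cfg$nbSize))
  }
  names(profiles) <- ids
  sequences <- Biostrings::DNAStringSet(setNames(seqs, ids))
  list(profiles = profiles, sequences = sequences,
       truth = list(dwell = dwell, expression = setNames(expr, ids),
                    lengths = setNames(L, ids)),
       config = cfg)
}

#' Resample counts for a replicate library sharing the ground truth
#'
#' Draws a fresh negative-binomial realization from the same sequences,
#' per-ORF expression, ramps and dwell multipliers as an existing synthetic
#' translatome — i.e. a technical/biological replicate with independent
#' counting noise.
#'
#' @param translatome Result of [generateTranslatome()].
#' @param seed Seed for the replicate draw.
#' @return The same structure with new `profiles`.
#' @export
resampleCounts <- function(translatome, seed) {
  cfg <- translatome$config
  set.seed(seed)
  chars <- .seqChar(translatome$sequences)
  dwell <- translatome$truth$dwell
  expr <- translatome$truth$expression
  profiles <- lapply(names(translatome$profiles), function(id) {
    L <- length(translatome$profiles[[id]])
    cv <- substring(chars[[id]], seq(1, 3 * L - 2, 3), seq(3, 3 * L, 3))
    mu <- expr[[id]] *
      .rampProfile(L, cfg$ramp5Height, cfg$ramp5Length,
                   cfg$ramp3Height, cfg$ramp3Length) *
      .dwellVector(cv, dwell, cfg$dwellSite)
    as.numeric(rnbinom(L, mu = mu, size = cfg$nbSize))
  })
  names(profiles) <- names(translatome$profiles)
  out <- translatome
  out$profiles <- profiles
  out
}

#' Inject ground-truth pausing outliers into normalized profiles
#'
#' Implements the two-step benchmark construction. Step 1 flattens
#' pre-existing outliers: every codon whose normalized count exceeds twice
#' the ORF's (pre-flattening, sample) SD of normalized counts is set to the
#' ORF mean (1 on the normalized scale). Step 2 adds `Uniform(2.5, 3) * SD`
#' (the same pre-flattening SD) to `nPerOrf` random positions per ORF; these
#' positions are the ground-truth pause labels. ORFs whose SD is zero are
#' not flattened and their spike uses the translatome mean SD as a
#' documented fallback.
#'
#' @param profiles Named list of count vectors (raw counts are normalized
#'   internally) or a [CodonProfileSet-class].
#' @param nPerOrf Injected positions per ORF (default 1).
#' @param seed Integer seed.
#' @return List with `profiles` (named list of normalized, spiked profiles),
#'   `labels` (data.frame orf_id, codon_index, magnitude) and `sd` (the
#'   per-ORF SDs used).
#' @export
injectPauses <- function(profiles, nPerOrf = 1L, seed = 1L) {
  counts <- .asCountsList(profiles)
  counts <- counts[vapply(counts, sum, numeric(1)) > 0]
  set.seed(seed)
  u <- lapply(names(counts), function(id) normalizeProfile(counts[[id]], id)$u)
  names(u) <- names(counts)
  sds <- vapply(u, stats::sd, numeric(1))
  sdFallback <- mean(sds[sds > 0])
  labs <- vector("list", length(u))
  for (k in seq_along(u)) {
    v <- u[[k]]
    s <- sds[k]
    if (s > 0) v[v > 2 * s] <- 1  # step 1: flatten outliers to the ORF mean
    sUse <- if (s > 0) s else sdFallback
    L <- length(v)
    npos <- min(nPerOrf, L)
    if (npos > 0) {
      pos <- sample.int(L, npos)
      mag <- runif(npos, 2.5, 3) * sUse
      v[pos] <- v[pos] + mag
      labs[[k]] <- data.frame(orf_id = names(u)[k], codon_index = pos - 1L,
                              magnitude = mag)
    }
    u[[k]] <- v
  }
  labels <- if (length(labs) && any(!vapply(labs, is.null, logical(1)))) {
    do.call(rbind, labs)
  } else {
    data.frame(orf_id = character(0), codon_index = integer(0),
               magnitude = numeric(0))
  }
  list(profiles = u, labels = labels, sd = sds)
}

#' ROC benchmark of pause scores against ground-truth labels
#'
#' AUC by the rank (Mann-Whitney) formulation with mid-ranks for ties; TPR
#' and FPR are evaluated on a provided flag set (typically the pipeline's
#' 0.95-quantile pausing peaks).
#'
#' @param scores Numeric vector of per-codon scores.
#' @param labels Logical vector, TRUE at injected positions.
#' @param flagged Optional logical vector of flagged codons; if NULL only the
#'   AUC is returned.
#' @return List with `auc`, `tpr`, `fpr`, `n_pos`, `n_neg`.
#' @export
benchmarkRoc <- function(scores, labels, flagged = NULL) {
  labels <- as.logical(labels)
  nP <- sum(labels); nN <- sum(!labels)
  if (nP == 0L || nN == 0L) stop("labels must contain both classes")
  r <- rank(scores)
  auc <- (sum(r[labels]) - nP * (nP + 1) / 2) / (nP * nN)
  tpr <- fpr <- NA_real_
  if (!is.null(flagged)) {
    flagged <- as.logical(flagged)
    tpr <- sum(flagged & labels) / nP
    fpr <- sum(flagged & !labels) / nN
  }
  list(auc = auc, tpr = tpr, fpr = fpr, n_pos = nP, n_neg = nN)
}

#' Run the injected-pause validation pipeline end to end
#'
#' Convenience wrapper used by the benchmark and the acceptance tests:
#' generates a translatome, computes the TPM partition from the raw counts,
#' injects ground-truth pauses into the normalized profiles, calls pauses
#' with the forest pipeline, and scores recovery.
#'
#' @param cfg A [simConfig()]; its seed drives the simulation and injection.
#' @param nTrees,thresholdQuantile,psi Forwarded to [callPauses()].
#' @return List with `roc` (from [benchmarkRoc()]), `calls`, `labels`,
#'   `partition`.
#' @export
injectedPauseBenchmark <- function(cfg = simConfig(), nTrees = 200L,
                                   thresholdQuantile = 0.95, psi = NULL) {
  tl <- generateTranslatome(cfg)
  tpm <- computeTpm(tl$profiles)
  part <- partitionByTpm(tpm)
  inj <- injectPauses(tl$profiles, nPerOrf = cfg$pausesPerOrf,
                      seed = cfg$seed + 7L)
  calls <- callPauses(inj$profiles, part, nTrees = nTrees,
                      thresholdQuantile = thresholdQuantile,
                      seed = cfg$seed, psi = psi)
  df <- pauseCalls(calls)
  key <- paste(df$orf_id, df$codon_index)
  lab <- key %in% paste(inj$labels$orf_id, inj$labels$codon_index)
  roc <- benchmarkRoc(df$score, lab, df$is_pause)
  list(roc = roc, calls = calls, labels = inj$labels, partition = part,
       translatome = tl)
}
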